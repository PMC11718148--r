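#' Read sequences from FASTA or FASTQ
#'
#' Reads a FASTA or FASTQ file into a \linkS4class{DNAStringSet}. Record ids
#' (the part of the header up to the first whitespace) become the element
#' names and must be unique. Lowercase bases are uppercased (soft masking is
#' ignored) and IUPAC ambiguity codes other than \code{N} are replaced by
#' \code{N} with a warning. For FASTQ, per-base qualities are kept in the
#' \code{quality} metadata column as plain character strings of the same
#' length as the read.
#'
#' @param path Path to the sequence file.
#' @param format \code{"auto"} (by extension), \code{"fasta"} or
#'   \code{"fastq"}.
#' @return A \code{DNAStringSet}; empty for an empty file.
#' @export
readSeqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0)
    return(Biostrings::DNAStringSet())
  raw <- Biostrings::readBStringSet(path, format = format,
                                    with.qualities = (format == "fastq"))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id '", dup, "' (record ",
         which(ids == dup)[2L], ") in ", path)
  }
  sq <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained IUPAC ambiguity codes; ",
            "replaced with N")
    sq[bad] <- gsub("[^ACGTN]", "N", sq[bad])
  }
  out <- Biostrings::DNAStringSet(sq)
  names(out) <- ids
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(raw)$qualities)
    if (any(nchar(qual) != nchar(sq)))
      stop("quality length differs from sequence length in ", path)
    S4Vectors::mcols(out)$quality <- qual
  }
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x A named \code{DNAStringSet} (or character vector). For FASTQ,
#'   qualities are taken from the \code{quality} metadata column when
#'   present, else a constant \code{"I"} (Phred 40) is used.
#' @param path Output path.
#' @param format \code{"fasta"} or \code{"fastq"}.
#' @return \code{path}, invisibly.
#' @export
writeSeqs <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) && length(x))
    names(x) <- paste0("seq", seq_along(x))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    qual <- S4Vectors::mcols(x)$quality
    if (is.null(qual))
      qual <- vapply(Biostrings::width(x),
                     function(w) strrep("I", w), "")
    xPlain <- x
    S4Vectors::mcols(xPlain) <- NULL
    qs <- Biostrings::QualityScaledDNAStringSet(
      xPlain, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(qs, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# feature tables: internal convention is 0-based half-open; GFF3 on disk is
# 1-based inclusive.

.FEATURE_CORE <- c("seq_id", "start", "end", "strand", "kind")

#' Convert a 0-based half-open feature table to GRanges (1-based inclusive)
#'
#' @param features data.frame with columns \code{seq_id}, \code{start},
#'   \code{end} (0-based half-open), \code{strand} (+/-/.), \code{kind};
#'   any further columns become metadata columns.
#' @return A \code{GRanges} object.
#' @export
featuresToGRanges <- function(features) {
  stopifnot(all(.FEATURE_CORE %in% names(features)))
  if (nrow(features) && any(features$start < 0 | features$end <= features$start))
    stop("invalid feature coordinates: need 0 <= start < end")
  str <- features$strand
  str[!str %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = str)
  gr$type <- features$kind
  extra <- setdiff(names(features), .FEATURE_CORE)
  for (cc in extra) S4Vectors::mcols(gr)[[cc]] <- features[[cc]]
  gr
}

#' Convert GRanges back to the 0-based half-open feature table
#'
#' @param gr A \code{GRanges} with a \code{type} metadata column.
#' @return data.frame in the internal convention.
#' @export
grangesToFeatures <- function(gr) {
  mc <- as.data.frame(S4Vectors::mcols(gr))
  kind <- if ("type" %in% names(mc)) as.character(mc$type) else
    rep(".", length(gr))
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "."
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = str,
    kind = kind,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(mc), "type")
  for (cc in extra) out[[cc]] <- as.character(mc[[cc]])
  out
}

#' Write a feature table as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to GFF3's 1-based inclusive columns; extra columns become GFF3
#' attributes, so \code{readFeatures(writeFeatures(x))} reproduces \code{x}.
#'
#' @param features Feature data.frame (see \code{\link{featuresToGRanges}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(features, path) {
  gr <- featuresToGRanges(features)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a GFF3 file into the internal 0-based half-open feature table
#'
#' @param path GFF3 file.
#' @return Feature data.frame.
#' @export
readFeatures <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  keep <- setdiff(names(S4Vectors::mcols(gr)),
                  c("source", "phase", "score"))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  grangesToFeatures(gr)
}

# ---------------------------------------------------------------------------
# result tables: TSV with '#'-commented header lines carrying provenance

#' Write a result table as TSV with commented provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named character vector written as \code{# key: value} lines
#'   (typically config hash and seed).
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table, skipping commented header lines
#'
#' @param path File written by \code{\link{writeResultTable}}.
#' @return data.frame. The provenance lines are attached as the
#'   \code{"meta"} attribute.
#' @export
readResultTable <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- sub("^# ?", "", metaLines)
  df
}
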