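#' Map RNA-seq reads to repeat references
#'
#' Seed-and-extend local alignment (both strands) of each read against the
#' reference set; a read is assigned to its single best target whose
#' alignment reaches \code{identityThreshold} percent identity over at
#' least \code{coverageThreshold} of the read. Score ties go to the
#' reference earlier in \code{references} (references are processed in
#' name order, so ties resolve to the smaller target id). Reads longer
#' than \code{capLength} are capped (never padded).
#'
#' @param reads Named \code{DNAStringSet}.
#' @param references Named \code{DNAStringSet} (contigs or genome).
#' @param identityThreshold,coverageThreshold Mapping criterion (defaults
#'   90 / 0.55).
#' @param capLength Maximum read length used (default 151).
#' @param clusterOf Optional named map contig id -> cluster id, used to
#'   fill the \code{cluster_id} column.
#' @return data.frame: read_id, target_id, cluster_id, identity,
#'   coverage, t_start, t_end (0-based half-open on the target),
#'   orientation. Unassigned reads have NA target.
#' @export
mapRnaReads <- function(reads, references, identityThreshold = 90,
                        coverageThreshold = 0.55, capLength = 151L,
                        clusterOf = NULL) {
  if (!length(references)) stop("empty reference set")
  ord <- order(names(references))
  references <- references[ord]
  sq <- as.character(reads)
  tooLong <- nchar(sq) > capLength
  sq[tooLong] <- substr(sq[tooLong], 1L, capLength)
  m <- .rs_map_reads(sq, as.character(references), identityThreshold,
                     coverageThreshold, 13L, 8L, 30L)
  targetId <- ifelse(is.na(m$target), NA_character_,
                     names(references)[m$target])
  clusterId <- NA_character_
  if (!is.null(clusterOf))
    clusterId <- unname(clusterOf[targetId])
  data.frame(
    read_id = names(reads), target_id = targetId, cluster_id = clusterId,
    identity = m$identity, coverage = m$coverage,
    t_start = m$t_start, t_end = m$t_end,
    orientation = ifelse(is.na(m$orientation), NA_character_,
                         ifelse(m$orientation == 1, "forward",
                                "reverse-complement")),
    stringsAsFactors = FALSE)
}

#' Transcript proportion of repeat clusters in one RNA library
#'
#' Reads assigned to rDNA-, organelle- or tRNA-flagged clusters are
#' removed from both the numerators and the denominator; the denominator
#' is the total reads analyzed minus those excluded reads. TP of a unit is
#' 100 x mapped reads / denominator. Per-cluster, per-lineage, per-class
#' and total TPs are returned; clusters with zero assigned reads keep a
#' 0\% row.
#'
#' @param assignments data.frame from \code{\link{mapRnaReads}} (cluster
#'   mode: \code{cluster_id} filled).
#' @param clusterAnno Cluster table with \code{cluster_id},
#'   \code{classLabel}, \code{lineage}, \code{flag}.
#' @param totalReads Total number of reads analyzed in the library.
#' @return List: \code{clusters}, \code{lineages}, \code{classes}
#'   (data.frames with mapped_reads and tp), \code{total} (scalar percent
#'   TP), \code{denominator}, \code{excluded_reads}.
#' @export
transcriptProportion <- function(assignments, clusterAnno, totalReads) {
  asg <- assignments[!is.na(assignments$cluster_id), , drop = FALSE]
  flagOf <- setNames(clusterAnno$flag, clusterAnno$cluster_id)
  excl <- flagOf[asg$cluster_id] %in% c("rDNA", "organelle", "tRNA")
  excludedReads <- sum(excl)
  denom <- totalReads - excludedReads
  if (denom <= 0) stop("denominator is not positive after exclusions")
  kept <- asg[!excl, , drop = FALSE]

  counts <- table(factor(kept$cluster_id,
                         levels = clusterAnno$cluster_id))
  cl <- data.frame(
    cluster_id = clusterAnno$cluster_id,
    classLabel = clusterAnno$classLabel,
    lineage = clusterAnno$lineage,
    flag = clusterAnno$flag,
    mapped_reads = as.integer(counts),
    stringsAsFactors = FALSE)
  isExcl <- cl$flag %in% c("rDNA", "organelle", "tRNA")
  cl$tp <- ifelse(isExcl, NA_real_, 100 * cl$mapped_reads / denom)
  ok <- cl[!isExcl, , drop = FALSE]

  agg <- function(keys) {
    sp <- split(ok, keys)
    data.frame(
      unit = names(sp),
      mapped_reads = vapply(sp, function(x) sum(x$mapped_reads), 0L),
      tp = vapply(sp, function(x) sum(x$tp), 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  lin <- agg(paste(ok$classLabel, ok$lineage, sep = ":"))
  cls <- agg(ok$classLabel)
  list(clusters = cl, lineages = lin, classes = cls,
       total = sum(ok$tp), denominator = denom,
       excluded_reads = excludedReads)
}

#' Count mapped reads per annotated element (union rule)
#'
#' A read counts for an element exactly when its aligned genomic interval
#' overlaps exactly one element; reads overlapping two or more elements
#' are ambiguous and discarded.
#'
#' @param assignments data.frame from \code{\link{mapRnaReads}} run
#'   against the assembly (target = contig; t_start/t_end genomic).
#' @param elements \code{GRanges} of elements (e.g. from
#'   \code{\link{annotateLtrElements}}).
#' @return List: \code{counts} (integer vector parallel to
#'   \code{elements}), \code{ambiguous} (number of discarded reads),
#'   \code{assigned} (number of counted reads).
#' @export
countPerElement <- function(assignments, elements) {
  asg <- assignments[!is.na(assignments$target_id), , drop = FALSE]
  counts <- integer(length(elements))
  ambiguous <- 0L
  if (nrow(asg) && length(elements)) {
    gr <- GenomicRanges::GRanges(
      asg$target_id,
      IRanges::IRanges(asg$t_start + 1L, asg$t_end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, elements, ignore.strand = TRUE))
    nHits <- tabulate(S4Vectors::queryHits(ov), nbins = length(gr))
    uniq <- which(nHits == 1L)
    ambiguous <- sum(nHits >= 2L)
    if (length(uniq)) {
      sel <- S4Vectors::queryHits(ov) %in% uniq
      counts <- tabulate(S4Vectors::subjectHits(ov)[sel],
                         nbins = length(elements))
    }
  }
  list(counts = counts, ambiguous = ambiguous, assigned = sum(counts))
}

#' Transcript-proportion summary by structural completeness
#'
#' For each library: TP of complete elements, TP of incomplete elements,
#' their sum, and the incomplete fraction (incomplete TP / total TP);
#' plus the mean over libraries of the same type.
#'
#' @param elementCounts data.frame with columns \code{library_id},
#'   \code{library_type}, \code{element_id}, \code{completeness},
#'   \code{mapped_reads}.
#' @param denominators Named numeric: per-library read denominator (after
#'   exclusions).
#' @return data.frame per library with \code{tp_complete},
#'   \code{tp_incomplete}, \code{tp_total}, \code{fraction_incomplete};
#'   attribute \code{"byType"} holds means per library type.
#' @export
completenessTpSummary <- function(elementCounts, denominators) {
  libs <- unique(elementCounts[, c("library_id", "library_type")])
  rows <- lapply(seq_len(nrow(libs)), function(i) {
    sub <- elementCounts[elementCounts$library_id == libs$library_id[i], ]
    denom <- denominators[[libs$library_id[i]]]
    tpc <- 100 * sum(sub$mapped_reads[sub$completeness == "complete"]) / denom
    tpi <- 100 * sum(sub$mapped_reads[sub$completeness == "incomplete"]) / denom
    tot <- tpc + tpi
    data.frame(library_id = libs$library_id[i],
               library_type = libs$library_type[i],
               tp_complete = tpc, tp_incomplete = tpi, tp_total = tot,
               fraction_incomplete = if (tot > 0) tpi / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  byType <- do.call(rbind, lapply(split(out, out$library_type), function(x)
    data.frame(library_type = x$library_type[1],
               tp_complete = mean(x$tp_complete),
               tp_incomplete = mean(x$tp_incomplete),
               tp_total = mean(x$tp_total),
               fraction_incomplete = mean(x$fraction_incomplete,
                                          na.rm = TRUE))))
  attr(out, "byType") <- byType
  out
}

#' Filter expressed elements and tally their genomic context
#'
#' Keeps elements with at least \code{minReads} mapped reads in any
#' library and reports the intronic / non-intronic tally.
#'
#' @param countsMatrix Integer matrix elements x libraries.
#' @param elements \code{GRanges} parallel to the rows (with
#'   \code{element_id} and \code{context}).
#' @param minReads Threshold (default 100; \code{>= minReads} is kept).
#' @return List: \code{elements} (data.frame of kept elements with
#'   per-library counts and context), \code{tally} (named counts:
#'   intronic, non_intronic).
#' @export
filterExpressedElements <- function(countsMatrix, elements,
                                    minReads = 100L) {
  countsMatrix <- as.matrix(countsMatrix)
  keep <- apply(countsMatrix, 1L, max) >= minReads
  df <- data.frame(
    element_id = elements$element_id[keep],
    context = elements$context[keep],
    completeness = elements$completeness[keep],
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(countsMatrix[keep, , drop = FALSE]))
  tally <- c(intronic = sum(df$context == "intronic"),
             non_intronic = sum(df$context != "intronic"))
  list(elements = df, tally = tally)
}

#' Export read-to-reference mappings as BED
#'
#' Writes one BED line per assigned read (target, 0-based half-open
#' interval, read id, alignment score, strand) — a lightweight record of
#' the in-memory alignments.
#'
#' @param assignments data.frame from \code{\link{mapRnaReads}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMappingsBed <- function(assignments, path) {
  asg <- assignments[!is.na(assignments$target_id), , drop = FALSE]
  strand <- ifelse(asg$orientation == "reverse-complement", "-", "+")
  score <- if ("score" %in% names(asg)) asg$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", asg$target_id,
                   asg$t_start, asg$t_end, asg$read_id,
                   as.integer(round(asg$identity * 10)), strand)
  writeLines(lines, path)
  invisible(path)
}
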