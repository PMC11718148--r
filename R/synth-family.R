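#' Generative description of one planted repeat family
#'
#' A family spec fixes everything the generator needs to emit one repeat
#' family: its class and lineage label, copy number, monomer/unit length,
#' GC target, per-copy divergence from the family master (independent
#' substitutions, star phylogeny) and indel rate, the structural layout
#' (LTR pair, PBS, TSD length and protein-domain order for LTR families;
#' terminal inverted repeats for DNA transposons; monomer and array size
#' for satellites), the fraction of copies emitted structurally incomplete,
#' and per-library transcription weights.
#'
#' @slot name Family name (unique within a run).
#' @slot classLabel One of \code{Ty1/copia}, \code{Ty3/gypsy}, \code{LINE},
#'   \code{unclassified_LTR}, \code{DNA_transposon}, \code{satellite},
#'   \code{rDNA}, \code{organelle}, \code{unknown}.
#' @slot lineage Lineage label (e.g. \code{Tekay}); \code{""} when not
#'   applicable.
#' @slot copyNumber Number of genomic copies (>= 1).
#' @slot unitLength Length of the family master in bp.
#' @slot gcTarget Target GC fraction in (0, 1).
#' @slot perCopyDivergence Substitution probability per base applied
#'   independently to each copy (0 to 0.3).
#' @slot indelRate Indel probability per base per copy.
#' @slot structure Named list: for LTR families \code{ltrLength},
#'   \code{pbsTrna} (name in \code{\link{trnaLibrary}}), \code{tsdLength}
#'   (4-6); for DNA transposons \code{tirLength}; for satellites
#'   \code{monomerLength} and \code{arrayCopies}.
#' @slot incompleteFraction Fraction of copies emitted lacking PBS and/or
#'   TSD.
#' @slot transcriptionWeight Named numeric, expected fraction of each RNA
#'   library's reads drawn from this family
#'   (\code{c(polyA = , ribodepleted = )}).
#' @slot copyFactor Read-sampling weight multiplier for separate-contig
#'   (organellar) families, emulating organelle copy number per cell.
#' @slot separateContig Whether the family is emitted as its own contig
#'   (organelle) rather than inserted into the nuclear background.
#' @export
setClass("RepeatFamilySpec", representation(
  name = "character", classLabel = "character", lineage = "character",
  copyNumber = "integer", unitLength = "integer", gcTarget = "numeric",
  perCopyDivergence = "numeric", indelRate = "numeric", structure = "list",
  incompleteFraction = "numeric", transcriptionWeight = "numeric",
  copyFactor = "numeric", separateContig = "logical"
))

.CLASS_LABELS <- c("Ty1/copia", "Ty3/gypsy", "LINE", "unclassified_LTR",
                   "DNA_transposon", "satellite", "rDNA", "organelle",
                   "unknown", "Pararetrovirus")

setValidity("RepeatFamilySpec", function(object) {
  msgs <- character(0)
  if (!nzchar(object@name)) msgs <- c(msgs, "name must be non-empty")
  if (!object@classLabel %in% .CLASS_LABELS)
    msgs <- c(msgs, paste0("unknown classLabel '", object@classLabel, "'"))
  if (object@copyNumber < 1L) msgs <- c(msgs, "copyNumber must be >= 1")
  if (object@perCopyDivergence < 0 || object@perCopyDivergence > 0.3)
    msgs <- c(msgs, "perCopyDivergence must be in [0, 0.3]")
  if (object@gcTarget <= 0 || object@gcTarget >= 1)
    msgs <- c(msgs, "gcTarget must be in (0, 1)")
  if (any(object@transcriptionWeight < 0))
    msgs <- c(msgs, "transcription weights must be >= 0")
  if (object@incompleteFraction < 0 || object@incompleteFraction > 1)
    msgs <- c(msgs, "incompleteFraction must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Create a repeat family spec
#'
#' @param name,classLabel,lineage,copyNumber,unitLength,gcTarget See
#'   \linkS4class{RepeatFamilySpec}.
#' @param perCopyDivergence,indelRate,structure,incompleteFraction See
#'   \linkS4class{RepeatFamilySpec}.
#' @param transcriptionWeight Named numeric with entries \code{polyA} and
#'   \code{ribodepleted}; missing entries default to 0.
#' @param copyFactor,separateContig See \linkS4class{RepeatFamilySpec}.
#' @return A \linkS4class{RepeatFamilySpec}.
#' @examples
#' repeatFamilySpec("tekay1", "Ty3/gypsy", lineage = "Tekay",
#'                  copyNumber = 30, unitLength = 5000,
#'                  structure = list(ltrLength = 300, pbsTrna = "tRNA-Met",
#'                                   tsdLength = 5))
#' @export
repeatFamilySpec <- function(name, classLabel, lineage = "",
                             copyNumber = 10L, unitLength = 3000L,
                             gcTarget = 0.42, perCopyDivergence = 0.02,
                             indelRate = 0.001, structure = list(),
                             incompleteFraction = 0,
                             transcriptionWeight = c(polyA = 0,
                                                     ribodepleted = 0),
                             copyFactor = 1, separateContig = FALSE) {
  tw <- c(polyA = 0, ribodepleted = 0)
  tw[names(transcriptionWeight)] <- transcriptionWeight
  if (classLabel == "satellite" && length(structure)) {
    ml <- structure$monomerLength %||% NULL
    ac <- structure$arrayCopies %||% NULL
    if (!is.null(ml) && !is.null(ac)) unitLength <- ml * ac
  }
  new("RepeatFamilySpec", name = name, classLabel = classLabel,
      lineage = lineage, copyNumber = as.integer(copyNumber),
      unitLength = as.integer(unitLength), gcTarget = gcTarget,
      perCopyDivergence = perCopyDivergence, indelRate = indelRate,
      structure = structure, incompleteFraction = incompleteFraction,
      transcriptionWeight = tw, copyFactor = copyFactor,
      separateContig = separateContig)
}

setMethod("show", "RepeatFamilySpec", function(object) {
  cat("RepeatFamilySpec '", object@name, "' (", object@classLabel,
      if (nzchar(object@lineage)) paste0(":", object@lineage), ")\n",
      "  ", object@copyNumber, " copies x ", object@unitLength,
      " bp, GC ", object@gcTarget, ", divergence ",
      object@perCopyDivergence, "\n", sep = "")
})

# one fixed codon per amino acid, used to embed peptide motifs in masters
.AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

encodePeptide <- function(pep) {
  paste(.AA_CODON[strsplit(pep, "", fixed = TRUE)[[1]]], collapse = "")
}

#' Build the master sequence of a repeat family
#'
#' Constructs the family master of length \code{unitLength} with base
#' composition matching \code{gcTarget} (exact-count sampling in the random
#' segments compensates for the fixed motif segments). For LTR families the
#' two LTRs are initially identical, the PBS (reverse complement of the
#' chosen tRNA 3' 18-mer) sits immediately internal to the 5' LTR, and the
#' protein-domain motifs are embedded in the superfamily's canonical order.
#' Satellites are exact tandem arrays of one random monomer; DNA
#' transposons carry terminal inverted repeats.
#'
#' @param spec A \linkS4class{RepeatFamilySpec}.
#' @return List with \code{seq} (character master sequence) and
#'   \code{features} (0-based half-open feature data.frame relative to the
#'   master: LTRs, PBS, domains).
#' @export
buildFamilyMaster <- function(spec) {
  n <- spec@unitLength
  gcN <- round(spec@gcTarget * n)
  feat <- data.frame(seq_id = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     kind = character(0), name = character(0),
                     stringsAsFactors = FALSE)
  addFeat <- function(start, end, kind, name = "") {
    rbind(feat, data.frame(seq_id = "master", start = start, end = end,
                           strand = "+", kind = kind, name = name,
                           stringsAsFactors = FALSE))
  }
  cls <- spec@classLabel
  st <- spec@structure

  if (cls %in% c("Ty1/copia", "Ty3/gypsy") && !is.null(st$ltrLength)) {
    L <- st$ltrLength
    trna <- st$pbsTrna %||% "tRNA-Met"
    pbs <- rcStrings(.TRNA_18MERS[[trna]])
    motifs <- .DOMAIN_MOTIFS[.DOMAIN_MOTIFS$lineage == spec@lineage, ]
    if (nrow(motifs) == 0)  # lineage without bundled motifs: borrow layout
      motifs <- .DOMAIN_MOTIFS[.DOMAIN_MOTIFS$lineage == "Tekay", ]
    ord <- domainOrder(cls)
    motifs <- motifs[match(ord, motifs$domain), ]
    cds <- vapply(motifs$peptide, encodePeptide, "")
    fixedLen <- 2L * L + nchar(pbs) + sum(nchar(cds))
    nSpacer <- length(cds) + 1L   # after PBS, between domains, before 3' LTR
    spacerTotal <- n - fixedLen
    if (spacerTotal < nSpacer * 10L)
      stop("structure lengths exceed unitLength for family ", spec@name)
    spl <- rep(spacerTotal %/% nSpacer, nSpacer)
    spl[1] <- spl[1] + spacerTotal %% nSpacer
    # composition compensation: random parts carry the remaining GC
    fixedGC <- sum(.rs_base_counts(c(pbs, cds))[c("G", "C")])
    gcRemain <- gcN - fixedGC
    ltrGC <- round(gcRemain * L / (2 * L + sum(spl)))
    ltr <- randomSeqExactGC(L, ltrGC)
    # canonical LTR boundary motif: retroviral-style TG...CA
    substr(ltr, 1L, 2L) <- "TG"
    substr(ltr, L - 1L, L) <- "CA"
    gcSpacer <- gcRemain - 2 * sum(.rs_base_counts(ltr)[c("G", "C")])
    spacers <- character(nSpacer)
    left <- gcSpacer
    for (i in seq_len(nSpacer)) {
      want <- round(gcSpacer * spl[i] / sum(spl))
      if (i == nSpacer) want <- left
      want <- max(0L, min(spl[i], want))
      spacers[i] <- randomSeqExactGC(spl[i], want)
      left <- left - sum(.rs_base_counts(spacers[i])[c("G", "C")])
    }
    pieces <- c(ltr, pbs, spacers[1])
    pos <- L + nchar(pbs) + spl[1]
    feat <- addFeat(0L, L, "LTR", "LTR5")
    feat <- addFeat(L, L + nchar(pbs), "PBS", trna)
    for (i in seq_along(cds)) {
      feat <- addFeat(pos, pos + nchar(cds[i]), "domain", motifs$domain[i])
      pieces <- c(pieces, cds[i], spacers[i + 1L])
      pos <- pos + nchar(cds[i]) + spl[i + 1L]
    }
    pieces <- c(pieces, ltr)
    feat <- addFeat(pos, pos + L, "LTR", "LTR3")
    seqs <- paste(pieces, collapse = "")
  } else if (cls == "satellite") {
    ml <- st$monomerLength %||% 150L
    ac <- st$arrayCopies %||% max(1L, n %/% ml)
    monomer <- randomSeqExactGC(ml, spec@gcTarget * ml)
    seqs <- strrep(monomer, ac)
    feat <- addFeat(0L, nchar(seqs), "satellite_array", spec@name)
  } else if (cls == "DNA_transposon" && !is.null(st$tirLength)) {
    tl <- st$tirLength
    if (2L * tl >= n)
      stop("structure lengths exceed unitLength for family ", spec@name)
    tir <- randomSeqExactGC(tl, spec@gcTarget * tl)
    mid <- randomSeqExactGC(n - 2L * tl, spec@gcTarget * (n - 2L * tl))
    seqs <- paste0(tir, mid, rcStrings(tir))
    feat <- addFeat(0L, tl, "TIR", "TIR5")
    feat <- addFeat(n - tl, n, "TIR", "TIR3")
  } else {
    seqs <- randomSeqExactGC(n, gcN)
  }
  list(seq = seqs, features = feat)
}
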