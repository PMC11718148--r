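# Default study conditions: a Table-1-like mix of repeat families with
# lineage labels, GC contrasts, a divergence gradient, structural
# incompleteness and library-specific transcription weights, plus an
# over-represented plastid-like contig and an rDNA family.

#' Default planted family set
#'
#' A realistic desk-scale mix: three Ty3/gypsy and two Ty1/copia lineages
#' with LTR/PBS/TSD structure (some copies incomplete), a CACTA-like DNA
#' transposon, a LINE, a satellite, a 45S-like rDNA family and a
#' plastid-like organellar contig. Copy numbers and unit lengths give
#' per-family genome proportions between about 0.5\% and 2\%; per-copy
#' divergences between 0.005 and 0.035 span young to middle-aged
#' families; transcription weights make poly-A libraries
#' retroelement-poor and ribo-depleted libraries GP-coupled.
#'
#' @param scale Multiplier on copy numbers (default 1) to shrink or grow
#'   the whole genome proportionally.
#' @return List of \linkS4class{RepeatFamilySpec}.
#' @export
defaultFamilies <- function(scale = 1) {
  n <- function(x) max(2L, as.integer(round(x * scale)))
  list(
    repeatFamilySpec("gypsy_tekay", "Ty3/gypsy", "Tekay",
                     copyNumber = n(60), unitLength = 6000L,
                     gcTarget = 0.47, perCopyDivergence = 0.015,
                     indelRate = 0.001,
                     structure = list(ltrLength = 400L,
                                      pbsTrna = "tRNA-Met",
                                      tsdLength = 5L),
                     incompleteFraction = 0.3,
                     transcriptionWeight = c(polyA = 0.0015,
                                             ribodepleted = 0.001)),
    repeatFamilySpec("gypsy_retand", "Ty3/gypsy", "Retand",
                     copyNumber = n(50), unitLength = 5000L,
                     gcTarget = 0.44, perCopyDivergence = 0.03,
                     indelRate = 0.001,
                     structure = list(ltrLength = 350L,
                                      pbsTrna = "tRNA-Lys",
                                      tsdLength = 4L),
                     incompleteFraction = 0.4,
                     transcriptionWeight = c(polyA = 0.0005,
                                             ribodepleted = 0.001)),
    repeatFamilySpec("gypsy_crm", "Ty3/gypsy", "CRM",
                     copyNumber = n(35), unitLength = 4500L,
                     gcTarget = 0.40, perCopyDivergence = 0.02,
                     indelRate = 0.001,
                     structure = list(ltrLength = 300L,
                                      pbsTrna = "tRNA-Trp",
                                      tsdLength = 5L),
                     incompleteFraction = 0.3,
                     transcriptionWeight = c(polyA = 0.0003,
                                             ribodepleted = 0.0008)),
    repeatFamilySpec("copia_angela", "Ty1/copia", "Angela",
                     copyNumber = n(55), unitLength = 5500L,
                     gcTarget = 0.45, perCopyDivergence = 0.01,
                     indelRate = 0.001,
                     structure = list(ltrLength = 350L,
                                      pbsTrna = "tRNA-Gly",
                                      tsdLength = 5L),
                     incompleteFraction = 0.25,
                     transcriptionWeight = c(polyA = 0.002,
                                             ribodepleted = 0.0012)),
    repeatFamilySpec("copia_sire", "Ty1/copia", "SIRE",
                     copyNumber = n(40), unitLength = 4500L,
                     gcTarget = 0.41, perCopyDivergence = 0.035,
                     indelRate = 0.001,
                     structure = list(ltrLength = 300L,
                                      pbsTrna = "tRNA-Ile",
                                      tsdLength = 4L),
                     incompleteFraction = 0.4,
                     transcriptionWeight = c(polyA = 0.0008,
                                             ribodepleted = 0.0008)),
    repeatFamilySpec("dta_cacta", "DNA_transposon", "CACTA",
                     copyNumber = n(55), unitLength = 3200L,
                     gcTarget = 0.40, perCopyDivergence = 0.02,
                     indelRate = 0.001,
                     structure = list(tirLength = 25L),
                     transcriptionWeight = c(polyA = 0.001,
                                             ribodepleted = 0.0008)),
    repeatFamilySpec("line_l1", "LINE", "L1",
                     copyNumber = n(45), unitLength = 3800L,
                     gcTarget = 0.43, perCopyDivergence = 0.025,
                     indelRate = 0.001,
                     transcriptionWeight = c(polyA = 0.0004,
                                             ribodepleted = 0.0005)),
    repeatFamilySpec("sat_1", "satellite", "",
                     copyNumber = n(55), gcTarget = 0.48,
                     perCopyDivergence = 0.02, indelRate = 0.001,
                     structure = list(monomerLength = 160L,
                                      arrayCopies = 20L),
                     transcriptionWeight = c(polyA = 0,
                                             ribodepleted = 0.0002)),
    repeatFamilySpec("unknown_1", "unknown", "",
                     copyNumber = n(40), unitLength = 3000L,
                     gcTarget = 0.44, perCopyDivergence = 0.02,
                     indelRate = 0.001,
                     transcriptionWeight = c(polyA = 0.0008,
                                             ribodepleted = 0.0008)),
    repeatFamilySpec("rdna_45s", "rDNA", "45S",
                     copyNumber = n(30), unitLength = 6000L,
                     gcTarget = 0.55, perCopyDivergence = 0.004,
                     indelRate = 0.0005),
    repeatFamilySpec("plastid", "organelle", "",
                     copyNumber = 1L, unitLength = 30000L,
                     gcTarget = 0.37, perCopyDivergence = 0,
                     indelRate = 0, copyFactor = 40,
                     separateContig = TRUE,
                     transcriptionWeight = c(polyA = 0.0005,
                                             ribodepleted = 0.004))
  )
}

#' Build the annotation reference library from a synthetic run
#'
#' Assembles the labelled reference set used to annotate clusters: the
#' planted family masters (repeat exemplars), the organellar contig and
#' the rDNA master flagged accordingly, and the tRNA fixtures. This plays
#' the role an external repeat/organelle/rDNA database plays on real
#' data.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @return List with \code{seqs} (named \code{DNAStringSet}) and
#'   \code{info} (data.frame: id, classLabel, lineage, flag).
#' @export
referenceLibrary <- function(manifest) {
  masters <- manifest@params$masters
  fam <- manifest@families
  seqs <- character(0)
  info <- list()
  for (i in seq_len(nrow(fam))) {
    nm <- fam$name[i]
    seqs[[nm]] <- masters[[nm]]$seq
    flag <- if (fam$separateContig[i]) "organelle"
      else if (fam$classLabel[i] == "rDNA") "rDNA"
      else "none"
    info[[length(info) + 1L]] <- data.frame(
      id = nm, classLabel = fam$classLabel[i], lineage = fam$lineage[i],
      flag = flag, stringsAsFactors = FALSE)
  }
  list(seqs = Biostrings::DNAStringSet(seqs),
       info = do.call(rbind, info))
}
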