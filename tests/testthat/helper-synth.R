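# shared fixture builders; everything is generated in code, nothing on disk

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutated <- function(s, subRate, indelRate = 0) {
  retroscribe:::mutateSeq(s, subRate, indelRate)
}

revComp <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAStringSet(s)))

# tiling error-free reads over a template (forward strand), fixed step
tilingReads <- function(template, readLen = 151L, step = 50L) {
  n <- nchar(template)
  starts <- seq(1L, n - readLen + 1L, by = step)
  out <- Biostrings::DNAStringSet(substring(template, starts,
                                            starts + readLen - 1L))
  names(out) <- paste0("t", seq_along(starts))
  out
}

# reads sampled uniformly from mutated copies of one master
familyReads <- function(master, nCopies, divergence, nReads,
                        readLen = 151L, prefix = "r") {
  copies <- vapply(seq_len(nCopies), function(i)
    mutated(master, divergence, 0.001), "")
  cp <- sample.int(nCopies, nReads, replace = TRUE)
  st <- vapply(cp, function(i)
    sample.int(nchar(copies[i]) - readLen + 1L, 1L), 1L)
  out <- Biostrings::DNAStringSet(substring(copies[cp], st,
                                            st + readLen - 1L))
  names(out) <- paste0(prefix, seq_len(nReads))
  attr(out, "copies") <- copies
  out
}

# independent oracle for local alignment: Biostrings with the package's
# scoring (match +1, mismatch -1, gap of length L costs 1 + L)
bsLocalScore <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  max(Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = mat,
        gapOpening = 1, gapExtension = 1)),
      Biostrings::score(Biostrings::pairwiseAlignment(
        a, revComp(b), type = "local", substitutionMatrix = mat,
        gapOpening = 1, gapExtension = 1)))
}

bsGlobalIdentity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)
  100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# a small planted genome shared by several test files (built once)
.fixtureEnv <- new.env(parent = emptyenv())

smallManifest <- function() {
  if (is.null(.fixtureEnv$manifest)) {
    set.seed(101)
    fams <- list(
      repeatFamilySpec("famA_tekay", "Ty3/gypsy", "Tekay",
                       copyNumber = 12L, unitLength = 3000L,
                       gcTarget = 0.47, perCopyDivergence = 0.01,
                       indelRate = 0.001,
                       structure = list(ltrLength = 250L,
                                        pbsTrna = "tRNA-Met",
                                        tsdLength = 5L),
                       incompleteFraction = 0.25,
                       transcriptionWeight = c(polyA = 0.004,
                                               ribodepleted = 0.002)),
      repeatFamilySpec("famB_angela", "Ty1/copia", "Angela",
                       copyNumber = 10L, unitLength = 2500L,
                       gcTarget = 0.42, perCopyDivergence = 0.03,
                       indelRate = 0.001,
                       structure = list(ltrLength = 200L,
                                        pbsTrna = "tRNA-Gly",
                                        tsdLength = 4L),
                       transcriptionWeight = c(polyA = 0.002,
                                               ribodepleted = 0.002)),
      repeatFamilySpec("famC_sat", "satellite", "",
                       copyNumber = 10L,
                       structure = list(monomerLength = 150L,
                                        arrayCopies = 8L),
                       gcTarget = 0.48, perCopyDivergence = 0.01),
      repeatFamilySpec("famD_rdna", "rDNA", "45S",
                       copyNumber = 6L, unitLength = 2000L,
                       gcTarget = 0.55, perCopyDivergence = 0.005),
      repeatFamilySpec("plastid", "organelle", "",
                       copyNumber = 1L, unitLength = 8000L,
                       gcTarget = 0.37, copyFactor = 15,
                       separateContig = TRUE,
                       transcriptionWeight = c(ribodepleted = 0.003))
    )
    .fixtureEnv$manifest <- plantGenome(fams, 2.5e5, geneCount = 10L)
  }
  .fixtureEnv$manifest
}
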