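#' @useDynLib retroscribe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats aov TukeyHSD lm coef pf runif rnorm rbinom rmultinom
#'   setNames quantile median na.omit var p.adjust
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

# reverse complement on plain character vectors (C++ backed)
rcStrings <- function(x) .rs_revcomp(x)

# draw a random DNA string of length n with an exact G+C count.
# gcCount is clamped to [0, n]; A/T and G/C are split as evenly as possible
# and the residue assigned at random so composition is exact, order random.
randomSeqExactGC <- function(n, gcCount) {
  if (n <= 0L) return("")
  gcCount <- max(0L, min(as.integer(n), as.integer(round(gcCount))))
  at <- n - gcCount
  g <- gcCount %/% 2L; cc <- gcCount - g
  if (gcCount %% 2L == 1L && runif(1) < 0.5) { g <- g + 1L; cc <- cc - 1L }
  a <- at %/% 2L; t <- at - a
  if (at %% 2L == 1L && runif(1) < 0.5) { a <- a + 1L; t <- t - 1L }
  paste(sample(c(rep("A", a), rep("T", t), rep("G", g), rep("C", cc))),
        collapse = "")
}

# apply substitutions (rate per base) and indels (rate per base) to a
# sequence; substitutions draw a different base uniformly
mutateSeq <- function(seq, subRate = 0, indelRate = 0) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n == 0L) return(seq)
  if (subRate > 0) {
    hit <- which(runif(n) < subRate)
    for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
  }
  if (indelRate > 0) {
    hit <- which(runif(length(v)) < indelRate)
    if (length(hit)) {
      vl <- as.list(v)
      for (i in hit) {
        if (runif(1) < 0.5) vl[[i]] <- character(0)                 # deletion
        else vl[[i]] <- c(v[i], sample(bases, 1L))                  # insertion
      }
      v <- unlist(vl, use.names = FALSE)
    }
  }
  paste(v, collapse = "")
}

# seeded substring error process for simulated reads (substitutions only)
addReadErrors <- function(seqs, errorRate) {
  if (errorRate <= 0) return(seqs)
  vapply(seqs, function(s) mutateSeq(s, subRate = errorRate), "",
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# short stable checksum of an R object (used to stamp outputs)
objectDigest <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}
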