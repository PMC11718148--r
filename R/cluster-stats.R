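#' Pairwise similarity scores within a cluster
#'
#' One score per unordered read pair: the percent identity of the best
#' local alignment (better of the two orientations) whose span covers at
#' least \code{coverageThreshold} of the shorter read. Self-hits are never
#' scored and reciprocal duplicates are collapsed by construction (each
#' unordered pair is scored once). Scores below the floor are omitted.
#'
#' @param reads \code{DNAStringSet} of the cluster's reads (>= 2).
#' @param floor Percent similarity floor (default 80).
#' @param coverageThreshold Minimum aligned fraction of the shorter read
#'   for a pair to be scored (default 0.55, the clustering criterion).
#' @param maxReads When the cluster exceeds this many reads, a uniform
#'   random subsample of this size is scored (default 2000).
#' @param exact Full dynamic programming over both orientations; when
#'   FALSE, alignments are banded around shared-13-mer diagonals (used
#'   automatically above 150 reads).
#' @return Numeric vector of percent scores (possibly empty), with the
#'   number of scored pairs as attribute \code{"n_pairs_scored"}.
#' @export
similarityScores <- function(reads, floor = 80, coverageThreshold = 0.55,
                             maxReads = 2000L, exact = NULL) {
  if (length(reads) < 2L) stop("need >= 2 reads to score pairs")
  if (length(reads) > maxReads)
    reads <- reads[sort(sample.int(length(reads), maxReads))]
  if (is.null(exact)) exact <- length(reads) <= 150L
  sc <- .rs_pairwise_scores(as.character(reads), coverageThreshold,
                            exact, 13L, 25L)
  out <- sc$identity[sc$identity + 1e-9 >= floor]
  attr(out, "n_pairs_scored") <- nrow(sc)
  out
}

#' Modal similarity score
#'
#' Scores are binned into integer-width bins starting at the floor
#' ([80, 81), [81, 82), ...); the mode is the left edge of the most
#' populated bin, ties broken toward the higher bin. An empty score set
#' yields \code{NA} (undefined), never zero.
#'
#' @param scores Numeric percent scores (e.g. from
#'   \code{\link{similarityScores}}).
#' @param floor Percent floor (default 80); scores below it are dropped.
#' @param binWidth Bin width in percent (default 1).
#' @return The modal bin's left edge (percent), or \code{NA_real_}.
#' @examples
#' modalSimilarity(c(92.4, 92.7, 93.1, 85.0, 79.0))  # 92
#' @export
modalSimilarity <- function(scores, floor = 80, binWidth = 1) {
  scores <- scores[!is.na(scores) & scores + 1e-9 >= floor]
  if (!length(scores)) return(NA_real_)
  bin <- floor + binWidth * floor((scores - floor) / binWidth)
  tab <- table(bin)
  best <- max(as.integer(tab))
  cand <- as.numeric(names(tab)[as.integer(tab) == best])
  max(cand)  # tie toward the higher bin
}

#' Pooled GC content of a set of reads
#'
#' 100 x (G + C) / (A + C + G + T), pooled over all reads (not averaged
#' per read); N and other ambiguity codes are excluded from numerator and
#' denominator. All-N input yields \code{NA}.
#'
#' @param reads \code{DNAStringSet} or character vector.
#' @return Percent GC (scalar).
#' @examples
#' gcContent(c("ATGC", "AT"))  # 33.33
#' @export
gcContent <- function(reads) {
  bc <- .rs_base_counts(as.character(reads))
  denom <- sum(bc[c("A", "C", "G", "T")])
  if (denom == 0L) return(NA_real_)
  100 * sum(bc[c("G", "C")]) / denom
}

#' Per-cluster similarity and GC statistics
#'
#' Computes, for every cluster in the set, the modal pairwise similarity
#' score (mode of per-pair identities at or above the floor) and the
#' pooled GC content of the member reads.
#'
#' @param cset A \linkS4class{RepeatClusterSet} (typically top clusters,
#'   annotated and with GP).
#' @param floor Similarity floor (default 80).
#' @param coverageThreshold Pair-scoring coverage rule (default 0.55).
#' @param maxReadsPerCluster Subsample cap for pair scoring (default
#'   2000).
#' @return The cluster set with \code{modal_similarity},
#'   \code{gc_percent} and \code{n_pairs_scored} columns added.
#' @export
clusterStats <- function(cset, floor = 80, coverageThreshold = 0.55,
                         maxReadsPerCluster = 2000L) {
  cl <- cset@clusters
  cl$modal_similarity <- NA_real_
  cl$gc_percent <- NA_real_
  cl$n_pairs_scored <- 0L
  for (i in seq_len(nrow(cl))) {
    rr <- cset@reads[which(cset@membership == i)]
    cl$gc_percent[i] <- gcContent(rr)
    if (length(rr) >= 2L) {
      sc <- similarityScores(rr, floor, coverageThreshold,
                             maxReadsPerCluster)
      cl$n_pairs_scored[i] <- attr(sc, "n_pairs_scored")
      cl$modal_similarity[i] <- modalSimilarity(sc, floor)
    }
  }
  cset@clusters <- cl
  cset
}

#' Aggregate cluster statistics by lineage and class
#'
#' Builds the lineage/superfamily summary: per lineage the summed GP, the
#' min-max range of modal similarity scores, the min-max GC range and the
#' cluster count; per class (superfamily) the same with class GP equal to
#' the sum of its lineage GPs; plus total rows with and without rDNA
#' clusters. Organelle-flagged clusters are omitted. Lineages with no
#' clusters are omitted.
#'
#' @param clusterDf Cluster table with columns \code{classLabel},
#'   \code{lineage}, \code{flag}, \code{gp}, \code{modal_similarity},
#'   \code{gc_percent} (as produced by \code{\link{clusterStats}} after
#'   \code{\link{annotateClusters}} and \code{\link{genomeProportion}}).
#' @return data.frame: level (\code{class}/\code{lineage}/\code{total}),
#'   classLabel, lineage, gp, sim_min, sim_max, gc_min, gc_max,
#'   n_clusters.
#' @export
aggregateLineage <- function(clusterDf) {
  df <- clusterDf[!(clusterDf$flag %in% "organelle"), , drop = FALSE]
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(NA_real_, NA_real_) else range(x)
  }
  rows <- list()
  addRow <- function(level, classLabel, lineage, sub) {
    r <- data.frame(level = level, classLabel = classLabel,
                    lineage = lineage, gp = sum(sub$gp, na.rm = TRUE),
                    sim_min = rng(sub$modal_similarity)[1],
                    sim_max = rng(sub$modal_similarity)[2],
                    gc_min = rng(sub$gc_percent)[1],
                    gc_max = rng(sub$gc_percent)[2],
                    n_clusters = nrow(sub), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- r
  }
  for (cls in unique(df$classLabel)) {
    sub <- df[df$classLabel == cls, , drop = FALSE]
    addRow("class", cls, "", sub)
    for (lin in unique(sub$lineage[nzchar(sub$lineage)]))
      addRow("lineage", cls, lin,
             sub[sub$lineage == lin, , drop = FALSE])
  }
  isRdna <- df$flag %in% "rDNA" | df$classLabel == "rDNA"
  addRow("total", "Total (excl. rDNA)", "", df[!isRdna, , drop = FALSE])
  addRow("total", "Total repeats", "", df)
  do.call(rbind, rows)
}
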