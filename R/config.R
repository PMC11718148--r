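#' Run configuration
#'
#' Holds the thresholds that define the analysis: the read-clustering and
#' RNA-mapping similarity criterion (percent identity over a fraction of the
#' read length), the top-cluster size rule, the similarity floor for modal
#' scores, the minimum mapped reads for an element to count as expressed,
#' and the global RNG seed that drives every stochastic stage.
#'
#' @slot identityThreshold Percent identity for clustering/mapping (default
#'   90).
#' @slot coverageThreshold Fraction of the (shorter) read an alignment must
#'   span (default 0.55).
#' @slot topClusterMinReads Minimum cluster size to be a "top cluster"
#'   (default 151, i.e. strictly more than 150 reads).
#' @slot similarityFloor Percent floor for pairwise scores entering the
#'   modal similarity statistic (default 80).
#' @slot expressedElementMinReads Minimum mapped reads for the expressed
#'   element report (default 100).
#' @slot seed Integer RNG seed recorded in every output.
#' @slot extra Named list of free-form settings (paths, library tags).
#' @export
setClass("RunConfig", representation(
  identityThreshold = "numeric",
  coverageThreshold = "numeric",
  topClusterMinReads = "integer",
  similarityFloor = "numeric",
  expressedElementMinReads = "integer",
  seed = "integer",
  extra = "list"
))

setValidity("RunConfig", function(object) {
  msgs <- character(0)
  if (!(object@identityThreshold > 0 && object@identityThreshold <= 100))
    msgs <- c(msgs, "identityThreshold must be in (0, 100]")
  if (!(object@coverageThreshold > 0 && object@coverageThreshold <= 1))
    msgs <- c(msgs, "coverageThreshold must be in (0, 1]")
  if (!(object@similarityFloor > 0 && object@similarityFloor <= 100))
    msgs <- c(msgs, "similarityFloor must be in (0, 100]")
  if (object@topClusterMinReads < 1L)
    msgs <- c(msgs, "topClusterMinReads must be >= 1")
  if (object@expressedElementMinReads < 0L)
    msgs <- c(msgs, "expressedElementMinReads must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' Create a run configuration
#'
#' Defaults are the analysis' citable settings: reads cluster (and RNA reads
#' map) when at least 90\% similar over at least 55\% of the read length;
#' repeat "top clusters" have more than 150 reads; pairwise similarity
#' scores below 80\% are excluded from the modal statistic; elements need at
#' least 100 mapped reads to enter the expressed-element report.
#'
#' @param identityThreshold,coverageThreshold,topClusterMinReads,similarityFloor,expressedElementMinReads
#'   See slot documentation in \linkS4class{RunConfig}.
#' @param seed Integer RNG seed.
#' @param ... Further settings stored in \code{extra}.
#' @return A \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig(seed = 1)
#' configHash(cfg)
#' @export
runConfig <- function(identityThreshold = 90, coverageThreshold = 0.55,
                      topClusterMinReads = 151L, similarityFloor = 80,
                      expressedElementMinReads = 100L, seed = 1L, ...) {
  new("RunConfig",
      identityThreshold = as.numeric(identityThreshold),
      coverageThreshold = as.numeric(coverageThreshold),
      topClusterMinReads = as.integer(topClusterMinReads),
      similarityFloor = as.numeric(similarityFloor),
      expressedElementMinReads = as.integer(expressedElementMinReads),
      seed = as.integer(seed),
      extra = list(...))
}

#' Stable hash of a run configuration
#'
#' @param config A \linkS4class{RunConfig}.
#' @return Character md5 digest of the configuration values.
#' @export
configHash <- function(config) {
  objectDigest(list(config@identityThreshold, config@coverageThreshold,
                    config@topClusterMinReads, config@similarityFloor,
                    config@expressedElementMinReads, config@seed,
                    config@extra))
}

#' Provenance metadata lines for output tables
#'
#' @param config A \linkS4class{RunConfig}.
#' @return Named character vector suitable for
#'   \code{\link{writeResultTable}}.
#' @export
configMeta <- function(config) {
  c(config_hash = configHash(config),
    seed = as.character(config@seed),
    identity_threshold = as.character(config@identityThreshold),
    coverage_threshold = as.character(config@coverageThreshold))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n",
      "  identity >= ", object@identityThreshold, "% over >= ",
      object@coverageThreshold * 100, "% of read\n",
      "  top cluster: > ", object@topClusterMinReads - 1L, " reads\n",
      "  similarity floor: ", object@similarityFloor, "%\n",
      "  expressed element: >= ", object@expressedElementMinReads,
      " mapped reads\n",
      "  seed: ", object@seed, "\n", sep = "")
})
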