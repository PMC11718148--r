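#' A set of repeat read clusters
#'
#' Clusters are connected components of the pairwise-similarity read graph
#' under the identity/coverage criterion. Cluster ids \code{CL1, CL2, ...}
#' are assigned by descending read count (ties broken by the first-seen
#' member read). Reads with no passing pair are "unclustered" singletons.
#'
#' @slot reads The clustered \code{DNAStringSet}.
#' @slot membership Integer cluster index per read (NA for unclustered),
#'   parallel to \code{reads}.
#' @slot clusters data.frame with \code{cluster_id} and \code{size}, plus
#'   annotation and GP columns once filled in.
#' @slot contigs \code{DNAStringSet} of consensus contigs (ids
#'   \code{CLn_contigm}), possibly empty.
#' @export
setClass("RepeatClusterSet", representation(
  reads = "DNAStringSet", membership = "integer", clusters = "data.frame",
  contigs = "DNAStringSet"
))

setValidity("RepeatClusterSet", function(object) {
  if (length(object@membership) != length(object@reads))
    return("membership must be parallel to reads")
  ok <- stats::na.omit(object@membership)
  if (length(ok) && nrow(object@clusters) &&
      max(ok) > nrow(object@clusters))
    return("membership index out of range")
  TRUE
})

setMethod("show", "RepeatClusterSet", function(object) {
  cat("RepeatClusterSet:", nrow(object@clusters), "clusters over",
      sum(!is.na(object@membership)), "reads (",
      sum(is.na(object@membership)), "unclustered )\n")
  if (nrow(object@clusters))
    print(head(object@clusters, 5))
})

#' Accessors for RepeatClusterSet
#' @param x A \linkS4class{RepeatClusterSet}.
#' @param clusterId A cluster id such as \code{"CL1"}.
#' @return \code{clusterTable}: the per-cluster data.frame;
#'   \code{clusterMembers}: the member read ids of one cluster;
#'   \code{clusterReadSeqs}: their sequences; \code{unclusteredReads}: ids
#'   of singleton reads; \code{clusterContigs}: consensus contigs.
#' @export
clusterTable <- function(x) x@clusters
#' @rdname clusterTable
#' @export
clusterMembers <- function(x, clusterId) {
  idx <- match(clusterId, x@clusters$cluster_id)
  if (is.na(idx)) stop("no such cluster: ", clusterId)
  names(x@reads)[which(x@membership == idx)]
}
#' @rdname clusterTable
#' @export
clusterReadSeqs <- function(x, clusterId) {
  idx <- match(clusterId, x@clusters$cluster_id)
  if (is.na(idx)) stop("no such cluster: ", clusterId)
  x@reads[which(x@membership == idx)]
}
#' @rdname clusterTable
#' @export
unclusteredReads <- function(x) names(x@reads)[is.na(x@membership)]
#' @rdname clusterTable
#' @export
clusterContigs <- function(x) x@contigs

#' All-vs-all pairwise read hits under the clustering criterion
#'
#' Every unordered read pair is aligned in both orientations (exact local
#' dynamic programming: match +1, mismatch -1, gap open -2, gap extend -1)
#' and the better orientation reported if it passes both the identity and
#' the coverage threshold. Coverage is measured on the shorter read.
#' Exactly one hit per unordered pair, with the lexicographically smaller
#' id as query; self-hits are never emitted.
#'
#' @param reads A named \code{DNAStringSet} (at least 2 reads).
#' @param identityThreshold Percent identity (default 90).
#' @param coverageThreshold Fraction of the shorter read (default 0.55).
#' @param prefilter Require a shared 13-mer before aligning (near-lossless
#'   speedup at these thresholds; default FALSE = fully exact).
#' @return data.frame: query_id, subject_id, identity, coverage,
#'   orientation (\code{"forward"}/\code{"reverse-complement"}), score.
#' @export
pairwiseHits <- function(reads, identityThreshold = 90,
                         coverageThreshold = 0.55, prefilter = FALSE) {
  if (length(reads) < 2L) stop("need at least 2 reads")
  ids <- names(reads)
  h <- .rs_pairwise_hits(as.character(reads), identityThreshold,
                         coverageThreshold, prefilter, 13L)
  if (!nrow(h))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      orientation = character(0), score = numeric(0)))
  q <- ids[h$query]; s <- ids[h$subject]
  swap <- q > s
  tmp <- q[swap]; q[swap] <- s[swap]; s[swap] <- tmp
  data.frame(query_id = q, subject_id = s, identity = h$identity,
             coverage = h$coverage,
             orientation = ifelse(h$orientation == 1, "forward",
                                  "reverse-complement"),
             score = h$score, stringsAsFactors = FALSE)
}

# order components into CL ids: size desc, ties by first-seen member index
.componentsToClusterSet <- function(reads, comp) {
  tab <- table(comp)
  sizes <- as.integer(tab)
  labels <- as.integer(names(tab))
  firstSeen <- as.integer(tapply(seq_along(comp), comp, min))
  keep <- sizes >= 2L
  ordr <- order(-sizes[keep], firstSeen[keep])
  compIds <- labels[keep][ordr]
  membership <- match(comp, compIds)
  clusters <- data.frame(
    cluster_id = sprintf("CL%d", seq_along(compIds)),
    size = sizes[keep][ordr], stringsAsFactors = FALSE)
  new("RepeatClusterSet", reads = reads, membership = membership,
      clusters = clusters, contigs = Biostrings::DNAStringSet())
}

#' Cluster genome-skim reads into repeat clusters
#'
#' Clusters are the connected components of the pairwise hit graph. The
#' scalable path proposes candidate pairs from shared 13-mers and skips
#' pairs already connected (such edges are redundant for connected
#' components, so the partition is identical to clustering the full hit
#' list); alignments are banded around the shared-seed diagonal. Set
#' \code{exact = TRUE} to force full all-vs-all dynamic programming.
#'
#' @param reads Named \code{DNAStringSet}.
#' @param identityThreshold,coverageThreshold Clustering criterion
#'   (defaults 90 / 0.55).
#' @param exact Use the exhaustive pairwise path (small inputs).
#' @return A \linkS4class{RepeatClusterSet}.
#' @export
clusterReads <- function(reads, identityThreshold = 90,
                         coverageThreshold = 0.55, exact = FALSE) {
  if (length(reads) < 2L) stop("need at least 2 reads")
  if (exact) {
    hits <- pairwiseHits(reads, identityThreshold, coverageThreshold)
    return(clusterFromHits(hits, reads))
  }
  comp <- .rs_cluster_components(as.character(reads), identityThreshold,
                                 coverageThreshold, 13L, 25L)
  .componentsToClusterSet(reads, comp)
}

#' Build clusters from a precomputed hit list
#'
#' @param hits data.frame from \code{\link{pairwiseHits}}.
#' @param reads The reads the hits were computed from.
#' @return A \linkS4class{RepeatClusterSet}.
#' @export
clusterFromHits <- function(hits, reads) {
  ids <- names(reads)
  parent <- seq_along(ids)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(hits)) {
    qi <- match(hits$query_id, ids)
    si <- match(hits$subject_id, ids)
    for (i in seq_len(nrow(hits))) {
      a <- findRoot(qi[i]); b <- findRoot(si[i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_along(ids), findRoot, 1L)
  .componentsToClusterSet(reads, comp)
}

#' Keep repeat "top clusters"
#'
#' Keeps clusters with strictly more reads than \code{minReads - 1}; the
#' default 151 implements the "more than 150 reads" rule.
#'
#' @param cset A \linkS4class{RepeatClusterSet}.
#' @param minReads Minimum cluster size kept (default 151).
#' @return A \linkS4class{RepeatClusterSet} containing only the top
#'   clusters (cluster ids are preserved).
#' @export
selectTopClusters <- function(cset, minReads = 151L) {
  keep <- which(cset@clusters$size >= minReads)
  membership <- cset@membership
  newIdx <- rep(NA_integer_, nrow(cset@clusters))
  newIdx[keep] <- seq_along(keep)
  membership <- newIdx[membership]
  cl <- cset@clusters[keep, , drop = FALSE]
  rownames(cl) <- NULL
  new("RepeatClusterSet", reads = cset@reads,
      membership = as.integer(membership), clusters = cl,
      contigs = cset@contigs)
}

#' Build consensus contigs for one cluster
#'
#' Greedy layout: the longest read seeds the contig; remaining reads whose
#' best seeded alignment against the current contig passes the clustering
#' thresholds are placed (reverse-complemented as needed) and a per-column
#' majority vote (ties resolved alphabetically) forms the consensus, which
#' can extend beyond the seed. Reads that never merge seed further contigs.
#'
#' @param reads \code{DNAStringSet} of the cluster's member reads.
#' @param identityThreshold,coverageThreshold Merge criterion (defaults
#'   90 / 0.55).
#' @param maxPasses Upper bound on placement passes per contig; passes
#'   stop as soon as no further read merges (default 100).
#' @return \code{DNAStringSet} of contigs (unnamed; caller assigns ids).
#' @export
buildConsensus <- function(reads, identityThreshold = 90,
                           coverageThreshold = 0.55, maxPasses = 100L) {
  if (!length(reads)) stop("empty cluster")
  seqs <- as.character(reads)
  remaining <- order(-nchar(seqs))
  contigs <- character(0)
  baseLv <- c("A", "C", "G", "T")

  while (length(remaining)) {
    seed <- remaining[1]
    remaining <- remaining[-1]
    placements <- list(list(offset = 0L, seq = seqs[seed]))
    contig <- seqs[seed]
    for (pass in seq_len(maxPasses)) {
      if (!length(remaining)) break
      m <- .rs_map_reads(seqs[remaining], contig, identityThreshold,
                         coverageThreshold, 13L, 8L, 30L)
      hit <- which(!is.na(m$target))
      if (!length(hit)) break
      for (i in hit) {
        lr <- nchar(seqs[remaining[i]])
        if (m$orientation[i] == 1L) {
          q <- seqs[remaining[i]]
          qStart <- m$r_start[i]
        } else {
          q <- rcStrings(seqs[remaining[i]])
          qStart <- lr - m$r_end[i]
        }
        placements[[length(placements) + 1L]] <-
          list(offset = m$t_start[i] - qStart, seq = q)
      }
      remaining <- remaining[-hit]
      # rebuild consensus from all placements
      offs <- vapply(placements, function(p) p$offset, 0L)
      lens <- vapply(placements, function(p) nchar(p$seq), 0L)
      minOff <- min(offs)
      offs <- offs - minOff
      L <- max(offs + lens)
      counts <- matrix(0L, nrow = 4L, ncol = L,
                       dimnames = list(baseLv, NULL))
      for (pi in seq_along(placements)) {
        v <- strsplit(placements[[pi]]$seq, "", fixed = TRUE)[[1]]
        idx <- offs[pi] + seq_along(v)
        okb <- v %in% baseLv
        if (any(okb))
          counts[cbind(match(v[okb], baseLv), idx[okb])] <-
            counts[cbind(match(v[okb], baseLv), idx[okb])] + 1L
      }
      cov <- colSums(counts)
      cons <- rep("N", L)
      cons[cov > 0] <- baseLv[apply(counts[, cov > 0, drop = FALSE],
                                    2L, which.max)]
      contig <- paste(cons, collapse = "")
      # placements are now relative to the rebuilt contig
      for (pi in seq_along(placements))
        placements[[pi]]$offset <- offs[pi]
    }
    contigs <- c(contigs, contig)
  }
  Biostrings::DNAStringSet(contigs)
}

#' Build and attach consensus contigs for all clusters
#'
#' @param cset A \linkS4class{RepeatClusterSet} (typically top clusters).
#' @param identityThreshold,coverageThreshold Merge criterion.
#' @param maxReadsPerCluster Reads used per cluster (uniform subsample
#'   when larger; default 400 — ample coverage for a consensus).
#' @return The cluster set with \code{contigs} filled in (ids
#'   \code{CLn_contigm}).
#' @export
buildClusterContigs <- function(cset, identityThreshold = 90,
                                coverageThreshold = 0.55,
                                maxReadsPerCluster = 400L) {
  allContigs <- Biostrings::DNAStringSet()
  for (i in seq_len(nrow(cset@clusters))) {
    idx <- which(cset@membership == i)
    if (length(idx) > maxReadsPerCluster)
      idx <- sort(sample(idx, maxReadsPerCluster))
    ct <- buildConsensus(cset@reads[idx], identityThreshold,
                         coverageThreshold)
    # report contigs longest-first, drop fragments shorter than a read
    ct <- ct[order(-Biostrings::width(ct))]
    keep <- Biostrings::width(ct) >= min(Biostrings::width(cset@reads[idx]))
    if (any(keep)) ct <- ct[keep]
    names(ct) <- paste0(cset@clusters$cluster_id[i], "_contig",
                        seq_along(ct))
    allContigs <- c(allContigs, ct)
  }
  cset@contigs <- allContigs
  cset
}

#' Annotate clusters against a labelled reference library
#'
#' Each cluster's contigs are aligned against the reference library (same
#' scoring as clustering); the cluster takes the label of the best hit
#' with identity >= 70\% over >= 100 aligned columns, else
#' \code{"unknown"}. Organelle / rDNA / tRNA reference entries take
#' precedence over repeat labels when both pass.
#'
#' @param cset A \linkS4class{RepeatClusterSet} with contigs.
#' @param refLib Reference library from \code{\link{referenceLibrary}}:
#'   list with \code{seqs} (named \code{DNAStringSet}) and \code{info}
#'   (data.frame id, classLabel, lineage, flag).
#' @param minIdentity,minColumns Annotation acceptance rule (70 / 100).
#' @return The cluster set with \code{classLabel}, \code{lineage} and
#'   \code{flag} columns added to the cluster table.
#' @export
annotateClusters <- function(cset, refLib, minIdentity = 70,
                             minColumns = 100L) {
  info <- refLib$info
  flagged <- which(info$flag %in% c("organelle", "rDNA", "tRNA"))
  plain <- setdiff(seq_len(nrow(info)), flagged)
  cl <- cset@clusters
  cl$classLabel <- "unknown"; cl$lineage <- ""; cl$flag <- "none"

  bestHit <- function(contigSeqs, subset) {
    if (!length(subset)) return(NULL)
    m <- .rs_map_reads(contigSeqs, as.character(refLib$seqs[subset]),
                       minIdentity, 0, 13L, 8L, 30L)
    m <- m[!is.na(m$target) & (m$r_end - m$r_start) >= minColumns, ,
           drop = FALSE]
    if (!nrow(m)) return(NULL)
    m[which.max(m$score), ]
  }

  for (i in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[i]
    ct <- cset@contigs[grepl(paste0("^", cid, "_"), names(cset@contigs))]
    if (!length(ct)) next
    ctSeqs <- as.character(ct)
    hf <- bestHit(ctSeqs, flagged)
    if (!is.null(hf)) {
      ref <- info[flagged[hf$target], ]
      cl$classLabel[i] <- ref$classLabel
      cl$lineage[i] <- ref$lineage
      cl$flag[i] <- ref$flag
      next
    }
    hp <- bestHit(ctSeqs, plain)
    if (!is.null(hp)) {
      ref <- info[plain[hp$target], ]
      cl$classLabel[i] <- ref$classLabel
      cl$lineage[i] <- ref$lineage
    }
  }
  cset@clusters <- cl
  cset
}

#' Genome proportion of repeat clusters
#'
#' GP of a cluster = member reads / (total reads analyzed - reads in
#' organelle-flagged clusters) x 100. The exclusion of organellar reads
#' from the denominator matches the convention used for genome-skim
#' repeat quantification; excluding a cluster can only increase the GP of
#' the others.
#'
#' @param cset An annotated \linkS4class{RepeatClusterSet} (typically top
#'   clusters).
#' @param totalReadsAnalyzed Total reads entering the analysis (clustered
#'   plus unclustered); defaults to the number of reads in \code{cset}.
#' @param exclusions Cluster flags removed from the denominator (default
#'   \code{"organelle"}).
#' @return The cluster set with a \code{gp} column; the denominator is
#'   attached as attribute \code{"denominator"} of the cluster table.
#' @export
genomeProportion <- function(cset, totalReadsAnalyzed = NULL,
                             exclusions = "organelle") {
  cl <- cset@clusters
  if (is.null(totalReadsAnalyzed))
    totalReadsAnalyzed <- length(cset@reads)
  if (totalReadsAnalyzed < sum(cl$size))
    stop("totalReadsAnalyzed smaller than the clustered read count")
  if (is.null(cl$flag)) cl$flag <- "none"
  excludedReads <- sum(cl$size[cl$flag %in% exclusions])
  denom <- totalReadsAnalyzed - excludedReads
  if (denom <= 0) stop("denominator is not positive after exclusions")
  cl$gp <- ifelse(cl$flag %in% exclusions, NA_real_,
                  100 * cl$size / denom)
  attr(cl, "denominator") <- denom
  attr(cl, "excluded_reads") <- excludedReads
  cset@clusters <- cl
  cset
}
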