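#' Canonical synthetic study conditions
#'
#' The fixed conditions used by \code{\link{runBenchmark}}: a 20 Mb
#' nuclear background carrying the default family mix (about 10\% repeat
#' content plus an over-represented plastid-like contig), 50,000 skim read
#' pairs (about 0.65x weighted genome coverage, skim-like relative to the
#' per-family copy numbers), and 200,000-read poly-A and ribo-depleted
#' libraries.
#'
#' @return Named list of generator parameters.
#' @export
studyConditions <- function() {
  list(backgroundLength = 2e7, backgroundGC = 0.42, geneCount = 120L,
       intronicLtrFraction = 0.3, familyScale = 1, skimPairs = 50000L,
       rnaReads = 200000L, readLength = 151L, errorRate = 0.002)
}

# family name of each annotated cluster via its (class, lineage) pair
.clusterFamilyMap <- function(clusterDf, refInfo) {
  key <- paste(refInfo$classLabel, refInfo$lineage)
  setNames(unname(setNames(refInfo$id, key)[
    paste(clusterDf$classLabel, clusterDf$lineage)]),
    clusterDf$cluster_id)
}

#' Ground-truth benchmark of the whole analysis
#'
#' Generates the canonical synthetic study (see
#' \code{\link{studyConditions}}), runs the full analysis against it, and
#' measures recovery against the ground-truth manifest:
#' \itemize{
#'   \item genome-proportion recovery per planted family (relative error,
#'     families at or above 0.5\% GP),
#'   \item transcript-proportion recovery per family and library
#'     (relative error, families at or above 0.05\% TP),
#'   \item modal similarity vs. the manifest's empirical pairwise
#'     identity (absolute error in points),
#'   \item completeness classification accuracy on a noise-free planted
#'     LTR genome,
#'   \item agreement of the seeded read mapper with an exhaustive
#'     dynamic-programming oracle on a small instance,
#'   \item log-log regression slope on exactly proportional data and on
#'     noisy planted slope-1 data,
#'   \item Tukey HSD family-wise type-I error over null simulations,
#'   \item byte-identity of a full pipeline rerun under one seed.
#' }
#'
#' @param seed Integer seed driving all randomness.
#' @param tukeySims Number of null simulations for the Tukey check
#'   (default 500).
#' @param outdir Directory for the rerun-determinism pipeline outputs
#'   (default a temporary directory).
#' @return List with \code{summary} (named numeric quantities) and
#'   \code{detail} (per-family tables).
#' @export
runBenchmark <- function(seed, tukeySims = 500L, outdir = tempdir()) {
  sc <- studyConditions()
  set.seed(seed)

  ## ---- skim arm: genome, clustering, GP/TP/similarity recovery ----------
  fams <- defaultFamilies(scale = sc$familyScale)
  manifest <- plantGenome(fams, sc$backgroundLength, sc$backgroundGC,
                          sc$geneCount, sc$intronicLtrFraction)
  skim <- simulateSkimReads(manifest, sc$skimPairs, sc$readLength,
                            errorRate = sc$errorRate)
  reads <- c(skim$r1, skim$r2)
  cset <- clusterReads(reads)
  top <- selectTopClusters(cset, 151L)
  top <- buildClusterContigs(top)
  refLib <- referenceLibrary(manifest)
  top <- annotateClusters(top, refLib)
  top <- genomeProportion(top, totalReadsAnalyzed = length(reads))
  top <- clusterStats(top)
  cl <- clusterTable(top)
  famMap <- .clusterFamilyMap(cl, refLib$info)

  famTab <- manifestFamilies(manifest)
  gpRows <- list()
  for (i in which(!famTab$separateContig & famTab$classLabel != "rDNA")) {
    fn <- famTab$name[i]
    cls <- names(famMap)[!is.na(famMap) & famMap == fn]
    est <- sum(cl$gp[cl$cluster_id %in% cls], na.rm = TRUE)
    modal <- if (length(cls))
      max(cl$modal_similarity[cl$cluster_id %in% cls], na.rm = TRUE)
      else NA_real_
    gpRows[[fn]] <- data.frame(
      family = fn, plantedGP = famTab$plantedGP[i], estimatedGP = est,
      gpRelError = abs(est - famTab$plantedGP[i]) / famTab$plantedGP[i],
      expectedIdentity = famTab$expectedIdentity[i],
      modalSimilarity = modal,
      simAbsError = abs(modal - famTab$expectedIdentity[i]),
      stringsAsFactors = FALSE)
  }
  gpDetail <- do.call(rbind, gpRows)
  gpEligible <- gpDetail[gpDetail$plantedGP >= 0.5, ]
  simEligible <- gpDetail[!is.na(gpDetail$expectedIdentity) &
                            !is.na(gpDetail$modalSimilarity), ]

  tpRows <- list()
  for (libType in c("polyA", "ribodepleted")) {
    rl <- simulateRnaLibrary(manifest, libType, sc$rnaReads,
                             sc$readLength, errorRate = sc$errorRate)
    contigCluster <- setNames(sub("_contig\\d+$", "", names(top@contigs)),
                              names(top@contigs))
    asg <- mapRnaReads(rl$reads, top@contigs, clusterOf = contigCluster)
    tp <- transcriptProportion(asg, cl, length(rl$reads))
    et <- rl$expectedTp
    for (i in seq_len(nrow(et))) {
      fn <- et$family[i]
      if (is.na(et$expected_tp[i])) next
      cls <- names(famMap)[!is.na(famMap) & famMap == fn]
      est <- sum(tp$clusters$tp[tp$clusters$cluster_id %in% cls],
                 na.rm = TRUE)
      tpRows[[paste(libType, fn)]] <- data.frame(
        library = libType, family = fn,
        plantedTP = et$expected_tp[i], estimatedTP = est,
        tpRelError = if (et$expected_tp[i] > 0)
          abs(est - et$expected_tp[i]) / et$expected_tp[i] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tpDetail <- do.call(rbind, tpRows)
  tpEligible <- tpDetail[!is.na(tpDetail$plantedTP) &
                           tpDetail$plantedTP >= 0.05, ]

  ## ---- structural arm: noise-free completeness --------------------------
  set.seed(seed + 101L)
  ltrFams <- list(
    repeatFamilySpec("bm_tekay", "Ty3/gypsy", "Tekay", copyNumber = 18L,
                     unitLength = 5000L, perCopyDivergence = 0,
                     indelRate = 0,
                     structure = list(ltrLength = 350L,
                                      pbsTrna = "tRNA-Met",
                                      tsdLength = 5L),
                     incompleteFraction = 0.35),
    repeatFamilySpec("bm_angela", "Ty1/copia", "Angela", copyNumber = 14L,
                     unitLength = 4200L, perCopyDivergence = 0,
                     indelRate = 0,
                     structure = list(ltrLength = 280L,
                                      pbsTrna = "tRNA-Gly",
                                      tsdLength = 4L),
                     incompleteFraction = 0.35))
  ltrMf <- plantGenome(ltrFams, 6e5, geneCount = 20L,
                       intronicLtrFraction = 0.4)
  el <- annotateLtrElements(manifestGenome(ltrMf),
                            genes = manifestGenes(ltrMf))
  cp <- manifestCopies(ltrMf)
  ovE <- suppressWarnings(GenomicRanges::findOverlaps(el, cp))
  hitQ <- S4Vectors::queryHits(ovE)
  hitS <- S4Vectors::subjectHits(ovE)
  dedup <- !duplicated(hitQ)
  matched <- hitS[dedup]
  sensitivity <- 100 * length(unique(matched)) / length(cp)
  precision <- 100 * length(unique(hitQ)) / length(el)
  agree <- (el$completeness[hitQ[dedup]] == "complete") ==
    cp$complete[matched]
  completenessAcc <- 100 * mean(agree)
  ctxAgree <- (el$context[hitQ[dedup]] == "intronic") ==
    (cp$context[matched] == "intronic")

  ## ---- mapper vs exhaustive-DP oracle on a small instance ---------------
  set.seed(seed + 202L)
  smallRl <- simulateRnaLibrary(ltrMf, "ribodepleted", 90L)
  refs <- referenceLibrary(ltrMf)$seqs
  refs <- refs[order(names(refs))]
  asgS <- mapRnaReads(smallRl$reads, refs)
  refSeqs <- as.character(refs)
  same <- logical(length(smallRl$reads))
  for (i in seq_along(smallRl$reads)) {
    rd <- as.character(smallRl$reads[[i]])
    best <- NULL
    for (t in seq_along(refSeqs)) {
      al <- .rs_align_pair(refSeqs[[t]], rd)
      cov <- (al$b_end - al$b_start) / nchar(rd)
      if (al$ok && al$identity >= 90 - 1e-9 && cov >= 0.55 - 1e-9 &&
          (is.null(best) || al$score > best$score))
        best <- list(score = al$score, target = names(refSeqs)[t])
    }
    same[i] <- if (is.null(best)) is.na(asgS$target_id[i])
      else identical(asgS$target_id[i], best$target)
  }
  mapperAgreement <- 100 * mean(same)

  ## ---- regression slopes ------------------------------------------------
  gp0 <- c(0.1, 0.3, 0.8, 1.5, 3, 6)
  fExact <- fitTpModel(data.frame(gp = gp0, tp = 0.02 * gp0), "gp",
                       transform = "log10-both")
  set.seed(seed + 303L)
  gpN <- 10^runif(50, -1, 1)
  tpN <- 10^(log10(gpN) + rnorm(50, 0, 0.1))
  fNoisy <- fitTpModel(data.frame(gp = gpN, tp = tpN), "gp",
                       transform = "log10-both")
  ciNoisy <- suppressMessages(stats::confint(
    lm(log10(tpN) ~ log10(gpN))))[2, ]

  ## ---- Tukey family-wise type-I error under the null --------------------
  set.seed(seed + 404L)
  rejections <- 0L
  for (s in seq_len(tukeySims)) {
    vals <- rnorm(32)
    tk <- tukeyMeans(vals, rep(sprintf("g%d", 1:4), each = 8))
    if (any(tk$pmat < 0.05, na.rm = TRUE)) rejections <- rejections + 1L
  }
  tukeyT1 <- rejections / tukeySims

  ## ---- end-to-end rerun determinism -------------------------------------
  d1 <- file.path(outdir, "bm_rerun_a")
  d2 <- file.path(outdir, "bm_rerun_b")
  cfg <- demoPipelineConfig(seed = seed + 505L, backgroundLength = 4e5,
                            familyScale = 0.12, skimPairs = 3000L,
                            rnaReads = 3000L, topClusterMinReads = 40L,
                            geneCount = 6L, maxScoredReads = 120L)
  runPipeline(cfg, d1, stages = c("simulate", "cluster", "stats"))
  runPipeline(cfg, d2, stages = c("simulate", "cluster", "stats"))
  tsv1 <- sort(list.files(d1, pattern = "\\.tsv$"))
  identicalRerun <- all(vapply(tsv1, function(f)
    unname(tools::md5sum(file.path(d1, f))) ==
      unname(tools::md5sum(file.path(d2, f))), TRUE))

  list(
    summary = c(
      gp_recovery_max_rel_error = max(gpEligible$gpRelError),
      tp_recovery_max_rel_error = max(tpEligible$tpRelError, na.rm = TRUE),
      modal_similarity_max_abs_error = max(simEligible$simAbsError),
      total_repeat_gp_estimated = sum(cl$gp[!cl$flag %in%
                                              c("organelle")], na.rm = TRUE),
      ltr_detection_sensitivity_pct = sensitivity,
      ltr_detection_precision_pct = precision,
      completeness_accuracy_pct = completenessAcc,
      intronic_context_accuracy_pct = 100 * mean(ctxAgree),
      mapper_oracle_agreement_pct = mapperAgreement,
      loglog_slope_exact = fExact$slope,
      loglog_slope_planted = fNoisy$slope,
      loglog_slope_ci_low = unname(ciNoisy[1]),
      loglog_slope_ci_high = unname(ciNoisy[2]),
      tukey_type1_error = tukeyT1,
      rerun_byte_identical = as.numeric(identicalRerun)),
    detail = list(gp = gpDetail, tp = tpDetail,
                  clusters = cl, elements = el,
                  manifest = famTab))
}
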