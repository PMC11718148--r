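#' Demo pipeline configuration
#'
#' A self-contained synthetic run: genome size, family mix (scaled
#' \code{\link{defaultFamilies}}), skim depth, RNA libraries (three
#' replicates each of a poly-A and a ribo-depleted library by default),
#' thresholds and seed. All thresholds default to the analysis' citable
#' values (90 / 0.55 / 151 / 80 / 100).
#'
#' @param seed RNG seed.
#' @param backgroundLength Nuclear background length (default 2e6).
#' @param familyScale Copy-number scale on the default families (default
#'   0.3, sized for the default genome).
#' @param skimPairs Number of skim read pairs (default 20000).
#' @param rnaReads Reads per RNA library (default 40000).
#' @param rnaReplicates Replicates per library type (default 1).
#' @param topClusterMinReads Top-cluster rule (default 151).
#' @param geneCount Gene models (default 30).
#' @param maxScoredReads Per-cluster subsample for pair scoring (default
#'   500).
#' @return Named list understood by \code{\link{runPipeline}}.
#' @export
demoPipelineConfig <- function(seed = 1L, backgroundLength = 2e6,
                               familyScale = 0.3, skimPairs = 20000L,
                               rnaReads = 40000L, rnaReplicates = 1L,
                               topClusterMinReads = 151L,
                               geneCount = 30L, maxScoredReads = 500L) {
  libs <- list()
  for (r in seq_len(rnaReplicates)) {
    libs[[length(libs) + 1L]] <- list(
      id = paste0("polyA_rep", r), type = "polyA", nReads = rnaReads)
    libs[[length(libs) + 1L]] <- list(
      id = paste0("ribo_rep", r), type = "ribodepleted", nReads = rnaReads)
  }
  list(seed = as.integer(seed), backgroundLength = backgroundLength,
       backgroundGC = 0.42, familyScale = familyScale,
       geneCount = as.integer(geneCount), intronicLtrFraction = 0.3,
       skimPairs = as.integer(skimPairs), readLength = 151L,
       errorRate = 0.002, rnaLibraries = libs,
       config = runConfig(topClusterMinReads = topClusterMinReads,
                          seed = seed),
       maxScoredReads = as.integer(maxScoredReads))
}

.logStage <- function(logPath, stage, status, extra = list()) {
  rec <- c(list(stage = stage, status = status), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logPath, append = TRUE, sep = "")
}

#' Run the end-to-end synthetic analysis
#'
#' Orchestrates simulate -> cluster -> cluster-stats -> ltr-annotate ->
#' quantify -> models from one configuration, writing TSV outputs (with
#' config hash and seed in their commented headers) into \code{outdir}.
#' Rerunning with an identical configuration and seed reproduces
#' byte-identical tables. Disabling the \code{ltr} stage makes the
#' quantification run in contig mode only.
#'
#' @param cfg Configuration list from \code{\link{demoPipelineConfig}}.
#' @param outdir Output directory (created if missing).
#' @param stages Character subset of
#'   \code{c("simulate","cluster","stats","ltr","quantify","models")};
#'   later stages require earlier ones in this in-memory pipeline.
#' @return Invisible list with the in-memory results of every executed
#'   stage.
#' @export
runPipeline <- function(cfg, outdir,
                        stages = c("simulate", "cluster", "stats", "ltr",
                                   "quantify", "models")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "pipeline_log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  rc <- cfg$config
  meta <- configMeta(rc)
  set.seed(cfg$seed)
  out <- list(config = cfg)

  # ---- simulate -----------------------------------------------------------
  stopifnot("simulate" %in% stages)
  .logStage(logPath, "simulate", "start")
  fams <- defaultFamilies(scale = cfg$familyScale)
  manifest <- plantGenome(fams, cfg$backgroundLength, cfg$backgroundGC,
                          cfg$geneCount, cfg$intronicLtrFraction)
  writeSeqs(manifest@genome, file.path(outdir, "genome.fasta"))
  writeResultTable(manifest@families,
                   file.path(outdir, "truth_manifest.tsv"), meta)
  if (length(manifest@copies))
    writeFeatures(grangesToFeatures(manifest@copies),
                  file.path(outdir, "truth_repeats.gff3"))
  if (length(manifest@genes))
    writeFeatures(grangesToFeatures(manifest@genes),
                  file.path(outdir, "truth_genes.gff3"))
  skim <- simulateSkimReads(manifest, cfg$skimPairs, cfg$readLength,
                            errorRate = cfg$errorRate)
  writeSeqs(skim$r1, file.path(outdir, "skim_R1.fastq"), "fastq")
  writeSeqs(skim$r2, file.path(outdir, "skim_R2.fastq"), "fastq")
  rnaLibs <- list()
  for (lib in cfg$rnaLibraries) {
    rl <- simulateRnaLibrary(manifest, lib$type, lib$nReads,
                             cfg$readLength, errorRate = cfg$errorRate)
    rnaLibs[[lib$id]] <- rl
    writeSeqs(rl$reads, file.path(outdir, paste0(lib$id, ".fastq")),
              "fastq")
    writeResultTable(rl$expectedTp,
                     file.path(outdir, paste0("expected_tp_", lib$id,
                                              ".tsv")), meta)
  }
  out$manifest <- manifest
  out$skim <- skim
  out$rnaLibs <- rnaLibs
  .logStage(logPath, "simulate", "done",
            list(genome_bp = sum(Biostrings::width(manifest@genome)),
                 skim_pairs = cfg$skimPairs))

  # ---- cluster ------------------------------------------------------------
  if (!"cluster" %in% stages) return(invisible(out))
  .logStage(logPath, "cluster", "start")
  reads <- c(skim$r1, skim$r2)
  cset <- clusterReads(reads, rc@identityThreshold, rc@coverageThreshold)
  top <- selectTopClusters(cset, rc@topClusterMinReads)
  top <- buildClusterContigs(top, rc@identityThreshold,
                             rc@coverageThreshold)
  refLib <- referenceLibrary(manifest)
  top <- annotateClusters(top, refLib)
  top <- genomeProportion(top, totalReadsAnalyzed = length(reads))
  writeSeqs(top@contigs, file.path(outdir, "contigs.fasta"))
  writeResultTable(clusterTable(top), file.path(outdir, "clusters.tsv"),
                   c(meta, denominator =
                       as.character(attr(clusterTable(top), "denominator"))))
  writeLines(unclusteredReads(cset),
             file.path(outdir, "unclustered.txt"))
  out$clusters <- cset
  out$top <- top
  .logStage(logPath, "cluster", "done",
            list(n_clusters = nrow(clusterTable(cset)),
                 n_top = nrow(clusterTable(top))))

  # ---- per-cluster stats --------------------------------------------------
  if (!"stats" %in% stages) return(invisible(out))
  .logStage(logPath, "stats", "start")
  top <- clusterStats(top, rc@similarityFloor, rc@coverageThreshold,
                      cfg$maxScoredReads)
  out$top <- top
  lineageTable <- aggregateLineage(clusterTable(top))
  writeResultTable(clusterTable(top),
                   file.path(outdir, "cluster_stats.tsv"), meta)
  writeResultTable(lineageTable,
                   file.path(outdir, "gp_by_lineage.tsv"), meta)
  out$lineageTable <- lineageTable
  .logStage(logPath, "stats", "done")

  # ---- ltr annotation -----------------------------------------------------
  elements <- NULL
  if ("ltr" %in% stages) {
    .logStage(logPath, "ltr", "start")
    elements <- annotateLtrElements(manifest@genome,
                                    genes = manifest@genes)
    if (length(elements)) {
      ef <- grangesToFeatures(elements)
      writeFeatures(ef, file.path(outdir, "elements.gff3"))
      writeResultTable(ef, file.path(outdir, "elements.tsv"), meta)
    }
    out$elements <- elements
    .logStage(logPath, "ltr", "done",
              list(n_elements = length(elements)))
  }

  # ---- quantify -----------------------------------------------------------
  if (!"quantify" %in% stages) return(invisible(out))
  if (!length(top@contigs)) {
    .logStage(logPath, "quantify", "skipped",
              list(reason = "no top-cluster contigs"))
    return(invisible(out))
  }
  .logStage(logPath, "quantify", "start")
  contigCluster <- setNames(
    sub("_contig\\d+$", "", names(top@contigs)), names(top@contigs))
  tpCluster <- list(); tpLineage <- list(); denominators <- list()
  elementCounts <- list()
  for (libId in names(rnaLibs)) {
    rl <- rnaLibs[[libId]]
    asg <- mapRnaReads(rl$reads, top@contigs, rc@identityThreshold,
                       rc@coverageThreshold, cfg$readLength,
                       clusterOf = contigCluster)
    tp <- transcriptProportion(asg, clusterTable(top), length(rl$reads))
    tpCluster[[libId]] <- tp
    writeResultTable(tp$clusters,
                     file.path(outdir, paste0("tp_by_cluster_", libId,
                                              ".tsv")), meta)
    writeResultTable(tp$lineages,
                     file.path(outdir, paste0("tp_by_lineage_", libId,
                                              ".tsv")), meta)
    if (!is.null(elements) && length(elements)) {
      gasg <- mapRnaReads(rl$reads, manifest@genome,
                          rc@identityThreshold, rc@coverageThreshold,
                          cfg$readLength)
      # exclusion: reads on organellar contigs or rDNA copies
      sepContigs <- manifest@families$name[manifest@families$separateContig]
      rdnaCopies <- manifest@copies[
        manifest@copies$family %in%
          manifest@families$name[manifest@families$classLabel == "rDNA"]]
      onOrganelle <- !is.na(gasg$target_id) &
        gasg$target_id %in% sepContigs
      onRdna <- rep(FALSE, nrow(gasg))
      okRows <- which(!is.na(gasg$target_id))
      if (length(okRows) && length(rdnaCopies)) {
        gr <- GenomicRanges::GRanges(
          gasg$target_id[okRows],
          IRanges::IRanges(gasg$t_start[okRows] + 1L,
                           gasg$t_end[okRows]))
        ov <- suppressWarnings(
          GenomicRanges::findOverlaps(gr, rdnaCopies))
        onRdna[okRows[unique(S4Vectors::queryHits(ov))]] <- TRUE
      }
      keep <- !(onOrganelle | onRdna)
      denominators[[libId]] <- length(rl$reads) - sum(!keep)
      pc <- countPerElement(gasg[keep, , drop = FALSE], elements)
      libType <- vapply(cfg$rnaLibraries,
                        function(l) if (l$id == libId) l$type else "",
                        "")
      elementCounts[[libId]] <- data.frame(
        library_id = libId,
        library_type = libType[nzchar(libType)][1],
        element_id = elements$element_id,
        completeness = elements$completeness,
        context = elements$context,
        mapped_reads = pc$counts, stringsAsFactors = FALSE)
    }
  }
  out$tpCluster <- tpCluster
  if (length(elementCounts)) {
    ec <- do.call(rbind, elementCounts)
    compSummary <- completenessTpSummary(ec, denominators)
    writeResultTable(compSummary,
                     file.path(outdir, "completeness_summary.tsv"), meta)
    countsMat <- do.call(cbind, lapply(elementCounts, function(x)
      x$mapped_reads))
    colnames(countsMat) <- names(elementCounts)
    expressed <- filterExpressedElements(countsMat, elements,
                                         rc@expressedElementMinReads)
    writeResultTable(expressed$elements,
                     file.path(outdir, "expressed_elements.tsv"),
                     c(meta, intronic =
                         as.character(expressed$tally[["intronic"]]),
                       non_intronic =
                         as.character(expressed$tally[["non_intronic"]])))
    out$elementCounts <- ec
    out$completenessSummary <- compSummary
    out$expressed <- expressed
  }
  .logStage(logPath, "quantify", "done")

  # ---- models -------------------------------------------------------------
  if (!"models" %in% stages) return(invisible(out))
  .logStage(logPath, "models", "start")
  fits <- list()
  cl <- clusterTable(top)
  for (libId in names(tpCluster)) {
    joined <- merge(cl, tpCluster[[libId]]$clusters[, c("cluster_id", "tp")],
                    by = "cluster_id")
    for (cls in c("Ty1/copia", "Ty3/gypsy", "DNA_transposon")) {
      sub <- joined[joined$classLabel == cls, , drop = FALSE]
      for (pred in c("gp", "gc_percent", "modal_similarity")) {
        tr <- if (pred == "gp") "log10-both" else "log10-response"
        f <- fitTpModel(sub, pred, response = "tp", transform = tr,
                        group = paste(libId, cls, sep = ":"))
        if (!is.null(f)) fits[[length(fits) + 1L]] <- f
      }
    }
  }
  fitsDf <- if (length(fits)) do.call(rbind, fits) else data.frame()
  if (nrow(fitsDf)) {
    fitsDf$p_adj_BH <- stats::p.adjust(fitsDf$p_value, "BH")
    writeResultTable(fitsDf, file.path(outdir, "fits.tsv"), meta)
  }
  out$fits <- fitsDf
  tkRows <- list()
  for (resp in c("modal_similarity", "gc_percent")) {
    cls2 <- cl[nzchar(cl$lineage) & !is.na(cl[[resp]]), , drop = FALSE]
    if (length(unique(cls2$lineage[table(cls2$lineage)[cls2$lineage] >= 2])) >= 2) {
      tk <- tryCatch(tukeyMeans(cls2[[resp]], cls2$lineage),
                     error = function(e) NULL)
      if (!is.null(tk))
        tkRows[[resp]] <- data.frame(
          response = resp, lineage = names(tk$letters),
          letters = unname(tk$letters), stringsAsFactors = FALSE)
    }
  }
  if (length(tkRows))
    writeResultTable(do.call(rbind, tkRows),
                     file.path(outdir, "tukey.tsv"), meta)
  out$tukey <- tkRows
  # map cluster -> family via the reference library annotation ids
  refLib <- referenceLibrary(manifest)
  linFam <- setNames(refLib$info$id,
                     paste(refLib$info$classLabel, refLib$info$lineage))
  clusterFamily <- setNames(
    unname(linFam[paste(cl$classLabel, cl$lineage)]), cl$cluster_id)
  tpPerCluster <- lapply(tpCluster, function(x) x$clusters)
  expTp <- lapply(rnaLibs, function(x) x$expectedTp)
  recov <- recoveryReport(manifest, cl, clusterFamily,
                          tpPerCluster, expTp)
  writeResultTable(recov, file.path(outdir, "recovery_report.tsv"), meta)
  out$recovery <- recov
  .logStage(logPath, "models", "done")
  invisible(out)
}
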