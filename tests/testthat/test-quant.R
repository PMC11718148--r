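test_that("RNA reads map to their best reference under the criterion", {
  set.seed(61)
  c1 <- randSeq(1500); c2 <- randSeq(1500)
  refs <- Biostrings::DNAStringSet(c(CL1_contig1 = c1, CL2_contig1 = c2))
  reads <- Biostrings::DNAStringSet(c(
    a = substr(c1, 301, 451),          # exact substring
    b = revComp(substr(c2, 601, 751)), # reverse complement
    c = randSeq(151)))                 # unmappable
  asg <- mapRnaReads(reads, refs,
                     clusterOf = c(CL1_contig1 = "CL1",
                                   CL2_contig1 = "CL2"))
  expect_equal(asg$target_id, c("CL1_contig1", "CL2_contig1", NA))
  expect_equal(asg$identity[1:2], c(100, 100))
  expect_equal(asg$cluster_id[1:2], c("CL1", "CL2"))
  expect_equal(asg$orientation[2], "reverse-complement")
  expect_equal(asg$t_start[1], 300L)   # 0-based half-open on target
  expect_equal(asg$t_end[1], 451L)
})

test_that("a read matching two contigs of one cluster counts once", {
  set.seed(62)
  core <- randSeq(400)
  refs <- Biostrings::DNAStringSet(c(
    CL1_contig1 = paste0(core, randSeq(300)),
    CL1_contig2 = paste0(randSeq(200), core)))
  rd <- Biostrings::DNAStringSet(c(x = substr(core, 100, 250)))
  asg <- mapRnaReads(rd, refs, clusterOf = c(CL1_contig1 = "CL1",
                                             CL1_contig2 = "CL1"))
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$cluster_id, "CL1")
  anno <- data.frame(cluster_id = "CL1", classLabel = "Ty3/gypsy",
                     lineage = "Tekay", flag = "none",
                     stringsAsFactors = FALSE)
  tp <- transcriptProportion(asg, anno, 1000L)
  expect_equal(tp$clusters$mapped_reads, 1L)  # +1, not +2
})

test_that("raising the identity threshold never adds assignments", {
  set.seed(63)
  tmpl <- randSeq(2000)
  refs <- Biostrings::DNAStringSet(c(CL1_contig1 = tmpl))
  reads <- Biostrings::DNAStringSet(setNames(
    vapply(1:40, function(i) {
      p <- sample(1800, 1)
      mutated(substr(tmpl, p, p + 150), runif(1, 0, 0.12))
    }, ""), sprintf("r%d", 1:40)))
  n90 <- sum(!is.na(mapRnaReads(reads, refs, 90)$target_id))
  n95 <- sum(!is.na(mapRnaReads(reads, refs, 95)$target_id))
  expect_lte(n95, n90)
})

test_that("transcript proportions exclude flagged clusters from both sides", {
  anno <- data.frame(
    cluster_id = c("CL1", "CL2", "CL3", "CL4"),
    classLabel = c("Ty3/gypsy", "Ty3/gypsy", "rDNA", "Ty1/copia"),
    lineage = c("Tekay", "Retand", "45S", "Angela"),
    flag = c("none", "none", "rDNA", "none"),
    stringsAsFactors = FALSE)
  asg <- data.frame(
    read_id = sprintf("r%d", 1:700),
    target_id = "x",
    cluster_id = rep(c("CL1", "CL2", "CL3"), c(200, 100, 400)),
    stringsAsFactors = FALSE)
  tp <- transcriptProportion(asg, anno, 100400L)
  expect_equal(tp$denominator, 100000L)
  expect_equal(tp$excluded_reads, 400L)
  cl <- tp$clusters
  expect_equal(cl$tp[cl$cluster_id == "CL1"], 0.2)
  expect_equal(cl$tp[cl$cluster_id == "CL4"], 0)   # zero-read row retained
  expect_true(is.na(cl$tp[cl$cluster_id == "CL3"]))
  # additivity: lineages -> classes -> total
  expect_equal(sum(tp$lineages$tp), sum(tp$classes$tp))
  expect_equal(tp$total, sum(tp$classes$tp))
  gy <- tp$classes$tp[tp$classes$unit == "Ty3/gypsy"]
  expect_equal(gy, sum(cl$tp[cl$classLabel == "Ty3/gypsy"], na.rm = TRUE))

  # moving CL2's reads into an rDNA cluster shrinks the denominator,
  # which can only increase the remaining clusters' TP
  asg2 <- asg
  asg2$cluster_id[201:300] <- "CL3"
  tp2 <- transcriptProportion(asg2, anno, 100400L)
  expect_equal(tp2$denominator, 99900L)
  expect_gt(tp2$clusters$tp[1], tp$clusters$tp[1])
})

test_that("per-element counting follows the union rule", {
  els <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 1400, 5000), c(1500, 2000, 6000)),
    element_id = c("TE1", "TE2", "TE3"),
    completeness = c("complete", "incomplete", "complete"),
    context = c("intronic", "intergenic", "intergenic"))
  asg <- data.frame(
    read_id = c("a", "b", "c", "d"),
    target_id = c("chr1", "chr1", "chr1", "chr1"),
    t_start = c(1050L, 1450L, 5500L, 8000L),
    t_end = c(1200L, 1600L, 5650L, 8151L),
    stringsAsFactors = FALSE)
  pc <- countPerElement(asg, els)
  expect_equal(pc$counts, c(1L, 0L, 1L))   # read b overlaps TE1+TE2
  expect_equal(pc$ambiguous, 1L)
  expect_equal(pc$assigned, 2L)
})

test_that("completeness summary adds complete and incomplete TP", {
  ec <- data.frame(
    library_id = rep(c("L1", "L2"), each = 2),
    library_type = rep("polyA", 4),
    element_id = rep(c("TE1", "TE2"), 2),
    completeness = rep(c("complete", "incomplete"), 2),
    mapped_reads = c(163L, 583L, 80L, 100L),
    stringsAsFactors = FALSE)
  sm <- completenessTpSummary(ec, c(L1 = 100000, L2 = 100000))
  r1 <- sm[sm$library_id == "L1", ]
  expect_equal(r1$tp_complete, 0.163)
  expect_equal(r1$tp_incomplete, 0.583)
  expect_equal(r1$tp_total, 0.746)
  expect_equal(r1$fraction_incomplete, 0.583 / 0.746, tolerance = 1e-12)
  byType <- attr(sm, "byType")
  expect_equal(byType$tp_total, mean(sm$tp_total))
})

test_that("expressed-element filter keeps >= minReads and tallies context", {
  els <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 100, 200), width = 50),
    element_id = c("TE1", "TE2", "TE3"),
    completeness = c("complete", "complete", "incomplete"),
    context = c("intronic", "intergenic", "intronic"))
  cm <- cbind(L1 = c(100L, 99L, 150L), L2 = c(0L, 10L, 80L))
  fe <- filterExpressedElements(cm, els, 100L)
  expect_setequal(fe$elements$element_id, c("TE1", "TE3"))
  expect_equal(unname(fe$tally["intronic"]), 2L)
  expect_equal(unname(fe$tally["non_intronic"]), 0L)
  feAll <- filterExpressedElements(cm, els, 0L)
  expect_equal(nrow(feAll$elements), 3L)
})

test_that("read bookkeeping is conserved through mapping and exclusion", {
  set.seed(64)
  mf <- smallManifest()
  rl <- simulateRnaLibrary(mf, "ribodepleted", 4000L)
  lib <- referenceLibrary(mf)
  refs <- lib$seqs
  names(refs) <- sprintf("CL%d_contig1", seq_along(refs))
  clOf <- setNames(sprintf("CL%d", seq_along(refs)), names(refs))
  asg <- mapRnaReads(rl$reads, refs, clusterOf = clOf)
  anno <- data.frame(cluster_id = unname(clOf),
                     classLabel = lib$info$classLabel,
                     lineage = lib$info$lineage,
                     flag = lib$info$flag, stringsAsFactors = FALSE)
  tp <- transcriptProportion(asg, anno, length(rl$reads))
  assigned <- sum(!is.na(asg$cluster_id))
  unassigned <- sum(is.na(asg$cluster_id))
  expect_equal(assigned + unassigned, length(rl$reads))
  expect_equal(sum(tp$clusters$mapped_reads) + tp$excluded_reads,
               assigned)
  expect_lte(sum(tp$clusters$tp, na.rm = TRUE), 100)
})

test_that("the seeded mapper agrees with an exhaustive-DP oracle", {
  set.seed(65)
  mf <- smallManifest()
  rl <- simulateRnaLibrary(mf, "ribodepleted", 90L)
  lib <- referenceLibrary(mf)
  refs <- lib$seqs[order(names(lib$seqs))]
  asg <- mapRnaReads(rl$reads, refs)
  refSeqs <- as.character(refs)
  for (i in seq_along(rl$reads)) {
    rd <- as.character(rl$reads[[i]])
    best <- NULL
    for (t in seq_along(refSeqs)) {
      al <- retroscribe:::.rs_align_pair(refSeqs[[t]], rd)
      cov <- (al$b_end - al$b_start) / nchar(rd)
      if (al$ok && al$identity >= 90 - 1e-9 && cov >= 0.55 - 1e-9 &&
          (is.null(best) || al$score > best$score))
        best <- list(score = al$score, target = names(refSeqs)[t],
                     identity = al$identity)
    }
    if (is.null(best)) {
      expect_true(is.na(asg$target_id[i]))
    } else {
      expect_equal(asg$target_id[i], best$target)
      expect_equal(asg$identity[i], best$identity, tolerance = 1e-6)
    }
  }
})
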