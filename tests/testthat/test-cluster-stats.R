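test_that("pair scores cover each unordered pair exactly once", {
  set.seed(41)
  a <- randSeq(151)
  reads <- Biostrings::DNAStringSet(c(x = a, y = a, z = a))
  sc <- similarityScores(reads)
  expect_equal(as.numeric(sc), c(100, 100, 100))   # 3 unordered pairs
  expect_equal(attr(sc, "n_pairs_scored"), 3L)

  # reciprocal duplicates collapse: two reads give one score, not two
  two <- similarityScores(reads[1:2])
  expect_length(two, 1L)
})

test_that("scores below the floor are omitted", {
  set.seed(42)
  a <- randSeq(151)
  b <- mutated(a, 0.28)           # ~72% pairwise identity
  sc <- similarityScores(Biostrings::DNAStringSet(c(x = a, y = b)),
                         floor = 80)
  expect_length(sc, 0L)
  scLow <- similarityScores(Biostrings::DNAStringSet(c(x = a, y = b)),
                            floor = 50)
  expect_length(scLow, 1L)
  expect_lt(scLow[1], 80)
})

test_that("modal similarity bins to integer left edges with ties upward", {
  expect_equal(modalSimilarity(c(92.4, 92.7, 93.1, 85.0, 79.0)), 92)
  expect_equal(modalSimilarity(c(90.1, 90.2, 90.9, 90.5,
                                 95.0, 95.3, 95.6, 95.9)), 95)
  expect_true(is.na(modalSimilarity(c(70, 75), floor = 80)))
  expect_true(is.na(modalSimilarity(numeric(0))))
})

test_that("GC content is pooled over reads and strand-symmetric", {
  expect_equal(gcContent("GGCC"), 100)
  expect_equal(gcContent(c("ATGC", "AT")), 100 * 2 / 6, tolerance = 1e-9)
  expect_true(is.na(gcContent("NNNN")))
  set.seed(43)
  rr <- c(randSeq(100), randSeq(80))
  rr2 <- c(rr[1], revComp(rr[2]))
  expect_equal(gcContent(rr), gcContent(rr2))
})

test_that("modal similarity decreases with planted divergence and tracks
           the empirical pairwise identity", {
  set.seed(44)
  master <- randSeq(1200)
  mkCluster <- function(d) familyReads(master, 8, d, 130)
  r1 <- mkCluster(0.01)
  r2 <- mkCluster(0.05)
  m1 <- modalSimilarity(similarityScores(r1))
  m2 <- modalSimilarity(similarityScores(r2))
  expect_gt(m1, m2)

  # oracle: mean pairwise global identity of the planted copies
  copies <- attr(r1, "copies")
  prs <- combn(length(copies), 2)
  expIdent <- mean(vapply(seq_len(ncol(prs)), function(i)
    bsGlobalIdentity(copies[prs[1, i]], copies[prs[2, i]]), 0))
  expect_lt(abs(m1 - expIdent), 1.5)
})

test_that("lineage aggregation sums class GP from its lineages", {
  df <- data.frame(
    cluster_id = paste0("CL", 1:6),
    size = rep(100L, 6),
    classLabel = c("Ty3/gypsy", "Ty3/gypsy", "Ty1/copia", "Ty1/copia",
                   "satellite", "rDNA"),
    lineage = c("Tekay", "Retand", "Angela", "Bianca", "", "45S"),
    flag = c("none", "none", "none", "none", "none", "rDNA"),
    gp = c(2.83, 2.57, 2.42, 0.03, 3.86, 3.52),
    modal_similarity = c(95, 90, 93, 90.95, 86, 99.9),
    gc_percent = c(50, 45, 40, 33, 48, 55),
    stringsAsFactors = FALSE)
  agg <- aggregateLineage(df)
  gy <- agg[agg$level == "class" & agg$classLabel == "Ty3/gypsy", ]
  expect_equal(gy$gp, 2.83 + 2.57)
  expect_equal(gy$n_clusters, 2L)
  # single-cluster lineage collapses its ranges to one value
  bianca <- agg[agg$lineage == "Bianca", ]
  expect_equal(bianca$sim_min, bianca$sim_max)
  expect_equal(bianca$sim_min, 90.95)
  # totals with and without rDNA
  totAll <- agg[agg$classLabel == "Total repeats", ]
  totNoR <- agg[agg$classLabel == "Total (excl. rDNA)", ]
  expect_equal(totAll$gp - totNoR$gp, 3.52)
  # empty lineages are not emitted
  expect_false(any(agg$lineage == "Ogre"))
})
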