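test_that("pairwise hits implement the similarity-over-coverage criterion", {
  set.seed(21)
  a <- randSeq(151)
  reads <- Biostrings::DNAStringSet(c(x = a, y = a))
  h <- pairwiseHits(reads)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$coverage, 1)
  expect_equal(h$orientation, "forward")

  # a read and its reverse complement: identity 100, rc orientation
  reads2 <- Biostrings::DNAStringSet(c(x = a, y = revComp(a)))
  h2 <- pairwiseHits(reads2)
  expect_equal(h2$identity, 100)
  expect_equal(h2$orientation, "reverse-complement")

  # shared overlap at ~95% identity covering 60% vs 50% of the shorter read
  core <- randSeq(100)
  mkOverlap <- function(frac) {
    ov <- substr(core, 1, round(100 * frac))
    ov95 <- mutated(ov, 0.04)
    r1 <- paste0(ov, randSeq(100 - nchar(ov)))
    r2 <- paste0(randSeq(100 - nchar(ov)), ov95)
    Biostrings::DNAStringSet(c(p = r1, q = r2))
  }
  h60 <- pairwiseHits(mkOverlap(0.60))
  expect_equal(nrow(h60), 1L)
  h50 <- pairwiseHits(mkOverlap(0.50))
  expect_equal(nrow(h50), 0L)
})

test_that("hits are canonical: one per unordered pair, smaller id first", {
  set.seed(22)
  a <- randSeq(151)
  reads <- Biostrings::DNAStringSet(c(zz = a, aa = a, mm = a))
  h <- pairwiseHits(reads)
  expect_equal(nrow(h), 3L)
  expect_true(all(h$query_id < h$subject_id))
  expect_equal(anyDuplicated(paste(h$query_id, h$subject_id)), 0L)
})

test_that("local alignment agrees with an independent implementation", {
  set.seed(23)
  for (i in 1:12) {
    a <- randSeq(sample(80:160, 1))
    b <- if (i %% 3 == 0) randSeq(sample(80:160, 1)) else
      mutated(paste0(randSeq(20), substr(a, 20, 120), randSeq(15)), 0.05)
    r <- retroscribe:::.rs_align_pair(a, b)
    expect_equal(r$score, bsLocalScore(a, b))
  }
  g1 <- randSeq(600)
  g2 <- mutated(g1, 0.05, 0.002)
  mine <- retroscribe:::.rs_global_identity(g1, g2, 60)
  expect_equal(mine$identity, bsGlobalIdentity(g1, g2), tolerance = 0.3)
})

test_that("connected components merge transitively and singletons stay out", {
  reads <- Biostrings::DNAStringSet(
    setNames(replicate(3, randSeq(151)), c("a", "b", "c")))
  hits <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                     identity = 95, coverage = 1,
                     orientation = "forward", score = 100)
  cs <- clusterFromHits(hits, reads)
  expect_equal(nrow(clusterTable(cs)), 1L)
  expect_setequal(clusterMembers(cs, "CL1"), c("a", "b", "c"))

  set.seed(24)
  lone <- Biostrings::DNAStringSet(
    setNames(replicate(10, randSeq(151)), paste0("r", 1:10)))
  cs2 <- clusterReads(lone, exact = TRUE)
  expect_equal(nrow(clusterTable(cs2)), 0L)
  expect_length(unclusteredReads(cs2), 10L)
})

test_that("well-separated families resolve into one cluster each", {
  set.seed(25)
  mA <- randSeq(1000)
  mB <- mutated(mA, 0.25)          # 25% mutual divergence
  rA <- familyReads(mA, 4, 0, 110, prefix = "a")
  rB <- familyReads(mB, 4, 0, 110, prefix = "b")
  cs <- clusterReads(c(rA, rB))
  tab <- clusterTable(cs)
  expect_equal(nrow(tab), 2L)
  m1 <- clusterMembers(cs, "CL1")
  expect_true(all(startsWith(m1, substr(m1[1], 1, 1))))
  famOf <- substr(c(names(rA), names(rB)), 1, 1)
  got <- ifelse(is.na(cs@membership), NA, cs@membership)
  expect_equal(length(unique(got[famOf == "a"])), 1L)
  expect_equal(length(unique(got[famOf == "b"])), 1L)
})

test_that("clustering is invariant to read order and reverse complement", {
  set.seed(26)
  m <- randSeq(1500)
  rr <- familyReads(m, 3, 0.01, 50)
  cs1 <- clusterReads(rr)
  perm <- sample(length(rr))
  cs2 <- clusterReads(rr[perm])
  part <- function(cs) {
    sets <- split(names(cs@reads), cs@membership)
    unname(lapply(sets, sort))
  }
  expect_setequal(part(cs1), part(cs2))

  rcIdx <- c(5, 12)
  rr3 <- rr
  rr3[rcIdx] <- Biostrings::reverseComplement(rr[rcIdx])
  cs3 <- clusterReads(rr3)
  expect_setequal(part(cs1), part(cs3))
})

test_that("top-cluster selection is a strict more-than rule", {
  set.seed(27)
  mkCs <- function(sizes) {
    total <- sum(sizes)
    reads <- Biostrings::DNAStringSet(
      setNames(vapply(seq_len(total), function(i) randSeq(60), ""),
               sprintf("r%d", seq_len(total))))
    membership <- rep(seq_along(sizes), sizes)
    new("RepeatClusterSet", reads = reads,
        membership = as.integer(membership),
        clusters = data.frame(cluster_id = sprintf("CL%d", seq_along(sizes)),
                              size = as.integer(sizes),
                              stringsAsFactors = FALSE),
        contigs = Biostrings::DNAStringSet())
  }
  cs <- mkCs(c(200, 151, 150, 10))
  top <- selectTopClusters(cs, 151L)
  expect_equal(clusterTable(top)$size, c(200L, 151L))
  all3 <- selectTopClusters(cs, 1L)
  expect_equal(nrow(clusterTable(all3)), 4L)
  none <- selectTopClusters(mkCs(integer(0)), 151L)
  expect_equal(nrow(clusterTable(none)), 0L)
})

test_that("consensus reconstructs an error-free template", {
  set.seed(28)
  template <- randSeq(1000)
  reads <- tilingReads(template, 151L, 40L)
  ct <- buildConsensus(reads)
  expect_equal(length(ct), 1L)
  expect_true(grepl(as.character(ct[[1]]), template, fixed = TRUE))
  expect_gte(nchar(as.character(ct[[1]])), 900L)

  single <- buildConsensus(reads[1])
  expect_equal(as.character(single[[1]]), as.character(reads[[1]]))
})

test_that("consensus majority vote breaks ties alphabetically", {
  set.seed(29)
  base <- randSeq(200)
  v <- rep(base, 6)
  substr(v[1], 100, 100) <- "G"; substr(v[2], 100, 100) <- "G"
  substr(v[3], 100, 100) <- "G"
  substr(v[4], 100, 100) <- "A"; substr(v[5], 100, 100) <- "A"
  substr(v[6], 100, 100) <- "A"
  ct <- buildConsensus(Biostrings::DNAStringSet(setNames(v, paste0("r", 1:6))))
  expect_equal(substr(as.character(ct[[1]]), 100, 100), "A")
})

test_that("annotation labels clusters and flags organellar content", {
  set.seed(30)
  mf <- smallManifest()
  lib <- referenceLibrary(mf)
  masters <- mf@params$masters

  mkTop <- function(seqs, ids) {
    reads <- Biostrings::DNAStringSet(
      setNames(replicate(4, randSeq(60)), paste0("x", 1:4)))
    ct <- Biostrings::DNAStringSet(setNames(seqs, ids))
    new("RepeatClusterSet", reads = reads,
        membership = rep(1L, 4),
        clusters = data.frame(cluster_id = "CL1", size = 4L,
                              stringsAsFactors = FALSE),
        contigs = ct)
  }
  tekayContig <- substr(masters[["famA_tekay"]]$seq, 300, 1800)
  cs <- annotateClusters(mkTop(tekayContig, "CL1_contig1"), lib)
  expect_equal(clusterTable(cs)$classLabel, "Ty3/gypsy")
  expect_equal(clusterTable(cs)$lineage, "Tekay")

  orgContig <- substr(as.character(manifestGenome(mf)[["plastid"]]),
                      1000, 2500)
  cs2 <- annotateClusters(mkTop(orgContig, "CL1_contig1"), lib)
  expect_equal(clusterTable(cs2)$flag, "organelle")

  cs3 <- annotateClusters(mkTop(randSeq(1200), "CL1_contig1"), lib)
  expect_equal(clusterTable(cs3)$classLabel, "unknown")
})

test_that("genome proportion uses the organelle-excluded denominator", {
  reads <- Biostrings::DNAStringSet(
    setNames(replicate(5, randSeq(60)), paste0("r", 1:5)))
  cl <- data.frame(cluster_id = c("CL1", "CL2", "CL3"),
                   size = c(1000L, 500L, 300L),
                   classLabel = c("Ty3/gypsy", "organelle", "satellite"),
                   lineage = c("Tekay", "", ""),
                   flag = c("none", "organelle", "none"),
                   stringsAsFactors = FALSE)
  cs <- new("RepeatClusterSet", reads = reads,
            membership = rep(NA_integer_, 5), clusters = cl,
            contigs = Biostrings::DNAStringSet())
  g <- genomeProportion(cs, totalReadsAnalyzed = 100500L)
  tab <- clusterTable(g)
  expect_equal(attr(tab, "denominator"), 100000L)
  expect_equal(tab$gp[1], 1.000)
  expect_true(is.na(tab$gp[2]))

  # removing an organelle cluster shrinks the denominator -> larger GPs
  cl2 <- cl; cl2$flag <- "none"
  cs2 <- cs; cs2@clusters <- cl2
  g2 <- genomeProportion(cs2, totalReadsAnalyzed = 100500L)
  expect_true(all(clusterTable(g)$gp[-2] > clusterTable(g2)$gp[-2]))
  expect_lte(sum(clusterTable(g)$gp, na.rm = TRUE), 100)
})
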