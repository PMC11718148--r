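test_that("family masters hit their composition and structural targets", {
  set.seed(11)
  for (gc in c(0.30, 0.50, 0.60)) {
    sp <- repeatFamilySpec("f", "unknown", unitLength = 5000L,
                           gcTarget = gc)
    m <- buildFamilyMaster(sp)
    expect_equal(nchar(m$seq), 5000L)
    expect_lt(abs(gcContent(m$seq) - 100 * gc), 2)
  }

  ltrSp <- repeatFamilySpec("ltr", "Ty3/gypsy", "Tekay",
                            unitLength = 4000L, gcTarget = 0.45,
                            structure = list(ltrLength = 300L,
                                             pbsTrna = "tRNA-Met",
                                             tsdLength = 5L))
  m <- buildFamilyMaster(ltrSp)
  fe <- m$features
  ltr <- fe[fe$kind == "LTR", ]
  expect_equal(nrow(ltr), 2L)
  l5 <- substr(m$seq, ltr$start[1] + 1L, ltr$end[1])
  l3 <- substr(m$seq, ltr$start[2] + 1L, ltr$end[2])
  expect_identical(l5, l3)                   # LTRs initially identical
  pbs <- fe[fe$kind == "PBS", ]
  expect_equal(pbs$start, ltr$end[1])        # PBS immediately internal
  expect_identical(substr(m$seq, pbs$start + 1L, pbs$end),
                   revComp(trnaLibrary()[["tRNA-Met"]]))
  doms <- fe[fe$kind == "domain", ]
  expect_equal(doms$name, domainOrder("Ty3/gypsy"))
  expect_lt(abs(gcContent(m$seq) - 45), 2)

  satSp <- repeatFamilySpec("sat", "satellite",
                            structure = list(monomerLength = 150L,
                                             arrayCopies = 10L))
  sm <- buildFamilyMaster(satSp)
  mono <- substr(sm$seq, 1, 150)
  expect_identical(sm$seq, strrep(mono, 10L))

  expect_error(buildFamilyMaster(
    repeatFamilySpec("bad", "Ty3/gypsy", "Tekay", unitLength = 700L,
                     structure = list(ltrLength = 300L))),
    "exceed")
})

test_that("planted GP is the family base fraction of the nuclear genome", {
  set.seed(12)
  sp <- repeatFamilySpec("f", "unknown", copyNumber = 10L,
                         unitLength = 3500L, perCopyDivergence = 0,
                         indelRate = 0)
  mf <- plantGenome(list(sp), 9.65e5, geneCount = 5L)
  fam <- manifestFamilies(mf)
  # 10 x 3500 = 35,000 planted bases in a ~1 Mb genome -> GP ~ 3.5%
  expect_equal(fam$plantedBases, 35000)
  expect_equal(fam$plantedGP,
               100 * 35000 / mf@nuclearBases, tolerance = 1e-12)
  expect_equal(fam$plantedGP, 3.5, tolerance = 0.01)
})

test_that("incompleteFraction = 0 plants only complete LTR copies", {
  set.seed(13)
  sp <- repeatFamilySpec("ltr", "Ty3/gypsy", "Tekay", copyNumber = 8L,
                         unitLength = 3000L,
                         structure = list(ltrLength = 250L,
                                          pbsTrna = "tRNA-Met",
                                          tsdLength = 5L),
                         incompleteFraction = 0)
  mf <- plantGenome(list(sp), 2e5, geneCount = 3L)
  cp <- manifestCopies(mf)
  expect_true(all(cp$complete))
  expect_true(all(cp$has_pbs & cp$has_tsd & cp$has_ltr_pair))
})

test_that("manifest expected identity matches an exhaustive alignment oracle", {
  set.seed(14)
  sp <- repeatFamilySpec("f", "unknown", copyNumber = 5L,
                         unitLength = 800L, perCopyDivergence = 0.02,
                         indelRate = 0.001)
  mf <- plantGenome(list(sp), 5e4, geneCount = 2L,
                    maxIdentityPairs = 100L)
  cp <- manifestCopies(mf)
  seqs <- as.character(Biostrings::extractAt(
    manifestGenome(mf)[["chr1"]], IRanges::ranges(cp)))
  neg <- as.character(GenomicRanges::strand(cp)) == "-"
  seqs[neg] <- revComp(seqs[neg])
  prs <- combn(length(seqs), 2)
  oracle <- mean(vapply(seq_len(ncol(prs)), function(i)
    bsGlobalIdentity(seqs[prs[1, i]], seqs[prs[2, i]]), 0))
  expect_equal(manifestFamilies(mf)$expectedIdentity, oracle,
               tolerance = 0.005)
  # star phylogeny: mean pairwise identity near 1 - 2d(1-d)
  expect_lt(abs(oracle - 100 * (1 - 2 * 0.02 * 0.98)), 1.5)
})

test_that("coverage-to-pairs uses ceiling and never undershoots", {
  expect_equal(pairsForCoverage(1e6, 0.004), 14L)
  expect_equal(pairsForCoverage(302, 1), 1L)
  expect_gte(2L * 151L * pairsForCoverage(1e7, 0.004), 0.004 * 1e7)
})

test_that("error-free skim reads are exact substrings of the genome", {
  set.seed(15)
  mf <- smallManifest()
  sk <- simulateSkimReads(mf, 60L, errorRate = 0)
  gseq <- as.character(manifestGenome(mf))
  hay <- paste(c(gseq, revComp(gseq)), collapse = "|")
  for (rd in as.character(c(sk$r1, sk$r2)))
    expect_true(grepl(rd, hay, fixed = TRUE))
  expect_equal(length(sk$r1), 60L)
  expect_equal(length(sk$r2), 60L)
})

test_that("skim read depth per family tracks planted GP (binomial)", {
  set.seed(16)
  mf <- smallManifest()
  n <- 6000L
  sk <- simulateSkimReads(mf, n)
  fams <- originFamily(mf, sk$origin)
  fam <- manifestFamilies(mf)
  nuclearShare <- mf@nuclearBases /
    (mf@nuclearBases + sum(fam$copyFactor[fam$separateContig] *
                             fam$unitLength[fam$separateContig]))
  for (i in which(!fam$separateContig)) {
    p <- fam$plantedGP[i] / 100 * nuclearShare
    obs <- sum(fams == fam$name[i])
    ci <- qbinom(c(0.0005, 0.9995), n, p)
    expect_gte(obs, ci[1])
    expect_lte(obs, ci[2])
  }
})

test_that("RNA library read fractions follow the generative design", {
  set.seed(17)
  mf <- smallManifest()
  rl <- simulateRnaLibrary(mf, "polyA", 30000L, rddmGpCoupling = 0,
                           intronRetention = 0, errorRate = 0)
  et <- rl$expectedTp
  # famA weight 0.004 -> ~0.4% of reads (binomial band)
  fA <- et$reads[et$family == "famA_tekay"]
  ci <- qbinom(c(0.0005, 0.9995), 30000L, 0.004)
  expect_gte(fA, ci[1]); expect_lte(fA, ci[2])
  # bookkeeping conserves reads and fractions sum to 1
  other <- attr(et, "other")
  expect_equal(other$reads[other$family == "total"], length(rl$reads))
  expect_equal(sum(et$fraction) +
                 other$fraction[other$family == "gene"], 1,
               tolerance = 1e-9)

  rib <- simulateRnaLibrary(mf, "ribodepleted", 20000L,
                            residualRrnaFraction = 0.05,
                            rddmGpCoupling = 0, errorRate = 0)
  rdnaReads <- sum(rib$origin == "famD_rdna")
  ci <- qbinom(c(0.0005, 0.9995), 20000L, 0.05)
  expect_gte(rdnaReads, ci[1]); expect_lte(rdnaReads, ci[2])
})

test_that("GP-coupled RdDM transcription reproduces the planted GP ordering", {
  set.seed(18)
  fams <- list(
    repeatFamilySpec("big", "unknown", copyNumber = 20L,
                     unitLength = 2000L),
    repeatFamilySpec("mid", "unknown", copyNumber = 10L,
                     unitLength = 2000L),
    repeatFamilySpec("small", "unknown", copyNumber = 4L,
                     unitLength = 2000L))
  mf <- plantGenome(fams, 2e5, geneCount = 4L)
  rl <- simulateRnaLibrary(mf, "ribodepleted", 30000L,
                           residualRrnaFraction = 0,
                           rddmGpCoupling = 0.2, errorRate = 0)
  et <- rl$expectedTp
  ord <- order(-manifestFamilies(mf)$plantedGP)
  expect_equal(order(-et$reads), ord)
})

test_that("unknown library type and bad parameters are rejected", {
  mf <- smallManifest()
  expect_error(simulateRnaLibrary(mf, "smallRNA", 100L))
  expect_error(simulateSkimReads(mf, 0L), "nPairs")
})
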