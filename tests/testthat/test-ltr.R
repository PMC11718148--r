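# helper: hand-build a genome string with one LTR element at a known spot
buildElementGenome <- function(ltrLen = 300L, interior = 2000L,
                               tsd = "ACGTG", pbsTrna = "tRNA-Met",
                               ltr3Divergence = 0, flankLen = 2500L) {
  ltr <- randSeq(ltrLen)
  substr(ltr, 1, 2) <- "TG"                       # canonical boundary motif
  substr(ltr, ltrLen - 1L, ltrLen) <- "CA"
  ltr3 <- if (ltr3Divergence > 0) mutated(ltr, ltr3Divergence) else ltr
  substr(ltr3, 1, 2) <- "TG"
  substr(ltr3, nchar(ltr3) - 1L, nchar(ltr3)) <- "CA"
  pbs <- revComp(trnaLibrary()[[pbsTrna]])
  motifs <- domainMotifLibrary()
  tek <- motifs[motifs$lineage == "Tekay", ]
  tek <- tek[match(domainOrder("Ty3/gypsy"), tek$domain), ]
  cds <- paste(vapply(tek$peptide, retroscribe:::encodePeptide, ""),
               collapse = "")
  spacer <- interior - nchar(pbs) - nchar(cds)
  stopifnot(spacer > 0)
  inner <- paste0(pbs, randSeq(spacer %/% 2), cds,
                  randSeq(spacer - spacer %/% 2))
  left <- randSeq(flankLen)
  right <- randSeq(flankLen)
  genome <- paste0(left, tsd, ltr, inner, ltr3, tsd, right)
  start0 <- flankLen + nchar(tsd)            # 0-based element start
  end0 <- start0 + ltrLen + nchar(inner) + nchar(ltr3)
  list(genome = genome, start = start0, end = end0, ltr = ltr,
       ltr3 = ltr3)
}

test_that("a planted complete element is found with its full structure", {
  set.seed(51)
  g <- buildElementGenome()
  gen <- Biostrings::DNAStringSet(c(chr = g$genome))
  el <- annotateLtrElements(gen)
  expect_equal(length(el), 1L)
  expect_equal(GenomicRanges::start(el) - 1L, g$start)
  expect_equal(GenomicRanges::end(el), g$end)
  expect_equal(el$ltr_identity, 100)
  expect_equal(el$ltr_len, 300L)
  expect_equal(el$tsd, "ACGTG")
  expect_equal(el$tsd_len, 5L)
  expect_equal(el$pbs, "tRNA-Met")
  expect_equal(el$lineage, "Tekay")
  expect_equal(el$superfamily, "Ty3/gypsy")
  expect_equal(el$completeness, "complete")
  expect_equal(strsplit(el$domains, ",")[[1]], domainOrder("Ty3/gypsy"))
})

test_that("LTR-pair identity matches a direct alignment oracle", {
  set.seed(52)
  g <- buildElementGenome(ltr3Divergence = 0.05)
  gen <- Biostrings::DNAStringSet(c(chr = g$genome))
  el <- annotateLtrElements(gen)
  expect_equal(length(el), 1L)
  oracle <- bsGlobalIdentity(g$ltr, g$ltr3)
  expect_lt(abs(el$ltr_identity - oracle), 1.5)

  g2 <- buildElementGenome(ltr3Divergence = 0.12)
  el2 <- annotateLtrElements(Biostrings::DNAStringSet(c(chr = g2$genome)))
  expect_equal(length(el2), 1L)
  expect_gt(el$ltr_identity, el2$ltr_identity)  # monotone in divergence
})

test_that("tandem satellite arrays yield no LTR candidates", {
  set.seed(53)
  mono <- randSeq(150)
  genome <- paste0(randSeq(2000), strrep(mono, 30), randSeq(2000))
  cand <- findLtrPairs(Biostrings::DNAStringSet(c(chr = genome)))
  expect_equal(nrow(cand), 0L)
})

test_that("TSD detection needs an exact 4-6 bp duplication", {
  set.seed(54)
  cs <- paste0(randSeq(100), "ACGTG", strrep("T", 50), "ACGTG",
               randSeq(100))
  # element = the T-run between the two ACGTG copies
  tsd <- detectTsd(cs, 105L, 155L)
  expect_equal(tsd$seq, "ACGTG")
  expect_equal(tsd$length, 5L)

  cs2 <- paste0(randSeq(100), "AAAA", strrep("T", 50), "CCCC",
                randSeq(100))
  expect_null(detectTsd(cs2, 104L, 154L))

  edge <- detectTsd("ACGTACGT", 2L, 6L)
  expect_true(isTRUE(edge$edge))
  expect_true(is.na(edge$length))
})

test_that("PBS detection honours the 12-bp / 1-mismatch boundary", {
  trna <- trnaLibrary()
  target <- revComp(trna[["tRNA-Lys"]])
  # exact 12/12 prefix match at offset 0 is accepted (boundary inclusive)
  region <- paste0(substr(target, 1, 12), randSeq(18))
  hit <- detectPbs(region)
  expect_equal(hit$trna, "tRNA-Lys")
  expect_gte(hit$length, 12L)

  set.seed(55)
  expect_null(detectPbs(randSeq(30)))

  # a full-length match with one mismatch still detects
  v <- strsplit(target, "")[[1]]
  v[9] <- setdiff(c("A", "C", "G", "T"), v[9])[1]
  hit2 <- detectPbs(paste0(paste(v, collapse = ""), randSeq(12)))
  expect_equal(hit2$trna, "tRNA-Lys")
})

test_that("completeness is the conjunction of LTR pair, PBS and TSD", {
  expect_equal(classifyCompleteness(TRUE, TRUE, TRUE), "complete")
  expect_equal(classifyCompleteness(TRUE, TRUE, FALSE), "incomplete")
  expect_equal(classifyCompleteness(TRUE, FALSE, TRUE), "incomplete")
  expect_equal(classifyCompleteness(FALSE, TRUE, TRUE), "incomplete")
  # toggling one component flips at most the completeness bit
  base <- classifyCompleteness(TRUE, TRUE, TRUE)
  for (k in 1:3) {
    args <- list(TRUE, TRUE, TRUE); args[[k]] <- FALSE
    expect_equal(do.call(classifyCompleteness, args), "incomplete")
  }
})

test_that("deleting the TSD from the genome flips the call to incomplete", {
  set.seed(56)
  g <- buildElementGenome(tsd = "GATTC")
  gen <- Biostrings::DNAStringSet(c(chr = g$genome))
  el <- annotateLtrElements(gen)
  expect_equal(el$completeness, "complete")
  # overwrite the right-flank TSD copy with a non-matching sequence
  broken <- g$genome
  substr(broken, g$end + 1L, g$end + 5L) <- "CCCCC"
  el2 <- annotateLtrElements(Biostrings::DNAStringSet(c(chr = broken)))
  expect_equal(el2$completeness, "incomplete")
  expect_true(is.na(el2$tsd))
  expect_equal(el2$pbs, "tRNA-Met")          # only the TSD bit changed
})

test_that("reverse-strand elements are detected with strand-aware calls", {
  set.seed(57)
  g <- buildElementGenome()
  rcGenome <- revComp(g$genome)
  el <- annotateLtrElements(Biostrings::DNAStringSet(c(chr = rcGenome)))
  expect_equal(length(el), 1L)
  expect_equal(el$completeness, "complete")
  expect_equal(el$lineage, "Tekay")
  expect_equal(as.character(GenomicRanges::strand(el)), "-")
  expect_equal(sort(strsplit(el$domains, ",")[[1]]),
               sort(domainOrder("Ty3/gypsy")))
})

test_that("genomic context separates intronic from intergenic elements", {
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1000, 1000, 2600, 10000, 10000, 10500),
                            c(3000, 1400, 3000, 11000, 10400, 11000)),
    strand = "+",
    type = c("gene", "exon", "exon", "gene", "exon", "exon"),
    gene = c("g1", "g1", "g1", "g2", "g2", "g2"))
  els <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(1500, 5000, 2900), c(2500, 6000, 3400)))
  ctx <- genomicContext(els, genes)
  expect_equal(ctx, c("intronic", "intergenic", "gene-adjacent"))
  expect_equal(genomicContext(els, NULL), rep("intergenic", 3))
})

test_that("planted elements in a synthetic genome are classified exactly
           on noise-free copies", {
  set.seed(58)
  sp <- repeatFamilySpec("el", "Ty3/gypsy", "Tekay", copyNumber = 10L,
                         unitLength = 3000L, perCopyDivergence = 0,
                         indelRate = 0,
                         structure = list(ltrLength = 250L,
                                          pbsTrna = "tRNA-Met",
                                          tsdLength = 5L),
                         incompleteFraction = 0.4)
  mf <- plantGenome(list(sp), 3e5, geneCount = 6L,
                    intronicLtrFraction = 0.5)
  el <- annotateLtrElements(manifestGenome(mf), genes = manifestGenes(mf))
  cp <- manifestCopies(mf)
  # sensitivity and precision 100%
  expect_equal(length(el), length(cp))
  ov <- GenomicRanges::findOverlaps(el, cp, type = "equal")
  expect_equal(length(ov), length(cp))
  hit <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  expect_equal(el$completeness == "complete", cp$complete[hit])
  expect_equal(el$context == "intronic",
               cp$context[hit] == "intronic")
})
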