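#' Number of read pairs for a requested genome coverage fraction
#'
#' Uses ceiling so a requested sampling fraction is never under-shot.
#'
#' @param genomeBases Genome length in bp.
#' @param coverage Requested fraction of the genome (e.g. 0.004 for 0.4\%).
#' @param readLength Read length in bp (default 151).
#' @return Integer number of read pairs.
#' @examples
#' pairsForCoverage(1e6, 0.004)  # 14
#' @export
pairsForCoverage <- function(genomeBases, coverage, readLength = 151L) {
  as.integer(ceiling(coverage * genomeBases / (2L * readLength)))
}

#' Simulate paired-end genome-skim reads
#'
#' Fragments are uniform over the genome (contigs weighted by length times
#' the family \code{copyFactor}, so organellar contigs can be
#' over-represented as in real skims); the fragment strand is sampled with
#' probability 0.5; substitution errors are applied at \code{errorRate}.
#' Read ids encode the true origin
#' (\code{skim<i>_<contig>_<start0>_<strand>}).
#'
#' @param manifest A \linkS4class{GroundTruthManifest} (or a plain
#'   \code{DNAStringSet} genome, in which case all contigs have weight 1).
#' @param nPairs Number of read pairs (> 0).
#' @param readLength Read length (default 151).
#' @param insertMean,insertSd Fragment length distribution (default 350/35).
#' @param errorRate Per-base substitution error rate (default 0.002).
#' @return List with \code{r1} and \code{r2} (\code{DNAStringSet} with a
#'   \code{quality} metadata column) and \code{origin} (data.frame: pair,
#'   contig, start, end — 0-based half-open fragment interval).
#' @export
simulateSkimReads <- function(manifest, nPairs, readLength = 151L,
                              insertMean = 350, insertSd = 35,
                              errorRate = 0.002) {
  if (nPairs <= 0) stop("nPairs must be > 0")
  if (is(manifest, "GroundTruthManifest")) {
    genome <- manifest@genome
    fam <- manifest@families
    cf <- setNames(rep(1, length(genome)), names(genome))
    sep <- fam$name[fam$separateContig]
    cf[sep] <- fam$copyFactor[fam$separateContig]
  } else {
    genome <- manifest
    cf <- setNames(rep(1, length(genome)), names(genome))
  }
  widths <- Biostrings::width(genome)
  if (any(widths < readLength)) {
    keep <- widths >= readLength
    genome <- genome[keep]; widths <- widths[keep]; cf <- cf[keep]
  }
  if (!length(genome)) stop("no contig is at least readLength long")
  w <- widths * cf[names(genome)]
  contigIdx <- sample.int(length(genome), nPairs, replace = TRUE,
                          prob = w / sum(w))
  ins <- pmin(pmax(round(rnorm(nPairs, insertMean, insertSd)),
                   readLength), widths[contigIdx])
  start0 <- floor(runif(nPairs) * (widths[contigIdx] - ins + 1))
  rev <- runif(nPairs) < 0.5

  seqs <- as.character(genome)
  frag <- substr(rep(seqs[contigIdx], 1L), start0 + 1L, start0 + ins)
  r1 <- substr(frag, 1L, readLength)
  r2 <- rcStrings(substr(frag, nchar(frag) - readLength + 1L, nchar(frag)))
  # reverse-strand fragments: swap mate roles
  tmp <- r1[rev]; r1[rev] <- r2[rev]; r2[rev] <- tmp

  r1 <- addReadErrors(r1, errorRate)
  r2 <- addReadErrors(r2, errorRate)

  ids <- sprintf("skim%07d_%s_%d_%s", seq_len(nPairs),
                 names(genome)[contigIdx], start0,
                 ifelse(rev, "m", "p"))
  mk <- function(x, mate) {
    ss <- Biostrings::DNAStringSet(x)
    names(ss) <- paste0(ids, "/", mate)
    S4Vectors::mcols(ss)$quality <- strrep("I", nchar(x))
    ss
  }
  list(r1 = mk(r1, 1L), r2 = mk(r2, 2L),
       origin = data.frame(pair = seq_len(nPairs),
                           contig = names(genome)[contigIdx],
                           start = start0, end = start0 + ins,
                           stringsAsFactors = FALSE))
}

#' Attribute simulated reads to planted families by true origin
#'
#' A fragment (or read) interval is attributed to a planted family when it
#' overlaps a planted copy by at least half the interval (or read length);
#' separate-contig families are attributed by contig; everything else is
#' \code{"background"}.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param origin Origin data.frame from the simulators (columns
#'   \code{contig}, \code{start}, \code{end}).
#' @return Character vector of family names / \code{"background"}.
#' @export
originFamily <- function(manifest, origin) {
  out <- rep("background", nrow(origin))
  sep <- manifest@families$name[manifest@families$separateContig]
  out[origin$contig %in% sep] <- origin$contig[origin$contig %in% sep]
  nuc <- which(!origin$contig %in% sep)
  if (length(nuc) && length(manifest@copies)) {
    gr <- GenomicRanges::GRanges(
      origin$contig[nuc],
      IRanges::IRanges(origin$start[nuc] + 1L, origin$end[nuc]))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, manifest@copies))
    if (length(ov)) {
      inter <- IRanges::pintersect(
        IRanges::ranges(gr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(manifest@copies)[S4Vectors::subjectHits(ov)])
      frac <- IRanges::width(inter) /
        IRanges::width(IRanges::ranges(gr)[S4Vectors::queryHits(ov)])
      ok <- frac >= 0.5
      hit <- S4Vectors::queryHits(ov)[ok]
      fams <- manifest@copies$family[S4Vectors::subjectHits(ov)[ok]]
      keep <- !duplicated(hit)
      out[nuc[hit[keep]]] <- fams[keep]
    }
  }
  out
}

#' Simulate an RNA-seq library with known repeat transcript proportions
#'
#' Poly-A libraries draw reads from spliced gene transcripts (intronic
#' repeat copies contribute only through a configurable intron-retention
#' rate on pre-mRNA) plus each family's \code{polyA} transcription weight.
#' Ribo-depleted libraries additionally draw reads from every nuclear
#' repeat family in proportion to its planted GP scaled by
#' \code{rddmGpCoupling} (emulating RdDM-pathway transcription), plus a
#' residual rRNA fraction from the rDNA family and the \code{ribodepleted}
#' transcription weights. The realized per-family read fractions are
#' returned as the expected-TP table.
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param libraryType \code{"polyA"} or \code{"ribodepleted"}.
#' @param nReads Number of reads.
#' @param readLength Read length (default 151).
#' @param residualRrnaFraction Fraction of ribo-depleted reads of rRNA
#'   origin that survived depletion (default 0.02; 0 for poly-A).
#' @param rddmGpCoupling Scale linking planted GP (percent) to the
#'   RdDM-transcript read fraction in ribo-depleted libraries: family
#'   fraction = coupling x plantedGP / 100 (default 0.05).
#' @param intronRetention Probability that a gene read is drawn from
#'   unspliced pre-mRNA (default 0.1).
#' @param errorRate Per-base substitution error rate (default 0.002).
#' @return List with \code{reads} (\code{DNAStringSet} with quality
#'   metadata), \code{origin} (per-read true source label), and
#'   \code{expectedTp} (data.frame: family, reads, fraction of library,
#'   expected TP percent after rRNA/organelle exclusion; plus gene and
#'   total rows in attribute \code{"other"}).
#' @export
simulateRnaLibrary <- function(manifest, libraryType = c("polyA",
                                                         "ribodepleted"),
                               nReads, readLength = 151L,
                               residualRrnaFraction = NULL,
                               rddmGpCoupling = 0.05,
                               intronRetention = 0.1, errorRate = 0.002) {
  libraryType <- match.arg(libraryType)
  if (nReads <= 0) stop("nReads must be > 0")
  fam <- manifest@families
  genome <- manifest@genome
  chrSeq <- as.character(genome[["chr1"]])
  if (is.null(residualRrnaFraction))
    residualRrnaFraction <- if (libraryType == "ribodepleted") 0.02 else 0

  w <- setNames(fam[[if (libraryType == "polyA") "weight_polyA"
                     else "weight_ribodepleted"]], fam$name)
  if (libraryType == "ribodepleted") {
    rd <- !fam$separateContig & fam$classLabel != "rDNA" &
      !is.na(fam$plantedGP)
    w[rd] <- w[rd] + rddmGpCoupling * fam$plantedGP[rd] / 100
  }
  # residual rRNA goes to the rDNA family
  rdna <- fam$name[fam$classLabel == "rDNA"]
  if (length(rdna)) w[rdna[1]] <- w[rdna[1]] + residualRrnaFraction
  if (sum(w) >= 1) stop("transcription weights sum to >= 1")
  geneW <- 1 - sum(w)

  probs <- c(w, gene = geneW)
  counts <- as.vector(rmultinom(1L, nReads, probs))
  names(counts) <- names(probs)

  # per-family transcript pools: realized copy sequences (element strand)
  copySeqsOf <- function(famName) {
    f <- fam[fam$name == famName, ]
    if (f$separateContig) return(as.character(genome[famName]))
    mine <- manifest@copies[manifest@copies$family == famName]
    if (!length(mine)) return(character(0))
    s <- as.character(Biostrings::extractAt(genome[["chr1"]],
                                            IRanges::ranges(mine)))
    neg <- as.character(GenomicRanges::strand(mine)) == "-"
    s[neg] <- rcStrings(s[neg])
    s
  }

  readsOut <- character(nReads)
  originOut <- character(nReads)
  ivContig <- character(nReads)
  ivStart <- integer(nReads)
  pos <- 0L

  drawWindows <- function(seqs, n) {
    lens <- nchar(seqs)
    ok <- lens >= readLength
    if (!any(ok)) return(NULL)
    seqs <- seqs[ok]; lens <- lens[ok]
    idx <- sample.int(length(seqs), n, replace = TRUE)
    st <- floor(runif(n) * (lens[idx] - readLength + 1))
    list(seq = substr(seqs[idx], st + 1L, st + readLength),
         idx = idx, start = st)
  }

  for (fn in names(w)) {
    nf <- counts[[fn]]
    if (nf == 0L) next
    pool <- copySeqsOf(fn)
    dw <- drawWindows(pool, nf)
    if (is.null(dw)) next
    sel <- pos + seq_len(nf)
    readsOut[sel] <- dw$seq
    originOut[sel] <- fn
    ivContig[sel] <- NA_character_
    pos <- pos + nf
  }

  # gene reads
  ng <- counts[["gene"]]
  genes <- manifest@genes
  geneNames <- unique(genes$gene[genes$type == "gene"])
  if (ng > 0L && length(geneNames)) {
    gidx <- sample(seq_along(geneNames), ng, replace = TRUE)
    preMrna <- runif(ng) < intronRetention
    exonsBy <- split(genes[genes$type == "exon"], genes$gene[genes$type == "exon"])
    for (gi in unique(gidx)) {
      sel <- which(gidx == gi)
      gn <- geneNames[gi]
      grange <- genes[genes$type == "gene" & genes$gene == gn]
      ex <- exonsBy[[gn]]
      ex <- ex[order(GenomicRanges::start(ex))]
      mrna <- paste(as.character(
        Biostrings::extractAt(genome[["chr1"]], IRanges::ranges(ex))),
        collapse = "")
      gspan <- as.character(Biostrings::extractAt(
        genome[["chr1"]], IRanges::ranges(grange)))[1]
      for (i in sel) {
        src <- if (preMrna[i]) gspan else mrna
        if (nchar(src) < readLength) src <- gspan
        if (nchar(src) < readLength) next
        st <- sample.int(nchar(src) - readLength + 1L, 1L) - 1L
        k <- pos + 1L
        readsOut[k] <- substr(src, st + 1L, st + readLength)
        originOut[k] <- "gene"
        if (preMrna[i]) {
          ivContig[k] <- "chr1"
          ivStart[k] <- GenomicRanges::start(grange) - 1L + st
        } else ivContig[k] <- NA_character_
        pos <- pos + 1L
      }
    }
  }

  readsOut <- readsOut[seq_len(pos)]
  originOut <- originOut[seq_len(pos)]
  ivContig <- ivContig[seq_len(pos)]
  ivStart <- ivStart[seq_len(pos)]

  # pre-mRNA reads overlapping a planted copy are repeat-origin
  pre <- which(!is.na(ivContig))
  if (length(pre)) {
    refam <- originFamily(manifest, data.frame(
      contig = ivContig[pre], start = ivStart[pre],
      end = ivStart[pre] + readLength))
    swap <- refam != "background"
    originOut[pre[swap]] <- refam[swap]
  }

  # random sequencing strand, then errors
  flip <- runif(length(readsOut)) < 0.5
  readsOut[flip] <- rcStrings(readsOut[flip])
  readsOut <- addReadErrors(readsOut, errorRate)

  ids <- sprintf("rna%07d_%s", seq_along(readsOut),
                 gsub("[^A-Za-z0-9]", ".", originOut))
  reads <- Biostrings::DNAStringSet(readsOut)
  names(reads) <- ids
  S4Vectors::mcols(reads)$quality <- strrep("I", nchar(readsOut))

  # expected-TP bookkeeping from realized origins
  tab <- table(originOut)
  excluded <- sum(tab[names(tab) %in%
                        c(fam$name[fam$separateContig],
                          fam$name[fam$classLabel == "rDNA"])])
  denom <- length(readsOut) - excluded
  famRows <- data.frame(
    family = fam$name,
    reads = as.integer(tab[fam$name]),
    stringsAsFactors = FALSE)
  famRows$reads[is.na(famRows$reads)] <- 0L
  famRows$fraction <- famRows$reads / length(readsOut)
  famRows$expected_tp <- ifelse(
    fam$separateContig | fam$classLabel == "rDNA", NA_real_,
    100 * famRows$reads / denom)
  geneReads <- if ("gene" %in% names(tab)) as.integer(tab[["gene"]]) else 0L
  other <- data.frame(
    family = c("gene", "total"),
    reads = c(geneReads, length(readsOut)),
    fraction = c(geneReads / length(readsOut), 1),
    expected_tp = c(NA_real_, NA_real_))
  attr(famRows, "other") <- other
  attr(famRows, "denominator") <- denom
  attr(famRows, "libraryType") <- libraryType

  list(reads = reads, origin = originOut, expectedTp = famRows)
}
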