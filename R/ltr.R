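# Structural annotation of LTR retroelements in an assembled (synthetic)
# genome: direct-repeat detection, TSD and PBS detection, protein-domain
# calls, completeness classification and genomic context. A deliberately
# simple detector for desk-scale genomes: no HMMs, no nested elements,
# no chimera resolution.

#' Find candidate LTR pairs by seeded self-comparison
#'
#' Shared 13-mers at a (near-)constant separation propose direct-repeat
#' runs; runs are refined by outward exact extension, and the two repeat
#' copies are globally aligned to give the LTR-pair identity. Candidates
#' must have an LTR length within \code{[minLtrLen, maxLtrLen]}, an
#' interior length within \code{interiorRange} and a pair identity of at
#' least \code{minPairIdentity}; overlapping candidates are resolved
#' greedily by genomic position. Tandem satellite arrays fail the
#' interior-range rule and rDNA-scale tandem units fail the LTR-length
#' rule, so neither is reported.
#'
#' @param genome \code{DNAStringSet}.
#' @param minLtrLen,maxLtrLen LTR length bounds (default 100 / 3000).
#' @param minPairIdentity Minimum percent identity between the two LTRs
#'   (default 80).
#' @param interiorRange Interior (between-LTR) length bounds in bp
#'   (default c(1000, 15000)).
#' @return data.frame of candidates: contig, start, end (0-based
#'   half-open element bounds), ltr5_start, ltr5_end, ltr3_start,
#'   ltr3_end (0-based half-open), ltr_len, ltr_identity.
#' @export
findLtrPairs <- function(genome, minLtrLen = 100L, maxLtrLen = 3000L,
                         minPairIdentity = 80, interiorRange = c(1000L, 15000L)) {
  out <- list()
  for (contig in names(genome)) {
    seqs <- as.character(genome[[contig]])
    n <- nchar(seqs)
    seeds <- .rs_self_repeat_seeds(seqs, 13L,
                                   interiorRange[1] + minLtrLen,
                                   interiorRange[2] + maxLtrLen, 64L)
    if (!nrow(seeds)) next
    sep <- seeds$pos2 - seeds$pos1
    o <- order(sep)
    sepBrk <- cumsum(c(TRUE, diff(sep[o]) > 15L))
    runs <- list()
    for (sg in unique(sepBrk)) {
      gi <- o[sepBrk == sg]
      gi <- gi[order(seeds$pos1[gi])]
      posBrk <- cumsum(c(TRUE, diff(seeds$pos1[gi]) > 60L))
      for (pg in unique(posBrk))
        runs[[length(runs) + 1L]] <- gi[posBrk == pg]
    }
    for (gi in runs) {
      p1 <- seeds$pos1[gi]; sp <- sep[gi]
      if (length(gi) < 2L && minLtrLen > 13L) next
      a <- min(p1)
      len <- max(p1) + 13L - a
      gsep <- as.integer(stats::median(sp))
      b <- a + gsep
      # outward exact extension of both repeat copies
      while (a > 0L && b > 0L &&
             substr(seqs, a, a) == substr(seqs, b, b)) {
        a <- a - 1L; b <- b - 1L
      }
      while (a + len < b && b + len < n &&
             substr(seqs, a + len + 1L, a + len + 1L) ==
             substr(seqs, b + len + 1L, b + len + 1L)) {
        len <- len + 1L
      }
      # snap to the canonical TG...CA LTR boundary motif when it lies
      # within a few bases of the maximal-repeat edge (flanking bases can
      # coincide by chance, making the maximal direct repeat slightly
      # longer than the LTR itself)
      runSeq <- substr(seqs, a + 1L, a + len)
      off <- regexpr("TG", substr(runSeq, 1L, 12L), fixed = TRUE)[1]
      if (off > 0L) {
        a <- a + off - 1L; b <- b + off - 1L; len <- len - off + 1L
        runSeq <- substr(runSeq, off, nchar(runSeq))
      }
      winStart <- max(1L, len - 11L)
      caHits <- gregexpr("CA", substr(runSeq, winStart, len),
                         fixed = TRUE)[[1]]
      if (caHits[1] > 0L) {
        oc <- winStart + max(caHits) - 1L    # 1-based start of last CA
        len <- oc + 1L
      }
      if (len < minLtrLen || len > maxLtrLen) next
      interior <- gsep - len
      if (interior < interiorRange[1] || interior > interiorRange[2]) next
      ltr5 <- substr(seqs, a + 1L, a + len)
      ltr3 <- substr(seqs, b + 1L, b + len)
      gid <- .rs_global_identity(ltr5, ltr3, 40L)
      if (!gid$ok || gid$identity < minPairIdentity) next
      # tandem-array guard: a true LTR is not followed by another copy of
      # itself inside the interior (satellite monomers are)
      follow <- substr(seqs, a + len + 1L, min(nchar(seqs), a + 2L * len))
      if (nchar(follow) >= 0.8 * len) {
        fid <- .rs_global_identity(ltr5, follow, 40L)
        if (fid$ok && fid$identity >= minPairIdentity) next
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = a, end = b + len,
        ltr5_start = a, ltr5_end = a + len,
        ltr3_start = b, ltr3_end = b + len,
        ltr_len = len, ltr_identity = gid$identity,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), ltr_len = integer(0),
                      ltr_identity = numeric(0)))
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$contig, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  lastEnd <- -1L; lastContig <- ""
  for (i in seq_len(nrow(cand))) {
    if (cand$contig[i] != lastContig || cand$start[i] >= lastEnd) {
      keep[i] <- TRUE
      lastEnd <- cand$end[i]; lastContig <- cand$contig[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Detect a target site duplication
#'
#' Reports the longest exact match of length 4-6 between the bases
#' immediately 5' of the element and immediately 3' of it; \code{NULL} if
#' no exact match of at least 4 bp exists. Elements closer than 6 bp to a
#' contig edge return \code{NULL} with attribute \code{edge = TRUE}.
#'
#' @param contigSeq Contig sequence (character).
#' @param start,end Element bounds, 0-based half-open.
#' @param lengths Candidate TSD lengths, longest tried first (default
#'   6:4).
#' @return List \code{(seq, length)} or \code{NULL}.
#' @export
detectTsd <- function(contigSeq, start, end, lengths = 6:4) {
  n <- nchar(contigSeq)
  if (start < max(lengths) || end + max(lengths) > n)
    return(list(seq = NA_character_, length = NA_integer_, edge = TRUE))
  for (l in sort(lengths, decreasing = TRUE)) {
    left <- substr(contigSeq, start - l + 1L, start)
    right <- substr(contigSeq, end + 1L, end + l)
    if (left == right) return(list(seq = left, length = l))
  }
  NULL
}

#' Detect a primer binding site
#'
#' Searches the \code{window} bases immediately internal to the 5' LTR for
#' a match of at least \code{minLen} bases (at most \code{maxMismatch}
#' mismatches) to the reverse complement of any tRNA 3'-terminal 18-mer
#' in the library. The longest (then cleanest) match wins.
#'
#' @param region The search region sequence (the \code{window} bases
#'   internal to the 5' LTR, already oriented in element reading
#'   direction).
#' @param trnaLib Named character vector of tRNA 18-mers (default
#'   \code{\link{trnaLibrary}}).
#' @param minLen Minimum match length (default 12).
#' @param maxMismatch Maximum mismatches (default 1).
#' @return List \code{(trna, length, mismatches, offset)} (offset 0-based
#'   within the region) or \code{NULL}.
#' @export
detectPbs <- function(region, trnaLib = trnaLibrary(), minLen = 12L,
                      maxMismatch = 1L) {
  if (!length(trnaLib)) stop("empty tRNA library")
  regionV <- strsplit(region, "", fixed = TRUE)[[1]]
  nr <- length(regionV)
  best <- NULL
  for (tn in names(trnaLib)) {
    targ <- strsplit(rcStrings(trnaLib[[tn]]), "", fixed = TRUE)[[1]]
    tl <- length(targ)
    for (L in seq(tl, minLen)) {
      for (off in 0:(tl - L)) {
        sub <- targ[(off + 1L):(off + L)]
        if (nr < L) next
        for (pos in 0:(nr - L)) {
          mm <- sum(sub != regionV[(pos + 1L):(pos + L)])
          if (mm <= maxMismatch) {
            if (is.null(best) || L > best$length ||
                (L == best$length && mm < best$mismatches)) {
              best <- list(trna = tn, length = L, mismatches = mm,
                           offset = pos)
            }
          }
        }
      }
      if (!is.null(best) && best$length >= L) break  # longest found
    }
  }
  best
}

#' Scan an element interior for protein-domain motifs
#'
#' Six-frame translation of the interior; each motif's best ungapped
#' peptide match is kept when at least \code{minIdentity} percent over the
#' motif length. The lineage call is the library lineage with the most
#' passing domains (ties or no hits give \code{"unclassified_LTR"}); the
#' element strand is the majority strand of the passing hits. The
#' expected genomic domain order of the called superfamily is attached as
#' a consistency annotation, not used as a filter.
#'
#' @param interiorSeq Interior sequence (between the LTRs).
#' @param motifLib data.frame from \code{\link{domainMotifLibrary}}.
#' @param minIdentity Percent identity threshold (default 60).
#' @return List: \code{domains} (data.frame name, lineage, start, end,
#'   strand, identity — coordinates 0-based half-open on the interior, in
#'   genomic order), \code{lineage}, \code{superfamily}, \code{strand},
#'   \code{orderConsistent}.
#' @export
detectDomains <- function(interiorSeq, motifLib = domainMotifLibrary(),
                          minIdentity = 60) {
  sc <- .rs_domain_scan(interiorSeq, motifLib$peptide)
  hit <- which(sc$identity >= minIdentity)
  if (!length(hit))
    return(list(domains = data.frame(), lineage = "unclassified_LTR",
                superfamily = "unclassified_LTR", strand = "*",
                orderConsistent = NA))
  dom <- data.frame(
    name = motifLib$domain[hit], lineage = motifLib$lineage[hit],
    superfamily = motifLib$superfamily[hit],
    start = sc$start[hit], end = sc$end[hit],
    strand = ifelse(sc$strand[hit] == 1L, "+", "-"),
    identity = sc$identity[hit], stringsAsFactors = FALSE)
  dom <- dom[order(dom$start), , drop = FALSE]
  votes <- table(dom$lineage)
  top <- names(votes)[votes == max(votes)]
  if (length(top) != 1L) {
    lineage <- "unclassified_LTR"; superfamily <- "unclassified_LTR"
  } else {
    lineage <- top
    superfamily <- motifLib$superfamily[match(top, motifLib$lineage)]
  }
  strand <- names(sort(table(dom$strand), decreasing = TRUE))[1]
  orderConsistent <- NA
  if (superfamily %in% names(.DOMAIN_ORDER)) {
    expOrd <- domainOrder(superfamily)
    got <- dom$name[dom$lineage == lineage]
    if (strand == "-") got <- rev(got)
    orderConsistent <- identical(got[got %in% expOrd],
                                 expOrd[expOrd %in% got])
  }
  list(domains = dom, lineage = lineage, superfamily = superfamily,
       strand = strand, orderConsistent = orderConsistent)
}

#' Classify an element as complete or incomplete
#'
#' An element is complete exactly when all three structural components
#' are present: the LTR pair, a PBS and a TSD.
#'
#' @param hasLtrPair,hasPbs,hasTsd Logicals.
#' @return \code{"complete"} or \code{"incomplete"}.
#' @export
classifyCompleteness <- function(hasLtrPair, hasPbs, hasTsd) {
  ifelse(hasLtrPair & hasPbs & hasTsd, "complete", "incomplete")
}

#' Genomic context of elements relative to gene models
#'
#' Introns are the per-gene gaps between consecutive exons. An element
#' fully inside one intron is \code{intronic}; otherwise, overlapping any
#' gene makes it \code{gene-adjacent}; otherwise \code{intergenic}. Genes
#' without exon records are treated as single-exon (no introns).
#'
#' @param elements \code{GRanges} of elements.
#' @param genes \code{GRanges} with \code{type} (\code{gene}/\code{exon})
#'   and \code{gene} metadata columns, or \code{NULL}.
#' @return Character vector of contexts parallel to \code{elements}.
#' @export
genomicContext <- function(elements, genes) {
  ctx <- rep("intergenic", length(elements))
  if (is.null(genes) || !length(genes)) return(ctx)
  geneR <- genes[genes$type == "gene"]
  exons <- genes[genes$type == "exon"]
  intronL <- list()
  for (gn in unique(geneR$gene)) {
    ex <- exons[exons$gene == gn]
    if (length(ex) < 2L) next
    gr <- GenomicRanges::reduce(geneR[geneR$gene == gn])
    intr <- GenomicRanges::setdiff(gr, ex, ignore.strand = TRUE)
    if (length(intr)) intronL[[gn]] <- intr
  }
  introns <- if (length(intronL))
    suppressWarnings(do.call(c, unname(intronL))) else GenomicRanges::GRanges()
  if (length(introns)) {
    within <- GenomicRanges::findOverlaps(elements, introns,
                                          type = "within",
                                          ignore.strand = TRUE)
    ctx[unique(S4Vectors::queryHits(within))] <- "intronic"
  }
  other <- which(ctx != "intronic")
  if (length(other) && length(geneR)) {
    ov <- GenomicRanges::findOverlaps(elements[other], geneR,
                                      ignore.strand = TRUE)
    ctx[other[unique(S4Vectors::queryHits(ov))]] <- "gene-adjacent"
  }
  ctx
}

#' Full structural annotation of LTR retroelements
#'
#' Runs the detector chain — LTR-pair finding, TSD detection, PBS
#' detection (trying both element orientations), domain scan and lineage
#' call, completeness classification, genomic context — over a genome.
#'
#' @param genome \code{DNAStringSet}.
#' @param genes Optional gene \code{GRanges} (see
#'   \code{\link{genomicContext}}).
#' @param trnaLib,motifLib Fixture libraries.
#' @param minLtrLen,maxLtrLen,minPairIdentity,interiorRange See
#'   \code{\link{findLtrPairs}}.
#' @param pbsWindow Bases internal to the 5' LTR searched for the PBS
#'   (default 30).
#' @return \code{GRanges} of elements with metadata: element_id,
#'   ltr5_start/ltr5_end/ltr3_start/ltr3_end (0-based half-open),
#'   ltr_identity, pbs, tsd, tsd_len, domains, lineage, superfamily,
#'   completeness, context, order_consistent.
#' @export
annotateLtrElements <- function(genome, genes = NULL,
                                trnaLib = trnaLibrary(),
                                motifLib = domainMotifLibrary(),
                                minLtrLen = 100L, maxLtrLen = 3000L,
                                minPairIdentity = 80,
                                interiorRange = c(1000L, 15000L),
                                pbsWindow = 30L) {
  cand <- findLtrPairs(genome, minLtrLen, maxLtrLen, minPairIdentity,
                       interiorRange)
  if (!nrow(cand)) return(GenomicRanges::GRanges())
  seqsCache <- lapply(as.list(as.character(genome)), identity)

  n <- nrow(cand)
  pbsName <- character(n); pbsLen <- integer(n)
  tsdSeq <- character(n); tsdLen <- integer(n)
  domStr <- character(n); lineage <- character(n); superf <- character(n)
  strand <- character(n); complete <- character(n); ordCons <- logical(n)
  for (i in seq_len(n)) {
    cs <- seqsCache[[cand$contig[i]]]
    tsd <- detectTsd(cs, cand$start[i], cand$end[i])
    if (!is.null(tsd) && is.na(tsd$length)) tsd <- NULL  # contig edge
    tsdSeq[i] <- if (is.null(tsd)) NA_character_ else tsd$seq
    tsdLen[i] <- if (is.null(tsd)) NA_integer_ else tsd$length

    # PBS: plus orientation = just after the left LTR; minus = just
    # before the right LTR, reverse-complemented
    regPlus <- substr(cs, cand$ltr5_end[i] + 1L,
                      min(nchar(cs), cand$ltr5_end[i] + pbsWindow))
    pb <- detectPbs(regPlus, trnaLib)
    pbStrand <- "+"
    if (is.null(pb)) {
      regMinus <- rcStrings(substr(cs, max(1L, cand$ltr3_start[i] - pbsWindow + 1L),
                                   cand$ltr3_start[i]))
      pb <- detectPbs(regMinus, trnaLib)
      pbStrand <- "-"
    }
    pbsName[i] <- if (is.null(pb)) NA_character_ else pb$trna
    pbsLen[i] <- if (is.null(pb)) NA_integer_ else pb$length

    interior <- substr(cs, cand$ltr5_end[i] + 1L, cand$ltr3_start[i])
    dd <- detectDomains(interior, motifLib)
    lineage[i] <- dd$lineage
    superf[i] <- dd$superfamily
    ordCons[i] <- isTRUE(dd$orderConsistent)
    strand[i] <- if (dd$strand %in% c("+", "-")) dd$strand
      else if (!is.null(pb)) pbStrand else "*"
    domStr[i] <- paste(dd$domains$name, collapse = ",")
    complete[i] <- classifyCompleteness(TRUE, !is.null(pb), !is.null(tsd))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = cand$contig,
    ranges = IRanges::IRanges(start = cand$start + 1L, end = cand$end),
    strand = strand,
    element_id = sprintf("TE_%05d", seq_len(n)),
    ltr5_start = cand$ltr5_start, ltr5_end = cand$ltr5_end,
    ltr3_start = cand$ltr3_start, ltr3_end = cand$ltr3_end,
    ltr_len = cand$ltr_len, ltr_identity = cand$ltr_identity,
    pbs = pbsName, pbs_len = pbsLen, tsd = tsdSeq, tsd_len = tsdLen,
    domains = domStr, lineage = lineage, superfamily = superf,
    completeness = complete, order_consistent = ordCons)
  gr$context <- genomicContext(gr, genes)
  gr
}
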