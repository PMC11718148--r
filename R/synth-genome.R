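#' Ground-truth manifest of a synthetic genome
#'
#' Records everything the generator planted: per-family genome proportions,
#' empirical expected pairwise identity and realized GC, every planted copy
#' as a genomic range with structural-completeness flags and genomic
#' context, and the generated gene models.
#'
#' @slot genome \code{DNAStringSet}: nuclear contig(s) plus any organellar
#'   contigs.
#' @slot families data.frame, one row per family (name, classLabel,
#'   lineage, copyNumber, unitLength, plantedBases, plantedGP,
#'   expectedIdentity, realizedGC, weight_polyA, weight_ribodepleted,
#'   copyFactor, separateContig).
#' @slot copies \code{GRanges} of planted copies with metadata columns
#'   \code{family}, \code{complete}, \code{has_pbs}, \code{has_tsd},
#'   \code{tsd}, \code{context}, \code{ltrLength}.
#' @slot genes \code{GRanges} of gene and exon features (final
#'   coordinates).
#' @slot nuclearBases Total nuclear genome length (denominator of planted
#'   GP; organellar contigs excluded, mirroring the GP estimator).
#' @slot params List of generator parameters.
#' @export
setClass("GroundTruthManifest", representation(
  genome = "DNAStringSet", families = "data.frame", copies = "GRanges",
  genes = "GRanges", nuclearBases = "numeric", params = "list"
))

setValidity("GroundTruthManifest", function(object) {
  msgs <- character(0)
  if (nrow(object@families) &&
      sum(object@families$plantedGP[!object@families$separateContig]) > 100)
    msgs <- c(msgs, "planted GP values exceed 100%")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat("GroundTruthManifest:", length(object@genome), "contig(s),",
      sum(Biostrings::width(object@genome)), "bp;",
      nrow(object@families), "families,",
      length(object@copies), "planted copies\n")
})

#' Accessors for GroundTruthManifest
#' @param x A \linkS4class{GroundTruthManifest}.
#' @return \code{manifestFamilies}: the per-family truth table;
#'   \code{manifestCopies}: planted copies as \code{GRanges};
#'   \code{manifestGenome}: the genome \code{DNAStringSet};
#'   \code{manifestGenes}: gene/exon features.
#' @export
manifestFamilies <- function(x) x@families
#' @rdname manifestFamilies
#' @export
manifestCopies <- function(x) x@copies
#' @rdname manifestFamilies
#' @export
manifestGenome <- function(x) x@genome
#' @rdname manifestFamilies
#' @export
manifestGenes <- function(x) x@genes

# generate non-overlapping gene models over background coordinates.
# Returns list(genes = df(gene, start, end), exons = df(gene, start, end)).
generateGeneModels <- function(backgroundLength, geneCount) {
  genes <- list(); exons <- list()
  occupied <- IRanges::IRanges()
  tries <- 0L
  g <- 0L
  while (g < geneCount && tries < geneCount * 50L) {
    tries <- tries + 1L
    nEx <- sample(2:4, 1L)
    exLen <- sample(150:400, nEx, replace = TRUE)
    inLen <- if (nEx > 1L) sample(300:1500, nEx - 1L, replace = TRUE) else integer(0)
    total <- sum(exLen) + sum(inLen)
    if (total + 200L >= backgroundLength) next
    s <- sample.int(backgroundLength - total - 100L, 1L) + 50L
    cand <- IRanges::IRanges(s, s + total - 1L)
    if (length(IRanges::findOverlaps(cand, occupied, maxgap = 100L))) next
    occupied <- c(occupied, cand)
    g <- g + 1L
    gname <- paste0("gene", g)
    genes[[g]] <- data.frame(gene = gname, start = s - 1L,
                             end = s - 1L + total)
    pos <- s - 1L
    exl <- list()
    for (i in seq_len(nEx)) {
      exl[[i]] <- data.frame(gene = gname, start = pos, end = pos + exLen[i])
      pos <- pos + exLen[i] + if (i < nEx) inLen[i] else 0L
    }
    exons[[g]] <- do.call(rbind, exl)
  }
  if (g < geneCount)
    warning("placed only ", g, " of ", geneCount, " genes")
  list(genes = do.call(rbind, genes) %||% data.frame(),
       exons = do.call(rbind, exons) %||% data.frame())
}

#' Plant repeat families into a synthetic genome
#'
#' Builds a random nuclear background of the requested length and GC,
#' generates gene models, then inserts mutated copies of each family master
#' at uniform-random non-overlapping positions (a configurable fraction of
#' LTR-family copies goes inside introns), flanked by a target site
#' duplication unless the copy is flagged incomplete-without-TSD. Families
#' with \code{separateContig = TRUE} (organelle) become their own contigs.
#' Planted GP per family is (family bases) / (nuclear genome bases) x 100;
#' expected pairwise identity is computed empirically by global alignment
#' over sampled pairs of realized copies.
#'
#' @param specs List of \linkS4class{RepeatFamilySpec}.
#' @param backgroundLength Nuclear background length in bp.
#' @param backgroundGC Background GC fraction (default 0.42).
#' @param geneCount Number of gene models to generate.
#' @param intronicLtrFraction Fraction of LTR-superfamily copies inserted
#'   inside introns (default 0.3).
#' @param maxIdentityPairs Per family, the maximum number of copy pairs
#'   sampled for the empirical expected-identity estimate (default 40).
#' @return A \linkS4class{GroundTruthManifest}.
#' @export
plantGenome <- function(specs, backgroundLength, backgroundGC = 0.42,
                        geneCount = 20L, intronicLtrFraction = 0.3,
                        maxIdentityPairs = 40L) {
  nuclear <- !vapply(specs, function(s) s@separateContig, TRUE)
  totalPlanted <- sum(vapply(specs[nuclear], function(s)
    as.numeric(s@copyNumber) * s@unitLength, 0))
  if (totalPlanted >= backgroundLength)
    stop("total planted bases (", totalPlanted,
         ") must be below backgroundLength (", backgroundLength, ")")

  background <- randomSeqExactGC(backgroundLength,
                                 backgroundGC * backgroundLength)
  gm <- generateGeneModels(backgroundLength, geneCount)

  introns <- data.frame()
  if (nrow(gm$exons)) {
    for (gn in unique(gm$exons$gene)) {
      ex <- gm$exons[gm$exons$gene == gn, ]
      ex <- ex[order(ex$start), ]
      if (nrow(ex) > 1L)
        introns <- rbind(introns, data.frame(
          gene = gn, start = head(ex$end, -1L), end = tail(ex$start, -1L)))
    }
  }
  geneIv <- if (nrow(gm$genes))
    IRanges::IRanges(gm$genes$start + 1L, gm$genes$end) else IRanges::IRanges()

  # --- choose insertion anchors -------------------------------------------
  masters <- lapply(specs, buildFamilyMaster)
  names(masters) <- vapply(specs, function(s) s@name, "")

  insertions <- list()   # anchor (0-based bg coord), block, element offset/len
  usedAnchors <- integer(0)
  margin <- 30L
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    if (spec@separateContig) next
    master <- masters[[si]]
    isLtr <- spec@classLabel %in% c("Ty1/copia", "Ty3/gypsy",
                                    "unclassified_LTR") &&
      !is.null(spec@structure$ltrLength)
    pbsFeat <- master$features[master$features$kind == "PBS", ]
    for (ci in seq_len(spec@copyNumber)) {
      incomplete <- runif(1) < spec@incompleteFraction
      mode <- if (incomplete)
        sample(c("pbs", "tsd", "both"), 1L, prob = c(0.4, 0.4, 0.2)) else "none"
      hasPbs <- isLtr && !(mode %in% c("pbs", "both"))
      hasTsd <- !(mode %in% c("tsd", "both"))
      copySeq <- master$seq
      if (isLtr && !hasPbs && nrow(pbsFeat)) {
        # overwrite the PBS with random sequence of the same length
        pl <- pbsFeat$end[1] - pbsFeat$start[1]
        substr(copySeq, pbsFeat$start[1] + 1L, pbsFeat$end[1]) <-
          randomSeqExactGC(pl, spec@gcTarget * pl)
      }
      copySeq <- mutateSeq(copySeq, spec@perCopyDivergence, spec@indelRate)
      strand <- if (runif(1) < 0.5) "+" else "-"
      oriented <- if (strand == "+") copySeq else rcStrings(copySeq)
      if (hasTsd) {
        tl <- sample(4:6, 1L)
        tsd <- randomSeqExactGC(tl, round(0.5 * tl))
        block <- paste0(tsd, oriented, tsd)
        padLen <- tl
      } else {
        # guard pads guarantee no accidental exact 4-6 bp flank match
        tsd <- ""
        block <- paste0("ACACAC", oriented, "GTGTGT")
        padLen <- 6L
      }

      intronic <- isLtr && nrow(introns) > 0 && runif(1) < intronicLtrFraction
      anchor <- NA_integer_
      for (try in 1:200) {
        if (intronic) {
          iv <- introns[sample.int(nrow(introns), 1L), ]
          if (iv$end - iv$start < 2L * margin) next
          a <- sample((iv$start + margin):(iv$end - margin), 1L)
        } else {
          a <- sample.int(backgroundLength - 2L * margin, 1L) + margin
          # keep non-intronic copies out of genes entirely
          if (length(geneIv) &&
              length(IRanges::findOverlaps(IRanges::IRanges(a, a), geneIv)))
            next
        }
        if (any(abs(usedAnchors - a) < margin)) next
        anchor <- a
        break
      }
      if (is.na(anchor))
        stop("could not place copy ", ci, " of family ", spec@name,
             " without overlap after bounded retries")
      usedAnchors <- c(usedAnchors, anchor)
      insertions[[length(insertions) + 1L]] <- list(
        anchor = anchor, block = block, family = spec@name,
        elementOffset = padLen, elementLen = nchar(oriented),
        strand = strand, hasPbs = hasPbs, hasTsd = hasTsd, tsd = tsd,
        hasLtrPair = isLtr,
        complete = isLtr && hasPbs && hasTsd,
        context = if (intronic) "intronic" else "intergenic",
        ltrLength = if (isLtr) spec@structure$ltrLength else NA_integer_)
    }
  }

  # --- assemble the nuclear contig ----------------------------------------
  ord <- order(vapply(insertions, function(x) x$anchor, 0L))
  insertions <- insertions[ord]
  anchors <- vapply(insertions, function(x) x$anchor, 0L)
  blockLens <- vapply(insertions, function(x) nchar(x$block), 0L)
  pieces <- character(2L * length(insertions) + 1L)
  prev <- 0L
  finalStarts <- integer(length(insertions))
  shift <- 0L
  for (i in seq_along(insertions)) {
    pieces[2L * i - 1L] <- substr(background, prev + 1L, anchors[i])
    pieces[2L * i] <- insertions[[i]]$block
    finalStarts[i] <- anchors[i] + shift
    shift <- shift + blockLens[i]
    prev <- anchors[i]
  }
  pieces[2L * length(insertions) + 1L] <-
    substr(background, prev + 1L, backgroundLength)
  chr <- paste(pieces, collapse = "")

  # shift of any background coordinate x: blocks with anchor <= x
  cumLens <- cumsum(blockLens)
  shiftOf <- function(x) {
    idx <- findInterval(x, anchors)
    out <- integer(length(x))
    out[idx > 0L] <- cumLens[idx[idx > 0L]]
    out
  }

  contigs <- c(chr1 = chr)
  for (si in seq_along(specs)) {
    if (specs[[si]]@separateContig)
      contigs[[specs[[si]]@name]] <- masters[[si]]$seq
  }
  genome <- Biostrings::DNAStringSet(contigs)

  # --- copies GRanges ------------------------------------------------------
  copies <- if (length(insertions)) GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      start = finalStarts + vapply(insertions, function(x) x$elementOffset, 0L) + 1L,
      width = vapply(insertions, function(x) x$elementLen, 0L)),
    strand = vapply(insertions, function(x) x$strand, ""),
    family = vapply(insertions, function(x) x$family, ""),
    complete = vapply(insertions, function(x) x$complete, TRUE),
    has_ltr_pair = vapply(insertions, function(x) x$hasLtrPair, TRUE),
    has_pbs = vapply(insertions, function(x) x$hasPbs, TRUE),
    has_tsd = vapply(insertions, function(x) x$hasTsd, TRUE),
    tsd = vapply(insertions, function(x) x$tsd, ""),
    context = vapply(insertions, function(x) x$context, ""),
    ltrLength = vapply(insertions, function(x)
      as.integer(x$ltrLength %||% NA_integer_), 1L)
  ) else GenomicRanges::GRanges()

  # --- genes GRanges in final coordinates ----------------------------------
  genes <- GenomicRanges::GRanges()
  if (nrow(gm$genes)) {
    gdf <- rbind(
      data.frame(kind = "gene", gene = gm$genes$gene,
                 start = gm$genes$start, end = gm$genes$end),
      data.frame(kind = "exon", gene = gm$exons$gene,
                 start = gm$exons$start, end = gm$exons$end))
    genes <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = gdf$start + shiftOf(gdf$start) + 1L,
                                end = gdf$end + shiftOf(gdf$end)),
      strand = "+", type = gdf$kind, gene = gdf$gene)
  }

  # --- per-family truth table ----------------------------------------------
  nuclearBases <- nchar(chr)
  fam <- lapply(specs, function(spec) {
    mine <- copies[copies$family == spec@name]
    if (spec@separateContig) {
      seqsC <- as.character(genome[spec@name])
      plantedBases <- 0
      gp <- NA_real_
      gcp <- 100 * sum(.rs_base_counts(seqsC)[c("G", "C")]) / nchar(seqsC)
      expId <- NA_real_
    } else {
      seqsC <- as.character(Biostrings::extractAt(
        genome[["chr1"]], IRanges::ranges(mine)))
      neg <- as.character(GenomicRanges::strand(mine)) == "-"
      seqsC[neg] <- rcStrings(seqsC[neg])
      plantedBases <- sum(nchar(seqsC))
      gp <- 100 * plantedBases / nuclearBases
      bc <- .rs_base_counts(seqsC)
      gcp <- 100 * sum(bc[c("G", "C")]) / sum(bc[c("A", "C", "G", "T")])
      expId <- NA_real_
      if (length(seqsC) >= 2L) {
        prs <- utils::combn(length(seqsC), 2L)
        if (ncol(prs) > maxIdentityPairs)
          prs <- prs[, sample.int(ncol(prs), maxIdentityPairs), drop = FALSE]
        band <- max(60L, ceiling(4 * spec@indelRate * spec@unitLength) + 40L)
        expId <- .rs_mean_pairwise_global_identity(
          seqsC, prs[1, ], prs[2, ], band)
      }
    }
    data.frame(
      name = spec@name, classLabel = spec@classLabel,
      lineage = spec@lineage, copyNumber = spec@copyNumber,
      unitLength = spec@unitLength, plantedBases = plantedBases,
      plantedGP = gp, expectedIdentity = expId, realizedGC = gcp,
      weight_polyA = unname(spec@transcriptionWeight["polyA"]),
      weight_ribodepleted = unname(spec@transcriptionWeight["ribodepleted"]),
      copyFactor = spec@copyFactor, separateContig = spec@separateContig,
      stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, fam)

  new("GroundTruthManifest", genome = genome, families = families,
      copies = copies, genes = genes, nuclearBases = as.numeric(nuclearBases),
      params = list(backgroundLength = backgroundLength,
                    backgroundGC = backgroundGC, geneCount = geneCount,
                    intronicLtrFraction = intronicLtrFraction,
                    masters = masters))
}
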