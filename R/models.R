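#' Fit a linear model of transcript proportion on a genomic predictor
#'
#' Ordinary least squares of TP on GP, GC or modal similarity, optionally
#' log10-transforming the response, the predictor or both. Rows with zero
#' TP are dropped (and counted) whenever the response is
#' log-transformed; untransformed fits keep zeros.
#'
#' @param table data.frame holding the response and predictor columns.
#' @param predictor Column name of the predictor (\code{"gp"},
#'   \code{"gc_percent"} or \code{"modal_similarity"}).
#' @param response Column name of the response (default \code{"tp"}).
#' @param transform One of \code{"none"}, \code{"log10-response"},
#'   \code{"log10-both"}.
#' @param group Optional label stored in the result.
#' @return One-row data.frame: group, predictor, transform, n_used,
#'   n_excluded_zero, slope, intercept, adj_r2, p_value. \code{NULL} (with
#'   a message) when fewer than 3 usable rows remain.
#' @export
fitTpModel <- function(table, predictor, response = "tp",
                       transform = c("none", "log10-response",
                                     "log10-both"),
                       group = "") {
  transform <- match.arg(transform)
  y <- table[[response]]
  x <- table[[predictor]]
  ok <- !is.na(y) & !is.na(x)
  nZero <- 0L
  if (transform != "none") {
    zero <- ok & y <= 0
    nZero <- sum(zero)
    ok <- ok & y > 0
  }
  if (transform == "log10-both") ok <- ok & x > 0
  x <- x[ok]; y <- y[ok]
  if (transform != "none") y <- log10(y)
  if (transform == "log10-both") x <- log10(x)
  if (length(y) < 3L) {
    message("fit skipped (", group, ", ", predictor, "): fewer than 3 rows")
    return(NULL)
  }
  fit <- lm(y ~ x)
  # exact proportionality is a legitimate input here; summary.lm warns
  # about "essentially perfect" fits, which is the expected case
  sm <- suppressWarnings(summary(fit))
  adjr2 <- sm$adj.r.squared
  if (!is.finite(adjr2) || var(y) < .Machine$double.eps) adjr2 <- 0
  pv <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  data.frame(group = group, predictor = predictor, transform = transform,
             n_used = length(y), n_excluded_zero = nZero,
             slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             adj_r2 = adjr2, p_value = pv,
             stringsAsFactors = FALSE)
}

# compact letter display from an adjusted p-value matrix at alpha:
# insert-absorb algorithm over the "not significantly different" relation
.letterDisplay <- function(pmat, alpha = 0.05) {
  gs <- rownames(pmat)
  k <- length(gs)
  if (k == 1L) return(setNames("a", gs))
  same <- !is.na(pmat) & pmat >= alpha
  diag(same) <- TRUE
  same[is.na(pmat)] <- TRUE
  # start with one group containing everything, then split on conflicts
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (same[i, j]) next
      newSets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          newSets <- c(newSets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else newSets <- c(newSets, list(s))
      }
      # absorb duplicated / contained sets
      newSets <- newSets[!duplicated(lapply(newSets, sort))]
      keep <- rep(TRUE, length(newSets))
      for (a in seq_along(newSets)) for (b in seq_along(newSets)) {
        if (a != b && keep[a] && all(newSets[[a]] %in% newSets[[b]]))
          keep[a] <- FALSE
      }
      sets <- newSets[keep]
    }
  }
  lets <- letters[seq_along(sets)]
  out <- vapply(seq_len(k), function(i)
    paste(lets[vapply(sets, function(s) i %in% s, TRUE)], collapse = ""),
    "")
  setNames(out, gs)
}

#' Tukey multiple comparison of group means with letter display
#'
#' One-way ANOVA followed by Tukey's HSD over all group pairs at
#' \code{alpha}; groups with fewer than 2 observations are excluded from
#' the test and listed separately. The compact letter display assigns the
#' same letter to groups that are not significantly different.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (e.g. repeat lineage), parallel to
#'   \code{values}.
#' @param alpha Significance level (default 0.05).
#' @return List: \code{pmat} (matrix of adjusted p-values),
#'   \code{letters} (named letter display), \code{excluded} (group names
#'   with < 2 observations), \code{anova_p}.
#' @export
tukeyMeans <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2L]
  keep <- !(groups %in% excluded)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups with >= 2 observations")
  if (stats::var(values) == 0) {
    # identical values everywhere: nothing differs
    gs <- levels(groups)
    pmat <- matrix(1, nlevels(groups), nlevels(groups),
                   dimnames = list(gs, gs))
    return(list(pmat = pmat, letters = setNames(rep("a", length(gs)), gs),
                excluded = excluded, anova_p = NA_real_))
  }
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  gs <- levels(groups)
  pmat <- matrix(NA_real_, length(gs), length(gs),
                 dimnames = list(gs, gs))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(prs)) {
    a <- prs[[i]][1]; b <- prs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(pmat = pmat, letters = .letterDisplay(pmat, alpha),
       excluded = excluded, anova_p = anovaP)
}

#' Recovery report against the ground-truth manifest
#'
#' Per planted family: planted vs estimated GP (relative error), planted
#' vs estimated TP per library, modal similarity vs the manifest's
#' empirical expected pairwise identity, and whether the family was
#' recovered at all (families whose expected cluster size falls below the
#' top-cluster threshold are reported as not detected, not as errors).
#'
#' @param manifest A \linkS4class{GroundTruthManifest}.
#' @param clusterDf Annotated cluster table with \code{gp},
#'   \code{modal_similarity}, \code{lineage}, \code{classLabel}.
#' @param clusterFamily Named map cluster_id -> family name (e.g. from
#'   annotation against \code{\link{referenceLibrary}}, whose reference
#'   ids are the family names).
#' @param tpTables Optional named list (per library id) of per-cluster TP
#'   tables from \code{\link{transcriptProportion}} plus attributes; each
#'   entry must be a data.frame with \code{cluster_id} and \code{tp}.
#' @param expectedTp Optional named list (per library id) of expected-TP
#'   tables from \code{\link{simulateRnaLibrary}}.
#' @return data.frame, one row per (family, quantity) with planted,
#'   estimated and relative error columns.
#' @export
recoveryReport <- function(manifest, clusterDf, clusterFamily,
                           tpTables = NULL, expectedTp = NULL) {
  fam <- manifest@families
  rows <- list()
  add <- function(family, quantity, planted, estimated, note = "") {
    rel <- if (!is.na(planted) && planted != 0 && !is.na(estimated))
      abs(estimated - planted) / abs(planted) else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, quantity = quantity, planted = planted,
      estimated = estimated, rel_error = rel, note = note,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(fam))) {
    fn <- fam$name[i]
    if (fam$separateContig[i]) next
    cls <- names(clusterFamily)[clusterFamily == fn]
    sub <- clusterDf[clusterDf$cluster_id %in% cls, , drop = FALSE]
    if (!nrow(sub)) {
      add(fn, "gp", fam$plantedGP[i], NA_real_,
          "not detected (below cluster size threshold)")
      next
    }
    add(fn, "gp", fam$plantedGP[i], sum(sub$gp, na.rm = TRUE))
    if (!is.na(fam$expectedIdentity[i]))
      add(fn, "modal_similarity", fam$expectedIdentity[i],
          max(sub$modal_similarity, na.rm = TRUE))
    add(fn, "gc_percent", fam$realizedGC[i],
        sum(sub$gc_percent * sub$size) / sum(sub$size))
    if (!is.null(tpTables)) {
      for (lib in names(tpTables)) {
        est <- sum(tpTables[[lib]]$tp[tpTables[[lib]]$cluster_id %in% cls],
                   na.rm = TRUE)
        planted <- NA_real_
        if (!is.null(expectedTp) && lib %in% names(expectedTp)) {
          et <- expectedTp[[lib]]
          planted <- et$expected_tp[et$family == fn]
          if (!length(planted)) planted <- NA_real_
        }
        add(fn, paste0("tp_", lib), planted, est)
      }
    }
  }
  do.call(rbind, rows)
}
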