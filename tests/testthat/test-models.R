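test_that("log-log fit of exactly proportional data recovers slope 1", {
  gp <- c(0.1, 0.5, 1, 2, 5, 8)
  df <- data.frame(gp = gp, tp = 0.03 * gp)
  f <- fitTpModel(df, "gp", transform = "log10-both")
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_equal(f$intercept, log10(0.03), tolerance = 1e-10)
  expect_equal(f$adj_r2, 1, tolerance = 1e-10)
})

test_that("degenerate fits behave: constant response, too-few rows", {
  df <- data.frame(gp = 1:6, tp = rep(2, 6))
  f <- fitTpModel(df, "gp")
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_lte(f$adj_r2, 0)
  expect_message(
    fNull <- fitTpModel(data.frame(gp = 1:2, tp = 1:2), "gp"),
    "fewer than 3")
  expect_null(fNull)
})

test_that("zero-TP rows are dropped only under a logged response", {
  df <- data.frame(gp = c(1, 2, 3, 4, 5), tp = c(0, 0.1, 0.2, 0.3, 0.4))
  fLog <- fitTpModel(df, "gp", transform = "log10-response")
  expect_equal(fLog$n_used, 4L)
  expect_equal(fLog$n_excluded_zero, 1L)
  fRaw <- fitTpModel(df, "gp", transform = "none")
  expect_equal(fRaw$n_used, 5L)
  expect_equal(fRaw$n_excluded_zero, 0L)
})

test_that("a noisy planted log-log slope of 1 is recovered within its CI", {
  set.seed(71)
  n <- 50
  gp <- 10^runif(n, -1, 1)
  tp <- 10^(log10(gp) + rnorm(n, 0, 0.1))
  f <- fitTpModel(data.frame(gp = gp, tp = tp), "gp",
                  transform = "log10-both")
  fit <- lm(log10(tp) ~ log10(gp))
  ci <- confint(fit)[2, ]
  expect_gte(1, ci[1]); expect_lte(1, ci[2])
  expect_equal(f$slope, unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("Tukey letters separate what differs and join what does not", {
  set.seed(72)
  vals <- c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 10))
  grp <- rep(c("a1", "a2", "far"), each = 8)
  tk <- tukeyMeans(vals, grp)
  expect_equal(tk$letters[["a1"]], tk$letters[["a2"]])
  expect_false(tk$letters[["far"]] %in%
                 c(tk$letters[["a1"]], tk$letters[["a2"]]))

  # identical values everywhere: a single letter for all
  tk2 <- tukeyMeans(rep(5, 12), rep(c("x", "y", "z"), each = 4))
  expect_true(all(tk2$letters == "a"))

  # single-observation groups are excluded from the test, listed aside
  tk3 <- tukeyMeans(c(rnorm(5), rnorm(5, 4), 9),
                    c(rep("p", 5), rep("q", 5), "solo"))
  expect_equal(tk3$excluded, "solo")
  expect_false("solo" %in% names(tk3$letters))
})

test_that("groups drawn from one distribution share a letter at nominal alpha", {
  set.seed(73)
  shared <- 0
  for (r in 1:40) {
    vals <- rnorm(24)
    tk <- tukeyMeans(vals, rep(c("g1", "g2", "g3"), each = 8))
    if (length(unique(tk$letters)) == 1L) shared <- shared + 1
  }
  expect_gte(shared / 40, 0.80)   # ~1 - alpha with Monte-Carlo slack
})

test_that("recovery report flags undetected families without error rows", {
  mf <- smallManifest()
  cl <- data.frame(cluster_id = "CL1", size = 500L,
                   classLabel = "Ty3/gypsy", lineage = "Tekay",
                   flag = "none", gp = 1.2, modal_similarity = 97,
                   gc_percent = 47, stringsAsFactors = FALSE)
  cf <- c(CL1 = "famA_tekay")
  rep1 <- recoveryReport(mf, cl, cf)
  expect_true("famA_tekay" %in% rep1$family)
  missing <- rep1[rep1$family == "famB_angela" & rep1$quantity == "gp", ]
  expect_match(missing$note, "not detected")
  expect_true(is.na(missing$estimated))
  # deterministic given identical inputs
  expect_identical(rep1, recoveryReport(mf, cl, cf))
})
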