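test_that("AUROC equals the Mann-Whitney pair-win probability", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.3, 0.4)), 1.0)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.7, 4)), 0.5)
  expect_true(is.na(auroc(c(1, 1), c(0.2, 0.3))))
})

test_that("AUROC agrees with O(N^2) brute-force pair counting, ties included", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2), n)  # coarse grid forces ties
    expect_equal(auroc(y, s), auroc_bruteforce(y, s), tolerance = 1e-12)
  }
})

test_that("AUPRC is step-wise average precision", {
  expect_equal(auprc(c(1, 0, 1), c(0.9, 0.8, 0.1)), (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.3, 0.4)), 1.0)
  expect_true(is.na(auprc(c(0, 0), c(0.1, 0.2))))
  # random scores converge to the prevalence baseline
  set.seed(77)
  y <- rbinom(20000, 1, 0.06)
  s <- runif(20000)
  expect_lt(abs(auprc(y, s) - 0.06), 0.01)
})

test_that("bootstrap median CI is deterministic and matches an independent run", {
  x <- rep(0.7, 101)
  ci <- bootstrap_median_ci(x, n_resamples = 1000, seed = 4)
  expect_equal(ci$ci_low, 0.7)
  expect_equal(ci$ci_high, 0.7)
  expect_equal(ci$median, 0.7)

  y <- c(rep(0.6, 50), rep(0.8, 51))
  a <- bootstrap_median_ci(y, n_resamples = 10000, seed = 9)
  b <- bootstrap_median_ci(y, n_resamples = 10000, seed = 9)
  expect_identical(a, b)
  # independent reimplementation of the percentile bootstrap
  set.seed(1234)
  meds <- replicate(10000, median(sample(y, length(y), replace = TRUE)))
  ref <- quantile(meds, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(a$ci_low - ref[1]), 0.005)
  expect_lt(abs(a$ci_high - ref[2]), 0.005)
  expect_true(a$ci_low <= a$median && a$median <= a$ci_high)
  expect_error(bootstrap_median_ci(c(0.5, NA)), "at least 2")
})

test_that("paired Wilcoxon handles degenerate, extreme and exact small cases", {
  expect_warning(p_eq <- wilcoxon_paired(1:5, 1:5), "zero")
  expect_equal(p_eq, 1)
  a <- runif(101)
  expect_lt(wilcoxon_paired(a + 0.1, a), 0.001)
  # exact enumeration oracle at n = 6, tied absolute differences included
  d <- c(1, 2, 3, -1, 4, 5)
  p_pkg <- wilcoxon_paired(d, rep(0, 6))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- 6 * 7 / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_oracle <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(p_pkg, p_oracle)
  # tie-free small case agrees with the exact signed-rank distribution
  d2 <- c(0.3, -0.9, 1.4, 2.2, -0.1, 0.7, 1.1)
  expect_equal(wilcoxon_paired(d2, rep(0, 7)),
               stats::wilcox.test(d2, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("per-surgery deltas are paired on the common evaluation region", {
  mk_fold <- function(id, widx, y, s) {
    list(surgery_id = id, model_name = "m", K_minutes = 0L, window_index = widx,
         y_true = y, y_score = s, auroc = auroc(y, s), failed = FALSE)
  }
  y <- c(0, 1, 0, 1, 0, 0)
  f_long <- list(mk_fold("A", 120:125, y, c(.1, .9, .2, .8, .1, .3)))
  f_same <- list(mk_fold("A", 120:125, y, c(.1, .9, .2, .8, .1, .3)))
  d0 <- per_surgery_delta(f_long, f_same)
  expect_equal(d0$table$delta, 0)
  expect_equal(d0$fraction_improved, 0)

  # the shorter-adaptation fold covers more windows; only common ones count
  f_short <- list(mk_fold("A", 112:125, c(1, 0, rep(0, 6), y[-(1:2)] * 0 + y[3:6]),
                          c(.5, .5, rep(.5, 6), .2, .1, .3, .6)))
  f_short[[1]]$y_true <- c(1, 0, 0, 0, 0, 0, 0, 0, y)[1:14]
  f_short[[1]]$y_score <- runif(14)
  d1 <- per_surgery_delta(f_long, f_short)
  expect_equal(nrow(d1$table), 1)
  expect_false(is.na(d1$table$delta))

  # hand-arithmetic summary
  mk <- function(id, s) mk_fold(id, 1:4, c(0, 1, 0, 1), s)
  hi <- list(mk("A", c(.1, .9, .2, .8)), mk("B", c(.9, .1, .8, .2)), mk("C", c(.1, .8, .2, .9)))
  lo <- list(mk("A", c(.1, .8, .3, .7)), mk("B", c(.1, .9, .2, .8)), mk("C", c(.4, .5, .5, .6)))
  d2 <- per_surgery_delta(hi, lo)
  expect_equal(d2$n_improved + d2$n_declined + sum(d2$table$delta == 0, na.rm = TRUE), 3)
  expect_error(per_surgery_delta(hi, lo[1:2]), "mismatched")
})

test_that("pooled metric on concatenated identical folds equals the per-fold metric", {
  y <- c(0, 1, 0, 1, 1, 0)
  s <- c(.2, .7, .4, .9, .6, .1)
  fold <- list(surgery_id = "A", model_name = "m", K_minutes = 0L,
               y_true = y, y_score = s, window_index = 0:5,
               auroc = auroc(y, s), auprc = auprc(y, s), failed = FALSE)
  folds <- structure(list(fold, modifyList(fold, list(surgery_id = "B")),
                          modifyList(fold, list(surgery_id = "C"))),
                     class = "loso_result")
  sm <- summarize_folds(folds, "auroc", n_resamples = 200, seed = 1)
  expect_equal(sm$pooled, auroc(y, s))
  expect_equal(sm$median, auroc(y, s))
})
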