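test_that("Platt scaling recovers a logistic truth and handles degenerate inputs", {
  set.seed(41)
  s <- rnorm(10000, 0, 1.5)  # raw scores on the logit scale
  y <- rbinom(10000, 1, plogis(s))
  m <- fit_platt(s, y)
  expect_lt(abs(m$a - 1), 0.1)
  expect_lt(abs(m$b), 0.1)
  # balanced labels with constant scores map to the base rate
  m0 <- fit_platt(rep(0.3, 100), rep(c(0, 1), 50))
  expect_equal(calibrate_scores(m0, 0.3), 0.5, tolerance = 1e-9)
  expect_error(fit_platt(runif(10), rep(0, 10)), class = "nocibench_skipped_fold")
})

test_that("isotonic fitting reproduces hand-run pool-adjacent-violators", {
  m <- fit_isotonic(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))
  expect_equal(m$fitted, c(0, 0.5, 0.5, 1))
  # clamping at the end steps
  expect_equal(calibrate_scores(m, c(-1, 2)), c(0, 1))
  expect_error(fit_isotonic(runif(5), rep(1, 5)), class = "nocibench_skipped_fold")
})

test_that("weighted PAV matches stats::isoreg on tie-free data", {
  set.seed(53)
  s <- sort(runif(200))
  y <- rbinom(200, 1, plogis(4 * s - 2))
  m <- fit_isotonic(s, y)
  ref <- stats::isoreg(s, y)
  expect_equal(m$fitted, ref$yf, tolerance = 1e-12)
})

test_that("monotone calibration preserves discrimination up to ties", {
  set.seed(61)
  s <- runif(3000)
  y <- rbinom(3000, 1, plogis(3 * s - 2))
  base <- auroc(y, s)
  for (m in list(fit_platt(s, y), fit_isotonic(s, y))) {
    expect_lt(abs(auroc(y, calibrate_scores(m, s)) - base), 0.005)
  }
})

test_that("quantile-binned ECE follows its definition on constructed cases", {
  # constructed perfect calibration in two score groups
  s <- c(rep(0.2, 5), rep(0.8, 5))
  y <- c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0)
  expect_equal(as.numeric(ece_quantile(s, y, n_bins = 2)), 0)
  # constant score collapses to a single merged bin
  y2 <- c(rep(1, 6), rep(0, 94))
  expect_equal(as.numeric(ece_quantile(rep(0.5, 100), y2)), 0.44)
  # scores equal to within-bin frequencies give zero
  expect_equal(as.numeric(ece_quantile(rep(0.06, 50), rbinom(50, 1, 1) * 0 + c(rep(1, 3), rep(0, 47)))), 0)
  expect_warning(e <- ece_quantile(runif(5), rbinom(5, 1, 0.5), n_bins = 10), "single bin")
  # bin table sums to N and reproduces the ECE from its own rows
  set.seed(3)
  s3 <- runif(500); y3 <- rbinom(500, 1, s3)
  e3 <- ece_quantile(s3, y3)
  b <- attr(e3, "bins")
  expect_equal(sum(b$count), 500)
  expect_equal(as.numeric(e3),
               sum(b$count / 500 * abs(b$mean_predicted - b$observed_frequency)))
  # ECE is invariant to within-bin permutation of samples
  ord <- order(s3)
  expect_equal(as.numeric(ece_quantile(s3[ord], y3[ord])), as.numeric(e3))
})

test_that("Brier score matches hand arithmetic and its irreducible bound", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
  # the constant-prevalence predictor attains exactly pi(1-pi)
  set.seed(71)
  y <- rbinom(5000, 1, 0.06)
  pi_hat <- mean(y)
  expect_equal(brier(rep(pi_hat, 5000), y), pi_hat * (1 - pi_hat), tolerance = 1e-12)
})

test_that("fold calibration skips exactly when the adaptation segment is single-class", {
  co <- tiny_cohort(5, c(12, 14), seed = 25)
  recipe <- recipe_tcn("naive", train = train_config(max_epochs = 2, patience = 1, seed = 1))
  res <- run_loso(co, recipe, K_minutes = 1, seed = 1)
  for (f in res) {
    single <- length(unique(f$adapt$y_true)) < 2
    for (method in c("platt", "isotonic")) {
      rep_ <- calibrate_fold(f, method)
      expect_equal(rep_$skipped, single)
      if (single) expect_match(rep_$reason, "lack of both positive and negative")
    }
    raw <- calibrate_fold(f, "raw")
    expect_false(raw$skipped)
    expect_equal(raw$auroc, f$auroc)  # identity mapping leaves AUROC exactly
  }
})

test_that("skipped-fold counts are non-increasing in the adaptation window", {
  co <- generate_cohort(cohort_config(n_surgeries = 30, duration_minutes_range = c(15, 20),
                                      seed = 33))
  census <- skipped_fold_census(co, c(1L, 2L, 5L, 10L))
  expect_true(all(diff(census$skipped) <= 0))
  expect_gt(census$skipped[1], census$skipped[4])  # 6% prevalence: short windows mostly single-class
  # census matches a direct count
  manual <- sum(vapply(co, function(r) length(unique(r$label[1:12])) < 2, logical(1)))
  expect_equal(census$skipped[1], manual)
})

test_that("refit-on-self isotonic calibration drives the quantile-binned ECE to zero", {
  set.seed(81)
  fold <- list(surgery_id = "A", y_true = rbinom(2000, 1, 0.2),
               y_score = runif(2000), window_index = 0:1999, failed = FALSE)
  fold$auroc <- auroc(fold$y_true, fold$y_score)
  rep_ <- calibrate_fold(fold, "isotonic", fit_on = "pooled_eval")
  expect_lt(rep_$ece, 1e-6)
})
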