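test_that("linear blending obeys its identities and recovers the informative base", {
  p_rf <- c(0.8, 0.3, 0.6)
  p_tl <- c(0.2, 0.9, 0.4)
  expect_equal(as.numeric(blend_linear(p_rf, p_tl, w = 1)), p_rf)
  expect_equal(as.numeric(blend_linear(0.8, 0.2, w = 0.5)), 0.5)
  expect_error(blend_linear(p_rf, p_tl[1:2]), "length mismatch")
  set.seed(91)
  n <- 10000
  y <- rbinom(n, 1, 0.3)
  good <- pmin(1, pmax(0, y + rnorm(n, 0, 0.1)))
  noise <- runif(n)
  b <- blend_linear(good, noise, labels = y)
  w <- attr(b, "weights")
  expect_gt(w["w_rf"], 0.9)
  expect_lt(abs(w["w_tl"]), 0.1)
  expect_true(all(b >= 0 & b <= 1))
})

test_that("the logistic meta-learner weights the predictive base model", {
  set.seed(92)
  n <- 4000
  p_rf <- runif(n)
  p_tl <- runif(n)
  y <- as.integer(p_rf > 0.5)
  m <- fit_meta("meta_logistic", p_rf, p_tl, y)
  expect_gt(m$coef["p_rf"], 2)
  expect_gt(m$coef["p_rf"], abs(m$coef["p_tl"]) * 5)
  # redundant bases: meta output is monotone in the shared score
  p_shared <- runif(n)
  y2 <- rbinom(n, 1, plogis(4 * p_shared - 2))
  m2 <- fit_meta("meta_logistic", p_shared, p_shared, y2)
  pred <- predict(m2, p_shared, p_shared)
  expect_equal(auroc(y2, pred), auroc(y2, p_shared), tolerance = 1e-12)
  expect_error(fit_meta("meta_logistic", p_rf, p_tl, rep(1, n)), "degenerate-labels")
})

test_that("the MLP meta-learner captures an XOR interaction the logistic cannot", {
  set.seed(93)
  n <- 3000
  p_rf <- runif(n)
  p_tl <- runif(n)
  y <- as.integer(xor(p_rf > 0.5, p_tl > 0.5))
  lo <- fit_meta("meta_logistic", p_rf, p_tl, y)
  ml <- fit_meta("meta_mlp", p_rf, p_tl, y, epochs = 200, seed = 2)
  loss_lo <- nocibench:::meta_train_loss(lo, p_rf, p_tl, y)
  loss_ml <- nocibench:::meta_train_loss(ml, p_rf, p_tl, y)
  expect_lt(loss_ml, loss_lo)
})

test_that("the gate learns to trust an oracle base model", {
  set.seed(94)
  n <- 6000
  y <- rbinom(n, 1, 0.3)
  p_rf <- pmin(1 - 1e-3, pmax(1e-3, y + rnorm(n, 0, 0.05)))
  p_tl <- runif(n)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  g <- fit_gatenet(X, p_rf, p_tl, y, epochs = 30, seed = 3)
  alpha <- predict_alpha(g, X)
  expect_gt(mean(alpha), 0.9)
  expect_true(all(alpha > 0 & alpha < 1))
  # the trained gate stays RF-dominant across its whole feature surface
  sweep_m <- alpha_sweep(g, colMeans(X), c("f1", "f2"), n_grid = 50)
  expect_equal(dim(sweep_m), c(50L, 50L))
  expect_true(all(sweep_m > 0 & sweep_m < 1))
  expect_gt(min(sweep_m), 0.5)
  expect_error(alpha_sweep(g, colMeans(X), c("f1", "nope")), "unknown feature")
})

test_that("identical base predictions leave the gate at its initialization", {
  set.seed(95)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  p <- runif(n)
  X <- matrix(rnorm(n * 3), n, 3)
  g <- fit_gatenet(X, p, p, y, epochs = 5, seed = 7)
  # zero gradient everywhere: parameters must equal the seeded initialization
  expect_equal(g$params, nocibench:::mlp_init(3, 16L, 7), tolerance = 1e-12)
})

test_that("the mixture identity holds bit-exactly and alpha = 1 reduces to the RF", {
  set.seed(96)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  p_rf <- runif(n); p_tl <- runif(n)
  X <- matrix(rnorm(n * 4), n, 4)
  g <- fit_gatenet(X, p_rf, p_tl, y, epochs = 3, seed = 1)
  pf <- predict(g, X, p_rf, p_tl)
  a <- attr(pf, "alpha")
  expect_identical(as.numeric(pf), a * p_rf + (1 - a) * p_tl)
  # constant-gate surface: zero weights and bias b give sigmoid(b) everywhere
  g$params$W1[] <- 0; g$params$b1[] <- 0; g$params$W2[] <- 0; g$params$b2 <- 1.2
  sweep_m <- alpha_sweep(g, stats::setNames(rep(0, 4), paste0("x", 1:4)),
                         c("x1", "x2"), n_grid = 10)
  expect_equal(as.numeric(sweep_m), rep(plogis(1.2), 100), tolerance = 1e-12)
  # alpha fixed at 1 makes the blend's fold metrics the RF's exactly
  blended <- blend_linear(p_rf, p_tl, w = 1)
  expect_equal(auroc(y, blended), auroc(y, p_rf))
  expect_equal(auprc(y, blended), auprc(y, p_rf))
})

test_that("permutation importance isolates the generating feature", {
  set.seed(97)
  n <- 10000
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- rbinom(n, 1, plogis(2.5 * X[, 3]))
  # depth-limited forest: deep trees memorize noise columns on their own
  # training rows, which would mask the null-feature property
  f <- fit_random_forest(make_fm(X, y), n_trees = 50, max_depth = 6, seed = 5)
  imp <- permutation_importance(f, X, y, n_repeats = 20, seed = 11)
  expect_equal(names(which.max(imp)), "x3")
  expect_gt(imp["x3"], max(imp[-3]) * 2)
  # a feature independent of the label has near-zero importance
  expect_lt(max(abs(imp[-3])), 0.01)
  # identity permutation yields exactly zero for every feature
  imp0 <- permutation_importance(f, X, y, n_repeats = 2, seed = 1,
                                 shuffle = function(n) seq_len(n))
  expect_equal(unname(imp0), rep(0, 6))
  # determinism
  expect_identical(imp, permutation_importance(f, X, y, n_repeats = 20, seed = 11))
})

test_that("out-of-fold tables never mix a surgery's rows into its own training", {
  co <- tiny_cohort(4, c(10, 12), seed = 27)
  res_a <- run_loso(co, recipe_rf("aware", n_trees = 20), seed = 1)
  res_b <- run_loso(co, recipe_rf("aware", n_trees = 10), seed = 2)
  oof <- oof_table(res_a, res_b, co, "aware")
  ids <- vapply(co, `[[`, character(1), "surgery_id")
  expect_setequal(unique(oof$surgery_of_row), ids)
  expect_equal(length(oof$p_rf), length(oof$labels))
  expect_equal(nrow(oof$features), length(oof$labels))
  # per-surgery rows come from the fold that held that surgery out
  f1 <- res_a[[1]]
  expect_equal(oof$p_rf[oof$surgery_of_row == ids[1]], f1$y_score)
  expect_false(ids[1] %in% f1$train_surgeries)
})
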