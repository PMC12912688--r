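test_that("closed-form parameter counts match the built network for any spec", {
  expect_equal(count_parameters(tcn_spec(48)), 20737L)
  expect_equal(count_parameters(tcn_spec(30)), 13825L)
  expect_equal(count_parameters(tcn_spec(1, 1, 1, 1, context_windows = 1)), 8L)
  set.seed(1)
  for (i in 1:8) {
    k <- sample(1:4, 1)
    sp <- tcn_spec(sample(1:20, 1), sample(1:16, 1), k, sample(1:10, 1),
                   context_windows = k + sample(0:3, 1))
    built <- build_tcn(sp, seed = i)
    expect_equal(nocibench:::tcn_num_parameters(built), count_parameters(sp))
  }
})

test_that("network construction enforces shape constraints and outputs probabilities", {
  expect_error(tcn_spec(48, 64, 6, 32, context_windows = 5), "shape error")
  co <- tiny_cohort(1, c(8, 10), seed = 3)
  model <- build_tcn(tcn_spec(48), seed = 1)
  model$scaler <- nocibench:::fit_scaler(nocibench:::record_feature_rows(co[[1]], "aware"))
  p <- predict_windows(model, co[[1]])
  expect_equal(length(p), length(co[[1]]$label))
  expect_true(all(p > 0 & p < 1))
  # drug-naive channel count builds and runs too
  m30 <- build_tcn(tcn_spec(30), seed = 1)
  m30$scaler <- nocibench:::fit_scaler(nocibench:::record_feature_rows(co[[1]], "naive"))
  expect_length(predict_windows(m30, co[[1]]), length(co[[1]]$label))
})

test_that("base training respects the epoch cap and prevalence weighting", {
  co <- tiny_cohort(4, c(10, 12), seed = 5)
  cfg <- train_config(max_epochs = 12, seed = 2)
  model <- train_base(tcn_spec(48), unclass(co), cfg)
  expect_lte(model$epochs_run, 12)
  expect_true(model$trained)
  # positive-class weight is (1 - pi) / pi for the training prevalence,
  # so balanced labels would give weight 1 (weighted = unweighted loss)
  expect_gt(model$pos_weight, 1)
  lw <- nocibench:::bce_weighted(c(0.3, 0.8), c(0, 1), pos_weight = 1)
  expect_equal(lw$loss, mean(-log(c(0.7, 0.8))))
  expect_error(train_base(tcn_spec(48), list(), cfg))
})

test_that("personalization freezes the trunk bit-exactly and moves only the head", {
  co <- tiny_cohort(3, c(12, 14), seed = 6)
  base <- train_base(tcn_spec(48), unclass(co)[1:2], train_config(max_epochs = 4, seed = 1))
  sp <- split_adaptation_evaluation(co[[3]], 2)
  pers <- personalize(base, sp$adaptation, finetune_config(K_minutes = 2))
  expect_identical(base$params$Wc, pers$params$Wc)
  expect_identical(base$params$bc, pers$params$bc)
  expect_identical(base$params$gamma, pers$params$gamma)
  expect_identical(base$params$beta, pers$params$beta)
  expect_identical(base$run_mean, pers$run_mean)
  expect_identical(base$run_var, pers$run_var)
  expect_equal(max(abs(base$params$Wc - pers$params$Wc)), 0)
  expect_false(identical(base$params[c("W1", "b1", "W2", "b2")],
                         pers$params[c("W1", "b1", "W2", "b2")]))
  # adaptation shorter than the context errors informatively
  stub <- nocibench:::subset_record(co[[3]], 1:3)
  expect_error(personalize(base, stub), class = "nocibench_insufficient_data")
})

test_that("fine-tuning on an all-negative adaptation segment lowers predictions", {
  co <- tiny_cohort(3, c(12, 14), seed = 10)
  base <- train_base(tcn_spec(48), unclass(co)[1:2], train_config(max_epochs = 4, seed = 1))
  sp <- split_adaptation_evaluation(co[[3]], 5)
  adapt <- sp$adaptation
  adapt$label <- rep(0L, length(adapt$label))
  pers <- personalize(base, adapt, finetune_config(K_minutes = 5, epochs = 5))
  before <- predict_windows(base, adapt)
  after <- predict_windows(pers, adapt)
  expect_lt(mean(after), mean(before))
})

test_that("window scoring is shift-aligned, complete and strictly in (0,1)", {
  co <- tiny_cohort(1, c(8, 10), seed = 4)
  r <- co[[1]]
  base <- build_tcn(tcn_spec(48), seed = 2)
  base$scaler <- nocibench:::fit_scaler(nocibench:::record_feature_rows(r, "aware"))
  # constant input gives a constant probability vector
  const <- r
  const$autonomic[] <- 1
  const$autonomic_derivative[] <- 0
  const$drug_cumulative[] <- 2
  const$drug_time_since[] <- 0.5
  p <- predict_windows(base, const)
  expect_equal(length(unique(round(p, 12))), 1L)
  p2 <- predict_windows(base, r)
  expect_equal(length(p2), length(r$label))
  expect_true(all(p2 > 0 & p2 < 1))
  # left-edge padding repeats the first computable score
  expect_equal(p2[1:5], rep(p2[6], 5))
  short <- nocibench:::subset_record(r, 1:4)
  expect_error(predict_windows(base, short), class = "nocibench_insufficient_data")
})

test_that("analytic network gradients match central finite differences", {
  set.seed(55)
  spec <- tcn_spec(3, 4, 2, 3, context_windows = 4)  # 3 conv positions: max-pool active
  model <- build_tcn(spec, seed = 2)
  R <- matrix(rnorm(40 * 3), 40, 3)
  tvec <- c(5L, 9L, 14L, 22L, 30L, 38L)
  y <- c(0, 1, 0, 1, 1, 0)
  w <- 2.5
  loss_at <- function(params) {
    m <- model; m$params <- params
    fwd <- nocibench:::tcn_forward(m, R, tvec, training = TRUE)
    nocibench:::bce_weighted(fwd$prob, y, w)$loss
  }
  fwd <- nocibench:::tcn_forward(model, R, tvec, training = TRUE)
  lb <- nocibench:::bce_weighted(fwd$prob, y, w)
  grads <- nocibench:::tcn_backward(model, fwd$cache, lb$dlogit)
  eps <- 1e-5
  for (nm in names(grads)) {
    idx <- seq_len(min(5L, length(model$params[[nm]])))
    for (i in idx) {
      up <- model$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- model$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})

test_that("gate gradients (through alpha only) match finite differences", {
  set.seed(56)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  p_rf <- runif(n); p_tl <- runif(n)
  y <- rbinom(n, 1, 0.5)
  params <- nocibench:::mlp_init(3, 4, seed = 9)
  eps_p <- 1e-7
  gate_loss <- function(pp) {
    a <- nocibench:::mlp_forward(pp, X)$out
    pf <- pmin(1 - eps_p, pmax(eps_p, a * p_rf + (1 - a) * p_tl))
    mean(-y * log(pf) - (1 - y) * log(1 - pf))
  }
  fwd <- nocibench:::mlp_forward(params, X)
  a <- fwd$out
  pf <- pmin(1 - eps_p, pmax(eps_p, a * p_rf + (1 - a) * p_tl))
  dL_dpf <- (pf - y) / (pf * (1 - pf)) / n
  dlogit <- dL_dpf * (p_rf - p_tl) * a * (1 - a)
  grads <- nocibench:::mlp_backward(params, X, fwd, dlogit)
  h <- 1e-6
  for (nm in names(grads)) {
    for (i in seq_len(min(4L, length(params[[nm]])))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
      num <- (gate_loss(up) - gate_loss(dn)) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d gate loss / d %s[%d]", nm, i))
    }
  }
})
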