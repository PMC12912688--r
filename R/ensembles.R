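#' Linear blend of two probability streams
#'
#' Fixed mode: `w * p_rf + (1 - w) * p_tl`. Regressed mode (when `labels`
#' is supplied): ordinary least squares of the labels on `(p_rf, p_tl)`
#' with intercept; the blended output is clipped to `[0, 1]`.
#'
#' @param p_rf,p_tl equal-length probability vectors from the two base
#'   models.
#' @param w fixed weight on `p_rf` (ignored when `labels` given).
#' @param labels optional binary labels; triggers the regressed mode.
#' @return the blended probability vector, with the weights attached as
#'   attribute `"weights"` (`w_rf`, `w_tl`, `intercept`).
#' @export
blend_linear <- function(p_rf, p_tl, w = 0.5, labels = NULL) {
  if (length(p_rf) != length(p_tl))
    stop("length mismatch between p_rf and p_tl", call. = FALSE)
  if (is.null(labels)) {
    out <- w * p_rf + (1 - w) * p_tl
    weights <- c(w_rf = w, w_tl = 1 - w, intercept = 0)
  } else {
    fit <- stats::lm(labels ~ p_rf + p_tl)
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    out <- pmin(1, pmax(0, co[1] + co[2] * p_rf + co[3] * p_tl))
    weights <- c(w_rf = unname(co[2]), w_tl = unname(co[3]),
                 intercept = unname(co[1]))
  }
  structure(out, weights = weights)
}

#' Meta-learners over base-model outputs
#'
#' `meta_logistic`: logistic regression on the two base probabilities.
#' `meta_mlp`: a one-hidden-layer network (8 ReLU units, sigmoid output) on
#' the same two inputs, capturing non-linear interactions between the base
#' model outputs. Train on out-of-fold base predictions so the meta-learner
#' never sees rows from its evaluation surgery.
#'
#' @param strategy `"meta_logistic"` or `"meta_mlp"`.
#' @param p_rf,p_tl base-model probabilities (training rows).
#' @param labels binary labels.
#' @param hidden MLP hidden width.
#' @param epochs,learning_rate,batch_size MLP training configuration.
#' @param seed RNG seed.
#' @return an object of class `meta_model`; predict with
#'   `predict(model, p_rf, p_tl)`.
#' @export
fit_meta <- function(strategy = c("meta_logistic", "meta_mlp"),
                     p_rf, p_tl, labels, hidden = 8L, epochs = 20L,
                     learning_rate = 1e-3, batch_size = 128L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(unique(labels)) < 2L)
    stop("degenerate-labels error: meta-learner needs both classes", call. = FALSE)
  if (strategy == "meta_logistic") {
    fit <- suppressWarnings(stats::glm(labels ~ p_rf + p_tl, family = stats::binomial()))
    co <- stats::coef(fit); co[is.na(co)] <- 0
    obj <- list(strategy = strategy, coef = co)
  } else {
    X <- cbind(p_rf, p_tl)
    params <- mlp_train(X, labels, hidden, epochs, learning_rate, batch_size, seed)
    obj <- list(strategy = strategy, params = params)
  }
  structure(obj, class = "meta_model")
}

# Plain BCE training loop for a 2-layer MLP.
mlp_train <- function(X, y, hidden, epochs, lr, batch_size, seed,
                      loss_grad = NULL) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  params <- mlp_init(ncol(X), hidden, seed)
  state <- adam_init(params)
  N <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(N)
    for (start in seq(1L, N, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, N)]
      Xb <- X[bi, , drop = FALSE]
      fwd <- mlp_forward(params, Xb)
      dlogit <- (fwd$out - y[bi]) / length(bi)
      grads <- mlp_backward(params, Xb, fwd, dlogit)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
  }
  params
}

#' @export
predict.meta_model <- function(object, p_rf, p_tl, ...) {
  if (object$strategy == "meta_logistic") {
    stats::plogis(object$coef[1] + object$coef[2] * p_rf + object$coef[3] * p_tl)
  } else {
    mlp_forward(object$params, cbind(p_rf, p_tl))$out
  }
}

# Mean training BCE of a meta model (used to compare learner capacity).
meta_train_loss <- function(model, p_rf, p_tl, labels) {
  p <- predict(model, p_rf, p_tl)
  eps <- 1e-12
  mean(-labels * log(pmax(p, eps)) - (1 - labels) * log(pmax(1 - p, eps)))
}

#' Feature-conditioned gating ensemble (GateNet)
#'
#' A small gating network (dense `p -> hidden` ReLU, dense `hidden -> 1`
#' sigmoid) maps the input features to a per-sample weight
#' `alpha in (0, 1)`; the final prediction is the mixture
#' `p_final = alpha * p_rf + (1 - alpha) * p_tl` (held exactly). Training
#' minimizes the binary cross-entropy of `p_final` against the labels with
#' the base predictions held fixed, so gradients flow only through the
#' gate.
#'
#' @param features numeric matrix (48- or 30-column design), row-aligned
#'   with the base predictions.
#' @param p_rf,p_tl base-model probabilities.
#' @param labels binary labels.
#' @param hidden gate hidden width.
#' @param epochs,learning_rate,batch_size,patience training configuration
#'   (Adam; early stopping on a 10% validation split when feasible).
#' @param seed RNG seed.
#' @return an object of class `gatenet`; use [predict_alpha()] for the gate
#'   weights and `predict(gate, features, p_rf, p_tl)` for the mixture.
#' @export
fit_gatenet <- function(features, p_rf, p_tl, labels, hidden = 16L,
                        epochs = 20L, learning_rate = 1e-3,
                        batch_size = 128L, patience = 3L, seed = 1L) {
  if (length(unique(labels)) < 2L)
    stop("degenerate-labels error: GateNet needs both classes", call. = FALSE)
  stopifnot(nrow(features) == length(p_rf), length(p_rf) == length(p_tl))
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  params <- mlp_init(ncol(features), hidden, seed)
  state <- adam_init(params)
  N <- nrow(features)
  set.seed(seed)
  val <- sample.int(N) <= floor(0.1 * N)
  if (sum(val) < 10L) val[] <- FALSE
  tr <- which(!val); va <- which(val)
  eps <- 1e-7
  gate_loss <- function(idx) {
    a <- mlp_forward(params, features[idx, , drop = FALSE])$out
    pf <- pmin(1 - eps, pmax(eps, a * p_rf[idx] + (1 - a) * p_tl[idx]))
    mean(-labels[idx] * log(pf) - (1 - labels[idx]) * log(1 - pf))
  }
  best <- list(loss = Inf, params = params); stale <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample(tr)
    for (start in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      Xb <- features[bi, , drop = FALSE]
      fwd <- mlp_forward(params, Xb)
      a <- fwd$out
      pf <- pmin(1 - eps, pmax(eps, a * p_rf[bi] + (1 - a) * p_tl[bi]))
      # dL/d(alpha logit): BCE wrt p_final, chain through the mixture and
      # the sigmoid; base predictions are constants
      dL_dpf <- (pf - labels[bi]) / (pf * (1 - pf)) / length(bi)
      dlogit <- dL_dpf * (p_rf[bi] - p_tl[bi]) * a * (1 - a)
      grads <- mlp_backward(params, Xb, fwd, dlogit)
      upd <- adam_step(params, grads, state, learning_rate)
      params <- upd$params
      state <- upd$state
    }
    mloss <- gate_loss(if (length(va)) va else tr)
    if (mloss < best$loss - 1e-9) {
      best <- list(loss = mloss, params = params); stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(params = best$params, hidden = hidden,
                 n_features = ncol(features),
                 feature_names = colnames(features)),
            class = "gatenet")
}

#' Per-sample gate weights
#'
#' @param gate a fitted `gatenet`.
#' @param features feature matrix with the training columns.
#' @return vector of `alpha` values in `(0, 1)`.
#' @export
predict_alpha <- function(gate, features) {
  stopifnot(inherits(gate, "gatenet"))
  if (ncol(features) != gate$n_features)
    stop(sprintf("schema error: %d feature columns supplied, gate expects %d",
                 ncol(features), gate$n_features), call. = FALSE)
  mlp_forward(gate$params, features)$out
}

#' @export
predict.gatenet <- function(object, features, p_rf, p_tl, ...) {
  alpha <- predict_alpha(object, features)
  structure(alpha * p_rf + (1 - alpha) * p_tl, alpha = alpha)
}

#' Gate-weight surface over a two-feature grid
#'
#' Evaluates the gate's `alpha` on the Cartesian grid of two named
#' features, all other features held at the supplied reference values
#' (typically the cohort means).
#'
#' @param gate a fitted `gatenet`.
#' @param feature_means named numeric vector of reference values for every
#'   gate feature.
#' @param features character vector of the two feature names to vary.
#' @param ranges list of two length-2 numeric ranges (defaults to +/- 2
#'   around the reference value).
#' @param n_grid grid resolution per axis.
#' @return `n_grid x n_grid` matrix of alpha values; `dimnames` carry the
#'   grid coordinates and attribute `"features"` the axis names
#'   (rows = first feature, columns = second).
#' @export
alpha_sweep <- function(gate, feature_means, features, ranges = NULL,
                        n_grid = 50L) {
  stopifnot(inherits(gate, "gatenet"), length(features) == 2L)
  nm <- gate$feature_names %||% names(feature_means)
  if (!all(features %in% nm))
    stop("unknown feature name: ",
         paste(setdiff(features, nm), collapse = ", "), call. = FALSE)
  base <- feature_means[nm]
  if (is.null(ranges)) {
    ranges <- lapply(features, function(f) base[f] + c(-2, 2))
  }
  g1 <- seq(ranges[[1]][1], ranges[[1]][2], length.out = n_grid)
  g2 <- seq(ranges[[2]][1], ranges[[2]][2], length.out = n_grid)
  grid <- expand.grid(g1 = g1, g2 = g2)
  X <- matrix(rep(base, each = nrow(grid)), nrow(grid), length(base),
              dimnames = list(NULL, nm))
  X[, features[1]] <- grid$g1
  X[, features[2]] <- grid$g2
  a <- predict_alpha(gate, X)
  m <- matrix(a, n_grid, n_grid,
              dimnames = list(signif(g1, 4), signif(g2, 4)))
  attr(m, "features") <- features
  m
}

#' Permutation feature importance
#'
#' `importance(j)` is the mean AUROC drop over `n_repeats` random
#' permutations of column `j`: a larger drop indicates greater model
#' reliance on that feature. Deterministic given the seed.
#'
#' @param model a fitted model with a [predict_proba()] method, or a
#'   function `f(X) -> scores`.
#' @param X feature matrix.
#' @param y binary labels (both classes required).
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @param shuffle permutation generator `function(n) -> integer vector`
#'   (exposed so degenerate permutations can be tested; default
#'   `sample.int`).
#' @return named numeric vector of importances (column order of `X`).
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10L, seed = 1L,
                                   shuffle = sample.int) {
  if (length(unique(y)) < 2L)
    stop("degenerate-labels error: both classes required", call. = FALSE)
  score_fun <- if (is.function(model)) model else function(Xn) predict_proba(model, Xn)
  base_auc <- auroc(y, score_fun(X))
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      Xp <- X
      Xp[, j] <- Xp[shuffle(nrow(X)), j]
      drops[r] <- base_auc - auroc(y, score_fun(Xp))
    }
    imp[j] <- mean(drops)
  }
  names(imp) <- colnames(X)
  imp
}

#' Out-of-fold base predictions for ensemble training
#'
#' Rebuilds, from two completed [run_loso()] runs over the same cohort, the
#' row-aligned training table for meta-learners and the gate: every surgery
#' is scored by the fold models that excluded it, so ensemble training never
#' touches rows from its own evaluation surgery.
#'
#' @param folds_rf,folds_tl `loso_result`s for the two base models over the
#'   same cohort and K.
#' @param cohort the cohort the runs were made on (for features/labels).
#' @param mode feature mode for the gate design matrix.
#' @return list with `p_rf`, `p_tl`, `labels`, `features`, `surgery_of_row`.
#' @export
oof_table <- function(folds_rf, folds_tl, cohort, mode = c("aware", "naive")) {
  mode <- match.arg(mode)
  records <- if (inherits(cohort, "noci_cohort")) unclass(cohort) else cohort
  ids <- vapply(records, `[[`, character(1), "surgery_id")
  frf <- fold_list(folds_rf); ftl <- fold_list(folds_tl)
  ids_rf <- vapply(frf, `[[`, character(1), "surgery_id")
  ids_tl <- vapply(ftl, `[[`, character(1), "surgery_id")
  p_rf <- c(); p_tl <- c(); labels <- c(); feats <- list(); sid <- c()
  for (i in seq_along(records)) {
    a <- frf[[match(ids[i], ids_rf)]]
    b <- ftl[[match(ids[i], ids_tl)]]
    if (isTRUE(a$failed) || isTRUE(b$failed)) next
    common <- intersect(a$window_index, b$window_index)
    if (!length(common)) next
    ia <- match(common, a$window_index)
    ib <- match(common, b$window_index)
    ri <- match(common, records[[i]]$window_index)
    p_rf <- c(p_rf, a$y_score[ia])
    p_tl <- c(p_tl, b$y_score[ib])
    labels <- c(labels, a$y_true[ia])
    feats[[length(feats) + 1L]] <- record_feature_rows(records[[i]], mode)[ri, , drop = FALSE]
    sid <- c(sid, rep(ids[i], length(common)))
  }
  list(p_rf = p_rf, p_tl = p_tl, labels = labels,
       features = do.call(rbind, feats), surgery_of_row = sid)
}
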