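#' L1-regularized logistic regression selected by AIC
#'
#' Fits an L1-penalized logistic path over a descending lambda grid (50
#' log-spaced values from the smallest all-zero-coefficient lambda down four
#' decades) and selects the fit minimizing
#' \eqn{AIC = 2k - 2\,\ell(\hat\beta)}, where \eqn{k} is the number of
#' nonzero coefficients plus one for the intercept — the standard LASSO
#' degrees-of-freedom estimate.
#'
#' @param train a `feature_matrix` (typically standardized).
#' @param n_lambda grid size.
#' @param lambda_decades how many decades below `lambda_max` the grid spans.
#' @return an object of class `lasso_aic` with elements `coefficients`
#'   (length-p, sparse in the sense of many exact zeros), `intercept`,
#'   `selected_lambda`, and `aic_path` (data frame of lambda, df, AIC).
#' @export
fit_lasso_aic <- function(train, n_lambda = 50L, lambda_decades = 4) {
  stopifnot(inherits(train, "feature_matrix"))
  y <- train$y
  if (length(unique(y)) < 2L)
    stop("degenerate-labels error: training labels contain a single class", call. = FALSE)
  X <- train$X
  # lambda_max: smallest penalty with an all-zero coefficient vector
  # (max absolute gradient of the unpenalized log-likelihood at beta = 0)
  n <- nrow(X)
  pbar <- mean(y)
  lambda_max <- max(abs(crossprod(X, y - pbar))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max) - lambda_decades * log(10),
                  length.out = n_lambda))
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = grid,
                        standardize = FALSE, intercept = TRUE)
  beta <- as.matrix(fit$beta)
  a0 <- fit$a0
  eta <- sweep(X %*% beta, 2, a0, "+")
  p <- 1 / (1 + exp(-eta))
  eps <- 1e-12
  loglik <- colSums(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  df <- colSums(beta != 0) + 1L
  aic <- 2 * df - 2 * loglik
  lam <- fit$lambda
  best <- which.min(aic)
  structure(list(
    coefficients = stats::setNames(beta[, best], train$column_names),
    intercept = unname(a0[best]),
    selected_lambda = lam[best],
    aic_path = data.frame(lambda = lam, df = df, aic = aic),
    column_names = train$column_names
  ), class = "lasso_aic")
}

#' @export
print.lasso_aic <- function(x, ...) {
  cat(sprintf("LASSO-AIC logistic model: %d/%d nonzero coefficients, lambda = %.5g, AIC = %.2f\n",
              sum(x$coefficients != 0), length(x$coefficients),
              x$selected_lambda, min(x$aic_path$aic)))
  invisible(x)
}

#' @export
coef.lasso_aic <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Random forest benchmark model
#'
#' Fits a probability forest with the benchmark's configuration: `n_trees`
#' trees (200, or 50 for the pruned variant), depth cap 50, each tree grown
#' on a 90% bootstrap sample (with replacement by default), Gini splits and
#' `sqrt(p)` candidate features per split.
#'
#' @param train a `feature_matrix`.
#' @param n_trees number of trees (benchmark uses 200 and 50).
#' @param max_depth per-tree depth cap.
#' @param bootstrap_fraction fraction of rows drawn per tree.
#' @param replace sample rows with replacement (the default reading of
#'   "90% bootstrap resampling"); flag-switchable.
#' @param seed integer RNG seed; fits are deterministic given the seed.
#' @return an object of class `noci_forest` with the fitted ensemble,
#'   `n_trees`, `max_depth`, `bootstrap_fraction`, `node_count` (total
#'   decision + leaf nodes) and the training column names.
#' @export
fit_random_forest <- function(train, n_trees = 200L, max_depth = 50L,
                              bootstrap_fraction = 0.9, replace = TRUE,
                              seed = 1L) {
  stopifnot(inherits(train, "feature_matrix"))
  if (length(unique(train$y)) < 2L)
    stop("degenerate-labels error: training labels contain a single class", call. = FALSE)
  df <- data.frame(train$X, check.names = FALSE)
  df$.label <- factor(train$y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, max.depth = max_depth,
    sample.fraction = bootstrap_fraction, replace = replace,
    mtry = max(1L, floor(sqrt(ncol(train$X)))),
    splitrule = "gini", probability = TRUE,
    seed = seed, num.threads = 1L
  )
  node_count <- sum(vapply(seq_len(n_trees),
                           function(i) nrow(ranger::treeInfo(fit, i)), numeric(1)))
  structure(list(
    forest = fit, n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
    bootstrap_fraction = bootstrap_fraction, replace = replace,
    node_count = as.integer(node_count),
    column_names = train$column_names, seed = seed
  ), class = "noci_forest")
}

#' @export
print.noci_forest <- function(x, ...) {
  cat(sprintf("Random forest: %d trees (depth cap %d), %d nodes, %.0f%% bootstrap\n",
              x$n_trees, x$max_depth, x$node_count, 100 * x$bootstrap_fraction))
  invisible(x)
}

# Maximum depth actually attained by each tree (root at depth 0).
forest_tree_depths <- function(model) {
  vapply(seq_len(model$n_trees), function(i) {
    info <- ranger::treeInfo(model$forest, i)
    depth <- integer(nrow(info))
    # nodeIDs are ordered so that children follow parents
    for (r in seq_len(nrow(info))) {
      if (!info$terminal[r]) {
        depth[info$leftChild[r] + 1L] <- depth[r] + 1L
        depth[info$rightChild[r] + 1L] <- depth[r] + 1L
      }
    }
    max(depth)
  }, integer(1))
}

#' Predicted event probabilities
#'
#' Forest output is the mean of per-tree class-1 leaf frequencies; logistic
#' output is the inverse logit of the linear predictor. Column count must
#' match the training design.
#'
#' @param model a `lasso_aic` or `noci_forest`.
#' @param X numeric matrix with the training columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' @export
predict_proba.lasso_aic <- function(model, X) {
  X <- check_columns(X, model$column_names)
  eta <- drop(X %*% model$coefficients) + model$intercept
  unname(1 / (1 + exp(-eta)))
}

#' @export
predict_proba.noci_forest <- function(model, X) {
  X <- check_columns(X, model$column_names)
  df <- data.frame(X, check.names = FALSE)
  colnames(df) <- model$column_names
  pr <- stats::predict(model$forest, data = df, num.threads = 1L)$predictions
  unname(pr[, "1"])
}

check_columns <- function(X, column_names) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(column_names))
    stop(sprintf("schema error: %d columns supplied, model expects %d",
                 ncol(X), length(column_names)), call. = FALSE)
  X
}

#' @export
predict.lasso_aic <- function(object, newdata, ...) predict_proba(object, newdata)

#' @export
predict.noci_forest <- function(object, newdata, ...) predict_proba(object, newdata)
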