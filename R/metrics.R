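#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair-win probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with ties
#' counted one half (midrank formulation). Returns `NA` when only one class
#' is present (the undefined flag).
#'
#' @param y_true binary 0/1 vector.
#' @param y_score numeric score vector of the same length.
#' @return AUROC in `[0, 1]`, or `NA_real_` if undefined.
#' @export
auroc <- function(y_true, y_score) {
  stopifnot(length(y_true) == length(y_score))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_score)  # midranks handle ties at 1/2
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over descending unique score
#' thresholds of precision times the recall increment. This is the
#' conservative (non-interpolated) convention for imbalanced data. Returns
#' `NA` when no positives are present.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, or `NA_real_` if undefined.
#' @export
auprc <- function(y_true, y_score) {
  stopifnot(length(y_true) == length(y_score))
  n1 <- sum(y_true == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate at the last index of each tied score block
  last <- which(!duplicated(s, fromLast = TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(prec * diff(c(0, rec)))
}

#' Bootstrap percentile confidence interval for the median
#'
#' Non-parametric bootstrap of the median over per-fold metrics, percentile
#' 2.5/97.5 interval, deterministic given the seed. Undefined (`NA`) fold
#' metrics are excluded and counted.
#'
#' @param per_fold_metrics numeric vector (one value per LOSO fold; `NA` =
#'   undefined fold).
#' @param n_resamples bootstrap resamples (benchmark: 10,000).
#' @param seed RNG seed.
#' @return list with `median`, `ci_low`, `ci_high`, `n_folds` (defined
#'   folds), `n_undefined`.
#' @export
bootstrap_median_ci <- function(per_fold_metrics, n_resamples = 10000L, seed = 1L) {
  x <- per_fold_metrics[!is.na(per_fold_metrics)]
  n_undef <- sum(is.na(per_fold_metrics))
  if (length(x) < 2L)
    stop("bootstrap_median_ci needs at least 2 defined fold metrics", call. = FALSE)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- length(x)
  meds <- vapply(seq_len(n_resamples),
                 function(i) stats::median(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  ci <- unname(stats::quantile(meds, c(0.025, 0.975)))
  list(median = stats::median(x), ci_low = ci[1], ci_high = ci[2],
       n_folds = n, n_undefined = n_undef)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Pairs with zero difference are dropped (the Wilcoxon convention); if all
#' differences are zero the p-value is 1 with a warning. `NA` pairs are
#' removed. For up to 14 informative pairs the exact null distribution is
#' computed by enumerating all sign assignments (midranks handle tied
#' absolute differences); larger samples use the standard signed-rank test
#' from `stats`.
#'
#' @param metrics_a,metrics_b equal-length numeric vectors paired by
#'   surgery.
#' @return two-sided p-value.
#' @export
wilcoxon_paired <- function(metrics_a, metrics_b) {
  stopifnot(length(metrics_a) == length(metrics_b))
  ok <- !is.na(metrics_a) & !is.na(metrics_b)
  d <- metrics_a[ok] - metrics_b[ok]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  n <- length(d)
  if (n <= 14L) {
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- drop(signs %*% r)
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12))
  }
  suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "two.sided"))$p.value
}

#' Per-surgery adaptation-benefit analysis
#'
#' For each surgery present in both fold sets, computes the AUROC difference
#' between two models on the surgery's *common* evaluation region (the
#' intersection of the two folds' evaluation windows), so the comparison is
#' exactly paired. With a K=10 and a K=1 fold set the common region is the
#' K=10 evaluation remainder.
#'
#' @param folds_K10,folds_K1 `loso_result` objects (or lists of fold
#'   results) for the two models; same surgeries required.
#' @return list with `table` (surgery_id, delta), `n_improved`,
#'   `n_declined`, `fraction_improved`, `median_delta`, `iqr`.
#' @export
per_surgery_delta <- function(folds_K10, folds_K1) {
  f10 <- fold_list(folds_K10)
  f01 <- fold_list(folds_K1)
  ids10 <- vapply(f10, `[[`, character(1), "surgery_id")
  ids01 <- vapply(f01, `[[`, character(1), "surgery_id")
  if (!setequal(ids10, ids01) || anyDuplicated(ids10) || anyDuplicated(ids01))
    stop("mismatched surgery sets between fold lists", call. = FALSE)
  deltas <- rep(NA_real_, length(f10))
  for (i in seq_along(f10)) {
    a <- f10[[i]]
    b <- f01[[match(a$surgery_id, ids01)]]
    if (isTRUE(a$failed) || isTRUE(b$failed)) next
    common <- intersect(a$window_index, b$window_index)
    if (!length(common)) next
    ia <- match(common, a$window_index)
    ib <- match(common, b$window_index)
    deltas[i] <- auroc(a$y_true[ia], a$y_score[ia]) -
                 auroc(b$y_true[ib], b$y_score[ib])
  }
  tab <- data.frame(surgery_id = ids10, delta = deltas)
  d <- deltas[!is.na(deltas)]
  list(table = tab,
       n_improved = sum(d > 0),
       n_declined = sum(d < 0),
       fraction_improved = if (length(d)) sum(d > 0) / length(d) else NA_real_,
       median_delta = stats::median(d),
       iqr = unname(stats::quantile(d, c(0.25, 0.75))))
}

#' Summarize per-fold metrics
#'
#' Median with bootstrap CI plus the pooled metric computed on the
#' concatenation of all defined folds' predictions.
#'
#' @param folds a `loso_result`.
#' @param metric `"auroc"` or `"auprc"`.
#' @param n_resamples,seed passed to [bootstrap_median_ci()].
#' @return list with `median`, `ci_low`, `ci_high`, `n_folds`,
#'   `n_undefined`, `pooled`.
#' @export
summarize_folds <- function(folds, metric = c("auroc", "auprc"),
                            n_resamples = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  ff <- fold_list(folds)
  ff <- ff[!vapply(ff, function(f) isTRUE(f$failed), logical(1))]
  vals <- vapply(ff, function(f) f[[metric]] %||% NA_real_, numeric(1))
  y_all <- unlist(lapply(ff, `[[`, "y_true"))
  s_all <- unlist(lapply(ff, `[[`, "y_score"))
  pooled <- if (metric == "auroc") auroc(y_all, s_all) else auprc(y_all, s_all)
  out <- bootstrap_median_ci(vals, n_resamples, seed)
  out$pooled <- pooled
  out
}

fold_list <- function(x) {
  if (inherits(x, "loso_result")) unclass(x) else x
}
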