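#' Platt scaling
#'
#' Fits the monotone logistic mapping `p = plogis(a * s + b)` to raw scores
#' by maximum likelihood. Requires both classes in the fitting set; a
#' single-class set raises a skipped-fold condition (the benchmark's
#' "skipped fold": the adaptation window lacked positive or negative
#' events). If the scores are constant the slope is undefined and the
#' mapping returns the base rate.
#'
#' @param scores raw probability scores.
#' @param labels binary 0/1 labels.
#' @return an object of class `platt_map` with coefficients `a`, `b`;
#'   apply with [calibrate_scores()].
#' @export
fit_platt <- function(scores, labels) {
  check_both_classes(labels, "Platt")
  fit <- suppressWarnings(stats::glm(labels ~ scores, family = stats::binomial()))
  co <- stats::coef(fit)
  a <- unname(co["scores"])
  b <- unname(co["(Intercept)"])
  if (is.na(a)) a <- 0  # constant scores: slope unidentifiable, use base rate
  structure(list(a = a, b = b), class = "platt_map")
}

#' Isotonic regression calibration
#'
#' Nondecreasing step mapping minimizing squared error, fitted with the
#' pool-adjacent-violators algorithm on weight-aggregated unique scores.
#' Out-of-range inputs are clamped to the end steps. Requires both classes.
#'
#' @inheritParams fit_platt
#' @return an object of class `isotonic_map` with the step knots and fitted
#'   values; apply with [calibrate_scores()].
#' @export
fit_isotonic <- function(scores, labels) {
  check_both_classes(labels, "isotonic")
  ord <- order(scores)
  s <- scores[ord]
  y <- as.numeric(labels[ord])
  # aggregate tied scores (weighted mean), then weighted PAV
  ux <- unique(s)
  w <- as.numeric(table(match(s, ux)))
  ybar <- as.numeric(tapply(y, match(s, ux), mean))
  pav <- pava_weighted(ybar, w)
  structure(list(knots = ux, fitted = pav), class = "isotonic_map")
}

# Weighted pool-adjacent-violators: isotonic (nondecreasing) weighted
# least-squares fit. Stack-based linear-time implementation.
pava_weighted <- function(y, w) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], len[seq_len(top)])
}

check_both_classes <- function(labels, method) {
  if (length(unique(labels)) < 2L) {
    stop(structure(
      class = c("nocibench_skipped_fold", "error", "condition"),
      list(message = sprintf(
        "%s calibration skipped: a lack of both positive and negative events in the fitting set",
        method), call = NULL)))
  }
  invisible(TRUE)
}

#' Apply a calibration mapping
#'
#' @param mapping a `platt_map`, `isotonic_map`, or `"raw"` for the
#'   identity.
#' @param scores raw scores to calibrate.
#' @return calibrated probabilities.
#' @export
calibrate_scores <- function(mapping, scores) {
  if (identical(mapping, "raw")) return(scores)
  UseMethod("calibrate_scores")
}

#' @export
calibrate_scores.platt_map <- function(mapping, scores) {
  stats::plogis(mapping$a * scores + mapping$b)
}

#' @export
calibrate_scores.isotonic_map <- function(mapping, scores) {
  if (length(mapping$knots) == 1L) return(rep(mapping$fitted, length(scores)))
  stats::approx(mapping$knots, mapping$fitted, xout = scores,
                method = "constant", f = 0, rule = 2, ties = "ordered")$y
}

#' Expected calibration error with quantile bins
#'
#' Bins scores by deciles (default 10 quantile bins) with duplicate-edge
#' merging for heavily tied score distributions, then computes the
#' bin-count-weighted mean absolute gap between the mean predicted
#' probability and the observed event frequency:
#' `ECE = sum_b (n_b / N) * |mean_pred_b - obs_freq_b|`.
#' With fewer samples than bins, falls back to a single bin with a warning.
#'
#' @param scores probability scores.
#' @param labels binary 0/1 labels.
#' @param n_bins number of quantile bins (benchmark: 10).
#' @return the ECE value; the per-bin table (mean_predicted,
#'   observed_frequency, count) is attached as attribute `"bins"`.
#' @export
ece_quantile <- function(scores, labels, n_bins = 10L) {
  N <- length(scores)
  stopifnot(N == length(labels))
  if (N < n_bins) {
    warning("fewer samples than bins; using a single bin")
    n_bins <- 1L
  }
  edges <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) {
    bin <- rep(1L, N)  # all scores identical
  } else {
    bin <- cut(scores, breaks = edges, include.lowest = TRUE, labels = FALSE)
  }
  mean_pred <- tapply(scores, bin, mean)
  obs_freq <- tapply(as.numeric(labels), bin, mean)
  count <- as.numeric(table(bin))
  ece <- sum(count / N * abs(mean_pred - obs_freq))
  structure(ece, bins = data.frame(mean_predicted = as.numeric(mean_pred),
                                   observed_frequency = as.numeric(obs_freq),
                                   count = count))
}

#' Brier score
#'
#' Mean squared error between predicted probability and binary outcome.
#'
#' @inheritParams ece_quantile
#' @return the Brier score.
#' @export
brier <- function(scores, labels) {
  mean((scores - as.numeric(labels))^2)
}

#' Calibrate one LOSO fold and report
#'
#' Fits the chosen calibrator and applies it to the fold's evaluation
#' scores. With `fit_on = "adaptation"` (default) the calibrator is fitted
#' on the fold's adaptation-segment predictions — the only regime in which
#' "skipped folds" are meaningful: Platt and isotonic fitting is skipped
#' exactly when the adaptation labels are single-class. With
#' `fit_on = "pooled_eval"` the calibrator is refitted on the evaluation
#' predictions themselves (a refit-on-self regime; isotonic ECE is then
#' essentially zero by construction).
#'
#' @param fold one fold from a personalized [run_loso()] run (must carry an
#'   `adapt` segment when `fit_on = "adaptation"`).
#' @param method `"raw"`, `"platt"`, or `"isotonic"`.
#' @param fit_on `"adaptation"` or `"pooled_eval"`.
#' @param n_bins quantile bins for the ECE.
#' @return an object of class `calibration_report`: method, fit_on, brier,
#'   ece, auroc, bins, skipped, reason.
#' @export
calibrate_fold <- function(fold, method = c("raw", "platt", "isotonic"),
                           fit_on = c("adaptation", "pooled_eval"),
                           n_bins = 10L) {
  method <- match.arg(method)
  fit_on <- match.arg(fit_on)
  out <- list(method = method, fit_on = fit_on, surgery_id = fold$surgery_id,
              skipped = FALSE, reason = NULL)
  mapping <- "raw"
  if (method != "raw") {
    if (fit_on == "adaptation") {
      if (is.null(fold$adapt))
        stop("fold carries no adaptation segment; run_loso with K_minutes > 0",
             call. = FALSE)
      fs <- fold$adapt$y_score; fl <- fold$adapt$y_true
    } else {
      fs <- fold$y_score; fl <- fold$y_true
    }
    mapping <- tryCatch(
      if (method == "platt") fit_platt(fs, fl) else fit_isotonic(fs, fl),
      nocibench_skipped_fold = function(e) {
        out$skipped <<- TRUE
        out$reason <<- conditionMessage(e)
        NULL
      })
    if (out$skipped) {
      out[c("brier", "ece", "auroc")] <- NA_real_
      return(structure(out, class = "calibration_report"))
    }
  }
  cal <- calibrate_scores(mapping, fold$y_score)
  e <- ece_quantile(cal, fold$y_true, n_bins)
  out$brier <- brier(cal, fold$y_true)
  out$ece <- as.numeric(e)
  out$auroc <- auroc(fold$y_true, cal)
  out$bins <- attr(e, "bins")
  structure(out, class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("Calibration (%s, %s): SKIPPED - %s\n", x$method, x$fit_on, x$reason))
  } else {
    cat(sprintf("Calibration (%s, %s): Brier %.4f, ECE %.4g, AUROC %s\n",
                x$method, x$fit_on, x$brier, x$ece,
                ifelse(is.na(x$auroc), "undefined", sprintf("%.3f", x$auroc))))
  }
  invisible(x)
}

#' Skipped-fold census across adaptation windows
#'
#' For each K, counts the LOSO folds whose adaptation segment is
#' single-class (so Platt/isotonic fitting must be skipped). Because
#' adaptation windows nest (the K-minute segment extends the shorter one),
#' the count is non-increasing in K on any cohort.
#'
#' @param cohort a `noci_cohort`.
#' @param K_list adaptation windows in minutes.
#' @return data frame with `K_minutes` and `skipped` counts.
#' @export
skipped_fold_census <- function(cohort, K_list = c(1L, 2L, 5L, 10L)) {
  records <- if (inherits(cohort, "noci_cohort")) unclass(cohort) else cohort
  skipped <- vapply(K_list, function(K) {
    sum(vapply(records, function(r) {
      n_adapt <- min(12L * K, n_windows(r))
      length(unique(r$label[seq_len(n_adapt)])) < 2L
    }, logical(1)))
  }, numeric(1))
  data.frame(K_minutes = K_list, skipped = as.integer(skipped))
}
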