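#' Diagnostic plots
#'
#' Base-graphics renderings of the benchmark's standard figures: the
#' per-surgery adaptation-benefit histogram, reliability curves, the gate
#' alpha surface, and permutation-importance bars.
#'
#' @param delta output of [per_surgery_delta()].
#' @param ... passed to the underlying graphics call.
#' @name noci_plots
NULL

#' @rdname noci_plots
#' @export
plot_delta_histogram <- function(delta, ...) {
  d <- delta$table$delta
  graphics::hist(d[!is.na(d)], breaks = 20,
                 main = "Per-surgery AUROC change",
                 xlab = expression(Delta * "AUROC (long - short adaptation)"),
                 col = "grey80", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(delta)
}

#' @rdname noci_plots
#' @param reports list of `calibration_report`s (one per method) for one
#'   pooled evaluation.
#' @export
plot_reliability <- function(reports, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey50",
                 xlab = "Mean predicted probability",
                 ylab = "Observed frequency", main = "Reliability curves", ...)
  cols <- c(raw = "black", platt = "steelblue", isotonic = "firebrick")
  for (r in reports) {
    if (isTRUE(r$skipped) || is.null(r$bins)) next
    graphics::lines(r$bins$mean_predicted, r$bins$observed_frequency,
                    type = "b", pch = 16, col = cols[[r$method]] %||% "darkgreen")
  }
  graphics::legend("topleft", legend = vapply(reports, `[[`, character(1), "method"),
                   col = vapply(reports, function(r) cols[[r$method]] %||% "darkgreen",
                                character(1)),
                   lty = 1, pch = 16, bty = "n")
  invisible(reports)
}

#' @rdname noci_plots
#' @param surface matrix from [alpha_sweep()].
#' @export
plot_alpha_surface <- function(surface, ...) {
  feats <- attr(surface, "features") %||% c("feature 1", "feature 2")
  graphics::image(as.numeric(rownames(surface)), as.numeric(colnames(surface)),
                  surface, xlab = feats[1], ylab = feats[2],
                  main = expression("GateNet " * alpha * " surface"),
                  col = grDevices::hcl.colors(50, "viridis"), zlim = c(0, 1), ...)
  invisible(surface)
}

#' @rdname noci_plots
#' @param importance named vector from [permutation_importance()].
#' @param top_n how many features to show.
#' @export
plot_importance <- function(importance, top_n = 10L, ...) {
  imp <- sort(importance, decreasing = TRUE)[seq_len(min(top_n, length(importance)))]
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "Permutation importance (AUROC drop)",
                    main = "Top features", ...)
  invisible(importance)
}
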