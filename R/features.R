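#' Assemble a pooled design matrix from surgery records
#'
#' Concatenates per-window feature rows across surgeries (surgery order,
#' then window order). The drug-aware mode yields 48 columns (15 autonomic +
#' 15 first-derivative + 9 cumulative-dose + 9 time-since-dose); the
#' drug-naive mode yields the 30 physiologic columns only. Missing values in
#' drug-dosing columns are imputed to zero before any scaling.
#'
#' @param records a `noci_cohort` or list of `surgery_record`s.
#' @param mode `"aware"` (physiologic + drug covariates) or `"naive"`.
#' @return a `feature_matrix`: list with `X` (numeric matrix), `y` (0/1
#'   integer vector), `surgery_of_row` (character), `column_names`, and
#'   `scaler` (`NULL` until [pooled_standard_scale()] is applied).
#' @export
assemble_matrix <- function(records, mode = c("aware", "naive")) {
  mode <- match.arg(mode)
  if (!length(records)) stop("schema error: empty record list", call. = FALSE)
  rows <- lapply(records, record_feature_rows, mode = mode)
  cn <- colnames(rows[[1]])
  for (r in rows) {
    if (!identical(colnames(r), cn))
      stop("schema error: inconsistent column sets across surgeries", call. = FALSE)
  }
  X <- do.call(rbind, rows)
  y <- unlist(lapply(records, `[[`, "label"), use.names = FALSE)
  ids <- unlist(lapply(records, function(r) rep(r$surgery_id, n_windows(r))), use.names = FALSE)
  structure(list(X = X, y = as.integer(y), surgery_of_row = ids,
                 column_names = cn, scaler = NULL, mode = mode),
            class = "feature_matrix")
}

# Per-window feature rows for one surgery, in the canonical column order.
record_feature_rows <- function(record, mode = c("aware", "naive")) {
  mode <- match.arg(mode)
  X <- cbind(record$autonomic, record$autonomic_derivative)
  if (mode == "aware") {
    drugs <- cbind(record$drug_cumulative, record$drug_time_since)
    drugs[is.na(drugs)] <- 0  # zero imputation for missing drug dosing
    X <- cbind(X, drugs)
  }
  X
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d windows x %d columns (%s), %d surgeries, prevalence %.4f%s\n",
              nrow(x$X), ncol(x$X), x$mode, length(unique(x$surgery_of_row)),
              mean(x$y), if (is.null(x$scaler)) "" else ", standardized"))
  invisible(x)
}

#' Standard-scale a pooled design matrix
#'
#' Centers each column to mean zero and scales to unit variance using the
#' population (divide-by-N) standard deviation, so the fitted columns have
#' exactly unit variance. Zero-variance columns are centered to zero and
#' their divisor is recorded as 1. The fitted `(mean, sd)` pairs are stored
#' in the returned object's `scaler` for reuse on new data via
#' [apply_scaler()].
#'
#' @param matrix a `feature_matrix` from [assemble_matrix()].
#' @return the scaled `feature_matrix`, with `scaler` populated.
#' @export
pooled_standard_scale <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  sc <- fit_scaler(matrix$X)
  matrix$X <- scale_with(matrix$X, sc)
  matrix$scaler <- sc
  matrix
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd_pop[sd_pop < .Machine$double.eps^0.5] <- 1  # zero-variance convention
  list(mean = mu, sd = sd_pop)
}

scale_with <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Apply or invert a fitted scaler
#'
#' @param matrix a `feature_matrix`, or a plain numeric matrix.
#' @param scaler a scaler as stored by [pooled_standard_scale()].
#' @return the transformed object of the same type.
#' @export
apply_scaler <- function(matrix, scaler) {
  if (inherits(matrix, "feature_matrix")) {
    matrix$X <- scale_with(matrix$X, scaler)
    matrix$scaler <- scaler
    matrix
  } else {
    scale_with(matrix, scaler)
  }
}

#' @rdname apply_scaler
#' @export
inverse_scale <- function(matrix, scaler = NULL) {
  if (inherits(matrix, "feature_matrix")) {
    sc <- scaler %||% matrix$scaler
    if (is.null(sc)) stop("no scaler stored on this feature_matrix", call. = FALSE)
    matrix$X <- sweep(sweep(matrix$X, 2, sc$sd, "*"), 2, sc$mean, "+")
    matrix$scaler <- NULL
    matrix
  } else {
    sweep(sweep(matrix, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a held-out surgery into adaptation and evaluation segments
#'
#' The first `12 * K_minutes` windows (K minutes at 12 windows/minute) form
#' the patient-specific adaptation segment; the remainder is the evaluation
#' segment. The partition is exact and disjoint.
#'
#' @param record a `surgery_record`.
#' @param K_minutes adaptation length in minutes (1, 2, 5 or 10 in the
#'   benchmark protocol; any positive integer is accepted).
#' @return list with elements `adaptation` and `evaluation`, both
#'   `surgery_record`s.
#' @export
split_adaptation_evaluation <- function(record, K_minutes) {
  stopifnot(inherits(record, "surgery_record"), K_minutes > 0)
  n_adapt <- as.integer(12 * K_minutes)
  n <- n_windows(record)
  if (n < n_adapt + 1L) {
    stop(insufficient_data_error(sprintf(
      "surgery %s has %d windows; K=%d minutes needs at least %d",
      record$surgery_id, n, K_minutes, n_adapt + 1L)))
  }
  list(adaptation = subset_record(record, seq_len(n_adapt)),
       evaluation = subset_record(record, (n_adapt + 1L):n))
}

insufficient_data_error <- function(msg) {
  structure(class = c("nocibench_insufficient_data", "error", "condition"),
            list(message = msg, call = NULL))
}
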