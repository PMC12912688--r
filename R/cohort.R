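#' Synthetic surgical cohort configuration
#'
#' Describes the generative model for a multi-surgery cohort of windowed
#' physiologic features, drug-dosing chronology covariates and binary
#' nociceptive-event labels. Features are tabulated in non-overlapping
#' 5-second windows (12 windows per minute). Nociceptive stimuli arrive as a
#' homogeneous point process; each stimulus marks a short run of positive
#' windows and injects an exponentially decaying response into the autonomic
#' channels, attenuated by cumulative anesthetic dosing.
#'
#' The stimulus rate is solved from `target_prevalence`: with rate
#' \eqn{\lambda} per minute and a positive-label run of \eqn{L} windows per
#' stimulus, the probability that a window is positive is
#' \eqn{1 - \exp(-\lambda L / 12)}, so
#' \eqn{\lambda = -12 \log(1 - p) / L}.
#'
#' @param n_surgeries number of surgeries in the cohort.
#' @param duration_minutes_range length-2 numeric, uniform range of surgery
#'   durations in minutes.
#' @param window_seconds window length in seconds (fixed at 5 in this study
#'   design; 12 windows per minute).
#' @param target_prevalence desired pooled fraction of positive windows.
#' @param n_autonomic number of autonomic channels (each also contributes a
#'   first-derivative channel).
#' @param n_drug_classes number of anesthetic drug classes (each contributes
#'   cumulative-dose and time-since-dose covariates).
#' @param event_rate_per_min stimulus arrival rate; `NULL` (default) solves
#'   it from `target_prevalence`.
#' @param response_amplitude nonnegative response amplitude per autonomic
#'   channel (recycled if scalar).
#' @param response_decay_windows exponential decay constant of the autonomic
#'   response, in windows; the positive-label run per stimulus is
#'   `ceiling(response_decay_windows / 2)` windows.
#' @param drug_attenuation per-class attenuation strength in `[0, 1]`
#'   (recycled); subsequent response amplitudes are multiplied by
#'   `prod_j (1 - a_j * c_j / (1 + c_j))` where `c_j` is cumulative dose.
#' @param dose_rate_per_min dose arrival rate per drug class, doses/minute.
#' @param noise_sd white-noise standard deviation on each autonomic channel.
#' @param surgery_heterogeneity_sd standard deviation of the per-surgery,
#'   per-channel baseline shift.
#' @param seed integer; per-surgery child seeds are `seed + ordinal`.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_surgeries = 101L,
                          duration_minutes_range = c(120, 240),
                          window_seconds = 5,
                          target_prevalence = 0.06,
                          n_autonomic = 15L,
                          n_drug_classes = 9L,
                          event_rate_per_min = NULL,
                          response_amplitude = round(2 * exp(-(seq_len(n_autonomic) - 1) / 4), 3),
                          response_decay_windows = 6L,
                          drug_attenuation = 0.2,
                          dose_rate_per_min = 0.05,
                          noise_sd = 1,
                          surgery_heterogeneity_sd = 0.5,
                          seed = 1L) {
  if (length(n_surgeries) != 1L || is.na(n_surgeries) || n_surgeries < 1)
    stop("configuration error: n_surgeries must be a positive integer", call. = FALSE)
  if (length(duration_minutes_range) != 2L || any(duration_minutes_range <= 0) ||
      duration_minutes_range[2] < duration_minutes_range[1])
    stop("configuration error: duration_minutes_range must be positive (min, max)", call. = FALSE)
  if (window_seconds <= 0)
    stop("configuration error: window_seconds must be positive", call. = FALSE)
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("configuration error: target_prevalence must lie in (0, 1)", call. = FALSE)
  if (noise_sd <= 0 || surgery_heterogeneity_sd < 0)
    stop("configuration error: noise_sd must be > 0 and surgery_heterogeneity_sd >= 0", call. = FALSE)
  if (any(response_amplitude < 0))
    stop("configuration error: response_amplitude must be nonnegative", call. = FALSE)
  if (any(drug_attenuation < 0 | drug_attenuation > 1))
    stop("configuration error: drug_attenuation must lie in [0, 1]", call. = FALSE)
  n_autonomic <- as.integer(n_autonomic)
  n_drug_classes <- as.integer(n_drug_classes)
  response_amplitude <- rep_len(as.numeric(response_amplitude), n_autonomic)
  drug_attenuation <- rep_len(as.numeric(drug_attenuation), n_drug_classes)
  windows_per_min <- 60 / window_seconds
  run_len <- as.integer(ceiling(response_decay_windows / 2))
  if (is.null(event_rate_per_min)) {
    # solve P(window positive) = 1 - exp(-rate * run_len / wpm) = prevalence
    event_rate_per_min <- -windows_per_min * log(1 - target_prevalence) / run_len
  }
  structure(list(
    n_surgeries = as.integer(n_surgeries),
    duration_minutes_range = as.numeric(duration_minutes_range),
    window_seconds = as.numeric(window_seconds),
    target_prevalence = target_prevalence,
    n_autonomic = n_autonomic,
    n_drug_classes = n_drug_classes,
    event_rate_per_min = event_rate_per_min,
    response_amplitude = response_amplitude,
    response_decay_windows = as.integer(response_decay_windows),
    drug_attenuation = drug_attenuation,
    dose_rate_per_min = dose_rate_per_min,
    noise_sd = noise_sd,
    surgery_heterogeneity_sd = surgery_heterogeneity_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  surgeries: %d, duration %g-%g min, %g-s windows\n",
              x$n_surgeries, x$duration_minutes_range[1],
              x$duration_minutes_range[2], x$window_seconds))
  cat(sprintf("  target prevalence: %.3f (stimulus rate %.4f/min)\n",
              x$target_prevalence, x$event_rate_per_min))
  cat(sprintf("  %d autonomic channels (+derivatives), %d drug classes\n",
              x$n_autonomic, x$n_drug_classes))
  invisible(x)
}

windows_per_minute <- function(config) 60 / config$window_seconds

label_run_length <- function(config) as.integer(ceiling(config$response_decay_windows / 2))

#' Generate a synthetic surgical cohort
#'
#' Draws `n_surgeries` independent surgery records under the generative model
#' described in [cohort_config()]. Generation is deterministic given the
#' config seed; each surgery uses the child seed `seed + ordinal` so records
#' are reproducible independently of one another.
#'
#' @param config a [cohort_config()] object.
#' @return a list of `surgery_record` objects with class `noci_cohort`; the
#'   config is attached as attribute `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_surgeries = 3,
#'                                         duration_minutes_range = c(10, 15),
#'                                         seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  records <- vector("list", config$n_surgeries)
  for (i in seq_len(config$n_surgeries)) {
    records[[i]] <- generate_surgery(config, ordinal = i)
  }
  structure(records, class = "noci_cohort", config = config)
}

#' @export
print.noci_cohort <- function(x, ...) {
  nw <- vapply(x, function(r) length(r$label), integer(1))
  prev <- sum(vapply(x, function(r) sum(r$label), numeric(1))) / sum(nw)
  cat(sprintf("Synthetic cohort: %d surgeries, %d windows total, pooled prevalence %.4f\n",
              length(x), sum(nw), prev))
  invisible(x)
}

# One surgery under the generative scheme. Labels come from the stimulus
# process alone (independent of attenuation), so prevalence control is exact
# in expectation regardless of drug dosing.
generate_surgery <- function(config, ordinal) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$seed + ordinal)

  wpm <- windows_per_minute(config)
  minutes <- stats::runif(1, config$duration_minutes_range[1], config$duration_minutes_range[2])
  n <- max(2L, as.integer(round(minutes * wpm)))
  C <- config$n_autonomic
  D <- config$n_drug_classes
  run_len <- label_run_length(config)

  # drug dosing chronology: Poisson arrivals per class, unit dose size
  cumdose <- matrix(0, n, D)
  tsince <- matrix(0, n, D)
  dose_windows <- vector("list", D)
  for (j in seq_len(D)) {
    n_doses <- stats::rpois(1, config$dose_rate_per_min * minutes)
    dw <- sort(unique(1L + as.integer(floor(stats::runif(n_doses) * n))))
    dw <- dw[dw <= n]
    dose_windows[[j]] <- dw
    dosed <- integer(n)
    dosed[dw] <- 1L
    cumdose[, j] <- cumsum(dosed)
    # time since dose: 0 at a dose window, + window_seconds/60 each window after;
    # before the first dose it counts minutes since surgery start
    tick <- config$window_seconds / 60
    t_min <- (seq_len(n) - 1) * tick
    last_dose_t <- rep(0, n)
    if (length(dw)) {
      idx <- findInterval(seq_len(n), dw)
      has_prior <- idx > 0
      last_dose_t[has_prior] <- t_min[dw][idx[has_prior]]
    }
    tsince[, j] <- t_min - last_dose_t
  }

  # stimulus process: homogeneous Poisson at event_rate_per_min
  n_stim <- stats::rpois(1, config$event_rate_per_min * minutes)
  stim_w <- sort(1L + as.integer(floor(stats::runif(n_stim) * n)))

  label <- integer(n)
  for (s in stim_w) {
    label[s:min(n, s + run_len - 1L)] <- 1L
  }

  # attenuation at stimulus onset: saturating in cumulative dose, per class
  response <- matrix(0, n, C)
  if (length(stim_w)) {
    span <- min(n, as.integer(ceiling(config$response_decay_windows * 9)))
    kernel <- exp(-(0:(span - 1)) / config$response_decay_windows)
    for (s in stim_w) {
      cd <- cumdose[s, ]
      atten <- prod(1 - config$drug_attenuation * cd / (1 + cd))
      idx <- s:min(n, s + span - 1L)
      response[idx, ] <- response[idx, ] +
        kernel[seq_along(idx)] %o% (config$response_amplitude * atten)
    }
  }

  baseline <- stats::rnorm(C, 0, config$surgery_heterogeneity_sd)
  noise <- matrix(stats::rnorm(n * C, 0, config$noise_sd), n, C)
  autonomic <- sweep(response + noise, 2, baseline, "+")

  deriv <- rbind(0, diff(autonomic)) / config$window_seconds

  colnames(autonomic) <- sprintf("a%02d", seq_len(C))
  colnames(deriv) <- sprintf("d_a%02d", seq_len(C))
  colnames(cumdose) <- sprintf("cumdose_%d", seq_len(D))
  colnames(tsince) <- sprintf("tsince_%d", seq_len(D))

  structure(list(
    surgery_id = sprintf("S%03d", ordinal),
    window_index = 0:(n - 1L),
    autonomic = autonomic,
    autonomic_derivative = deriv,
    drug_cumulative = cumdose,
    drug_time_since = tsince,
    label = label
  ), class = "surgery_record")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.surgery_record <- function(x, ...) {
  cat(sprintf("Surgery %s: %d windows, %d positive (%.3f)\n",
              x$surgery_id, length(x$label), sum(x$label), mean(x$label)))
  invisible(x)
}

n_windows <- function(record) length(record$label)

# Subset a record's windows, keeping all matrices aligned.
subset_record <- function(record, idx) {
  structure(list(
    surgery_id = record$surgery_id,
    window_index = record$window_index[idx],
    autonomic = record$autonomic[idx, , drop = FALSE],
    autonomic_derivative = record$autonomic_derivative[idx, , drop = FALSE],
    drug_cumulative = record$drug_cumulative[idx, , drop = FALSE],
    drug_time_since = record$drug_time_since[idx, , drop = FALSE],
    label = record$label[idx]
  ), class = "surgery_record")
}

validate_surgery_record <- function(record) {
  n <- length(record$label)
  mats <- list(autonomic = record$autonomic,
               autonomic_derivative = record$autonomic_derivative,
               drug_cumulative = record$drug_cumulative,
               drug_time_since = record$drug_time_since)
  for (nm in names(mats)) {
    if (nrow(mats[[nm]]) != n)
      stop(sprintf("format error: %s has %d rows, expected %d", nm, nrow(mats[[nm]]), n),
           call. = FALSE)
    if (anyNA(mats[[nm]]))
      stop(sprintf("format error: missing values in %s", nm), call. = FALSE)
  }
  if (!all(record$label %in% c(0L, 1L)))
    stop("format error: column label must be binary 0/1", call. = FALSE)
  if (!identical(as.integer(record$window_index), 0:(n - 1L)))
    stop("format error: column window_index must be contiguous and 0-based", call. = FALSE)
  if (any(apply(record$drug_cumulative, 2, function(z) any(diff(z) < 0))))
    stop("format error: drug_cumulative must be nondecreasing", call. = FALSE)
  invisible(record)
}

#' Convert a surgery record to a data frame
#'
#' Column layout matches the on-disk CSV schema: `surgery_id`,
#' `window_index`, `a01..`, `d_a01..`, `cumdose_1..`, `tsince_1..`, `label`.
#'
#' @param x a `surgery_record`.
#' @param ... unused.
#' @export
as.data.frame.surgery_record <- function(x, ...) {
  data.frame(surgery_id = x$surgery_id,
             window_index = x$window_index,
             x$autonomic, x$autonomic_derivative,
             x$drug_cumulative, x$drug_time_since,
             label = x$label,
             check.names = FALSE)
}

#' Write / read a cohort as per-surgery CSV files
#'
#' One UTF-8 CSV per surgery (`<surgery_id>.csv`), header row, '.' decimal
#' separator, numeric values at 15 significant digits so that a write/read
#' round trip is an identity to at least 12 significant digits.
#'
#' @param records a `noci_cohort` or list of `surgery_record`s.
#' @param directory_path directory to write into (created if needed).
#' @return `write_cohort` returns the written file paths invisibly;
#'   `read_cohort` returns a `noci_cohort`.
#' @export
write_cohort <- function(records, directory_path) {
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    validate_surgery_record(r)
    df <- as.data.frame(r)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(z) sprintf("%.15g", z))
    paths[i] <- file.path(directory_path, paste0(r$surgery_id, ".csv"))
    utils::write.csv(df, paths[i], row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory_path) {
  files <- sort(list.files(directory_path, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("format error: no CSV files in ", directory_path, call. = FALSE)
  records <- lapply(files, read_surgery_csv)
  structure(records, class = "noci_cohort")
}

read_surgery_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  cols <- names(df)
  a_cols <- grep("^a[0-9]{2}$", cols, value = TRUE)
  d_cols <- grep("^d_a[0-9]{2}$", cols, value = TRUE)
  c_cols <- grep("^cumdose_[0-9]+$", cols, value = TRUE)
  t_cols <- grep("^tsince_[0-9]+$", cols, value = TRUE)
  for (required in c("surgery_id", "window_index", "label")) {
    if (!required %in% cols)
      stop("format error: missing column ", required, call. = FALSE)
  }
  if (!length(a_cols)) stop("format error: missing column a01", call. = FALSE)
  if (length(d_cols) != length(a_cols))
    stop("format error: derivative columns do not match autonomic columns", call. = FALSE)
  if (length(t_cols) != length(c_cols))
    stop("format error: tsince columns do not match cumdose columns", call. = FALSE)
  if (!all(df$label %in% c(0, 1)))
    stop("format error: column label must be binary 0/1", call. = FALSE)
  record <- structure(list(
    surgery_id = as.character(df$surgery_id[1]),
    window_index = as.integer(df$window_index),
    autonomic = as.matrix(df[a_cols]),
    autonomic_derivative = as.matrix(df[d_cols]),
    drug_cumulative = as.matrix(df[c_cols]),
    drug_time_since = as.matrix(df[t_cols]),
    label = as.integer(df$label)
  ), class = "surgery_record")
  validate_surgery_record(record)
  record
}
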