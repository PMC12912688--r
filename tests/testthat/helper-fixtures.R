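# Shared fixtures, all generated in code at test time.

# Small cohort with moderate signal (defaults except size).
tiny_cohort <- function(n = 5, mins = c(15, 20), seed = 7, ...) {
  generate_cohort(cohort_config(n_surgeries = n, duration_minutes_range = mins,
                                seed = seed, ...))
}

# Signal-free cohort: labels independent of all features.
null_cohort <- function(n = 5, mins = c(15, 20), seed = 7) {
  tiny_cohort(n, mins, seed, response_amplitude = 0, drug_attenuation = 0)
}

# Drug-informative cohort: one drug class attenuates responses almost
# completely, clean-state responses are near-perfectly detectable, and each
# surgery is dosed roughly once per half hour — the regime in which the
# drug-chronology covariates carry the most usable information.
drug_informative_cohort <- function(n = 8, mins = c(30, 40), seed = 11) {
  generate_cohort(cohort_config(
    n_surgeries = n, duration_minutes_range = mins,
    drug_attenuation = c(0.98, rep(0, 8)), dose_rate_per_min = 0.03,
    response_amplitude = round(8 * exp(-(0:14) / 4), 3),
    noise_sd = 0.5, surgery_heterogeneity_sd = 0.3, seed = seed))
}

# Plain feature_matrix from raw columns (for model unit tests).
make_fm <- function(X, y, mode = "naive") {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = as.integer(y),
                 surgery_of_row = rep("S1", nrow(X)),
                 column_names = colnames(X), scaler = NULL, mode = mode),
            class = "feature_matrix")
}

# O(N^2) brute-force AUROC: explicit pair counting, ties worth 1/2.
auroc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}
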