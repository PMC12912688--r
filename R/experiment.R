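#' Run the full benchmark experiment from a configuration
#'
#' Orchestrates the pipeline end-to-end: cohort (synthetic or from a CSV
#' directory), LOSO evaluation of the requested models in the requested
#' feature modes, calibration analysis of the personalized model,
#' ensemble strategies over out-of-fold base predictions, per-surgery
#' adaptation-benefit analysis, and the analytic compute-cost report.
#' Every output is regenerable from the configuration and seed alone.
#'
#' Configuration fields (YAML/JSON file or list): `cohort` (either
#' [cohort_config()] arguments or `list(directory = ...)`), `modes`
#' (subset of `"aware"`, `"naive"`), `models` (subset of `"lr"`, `"rf50"`,
#' `"rf200"`, `"tcn"`), `K_list` (adaptation minutes for the personalized
#' model), `calibration_methods`, `ensemble_strategies`, `seed`,
#' `output_dir`.
#'
#' @param config list, or path to a YAML/JSON config file.
#' @param output_dir overrides the config's output directory.
#' @return invisibly, a list with all stage results and the paths written;
#'   element `failed_stages` names any stage that errored.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    config <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
              else yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(list(
    modes = "aware", models = c("rf200", "tcn"), K_list = c(1L, 10L),
    calibration_methods = c("raw", "platt", "isotonic"),
    ensemble_strategies = c("linear_fixed", "linear_regressed",
                            "meta_logistic", "meta_mlp", "gatenet"),
    seed = 1L, output_dir = "nocibench_results"
  ), config)
  out_dir <- output_dir %||% cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  failed <- character(0)
  results <- list()

  # ---- cohort ----
  if (!is.null(cfg$cohort$directory)) {
    if (!dir.exists(cfg$cohort$directory))
      stop("cohort data directory not found: ", cfg$cohort$directory, call. = FALSE)
    cohort <- read_cohort(cfg$cohort$directory)
    log_stage("cohort", sprintf("read %d surgeries from %s",
                                length(cohort), cfg$cohort$directory))
  } else {
    cc_args <- cfg$cohort %||% list()
    if (is.null(cc_args$seed)) cc_args$seed <- cfg$seed
    cohort <- generate_cohort(do.call(cohort_config, cc_args))
    log_stage("cohort", sprintf("generated %d surgeries", length(cohort)))
  }
  results$cohort <- cohort

  make_recipe <- function(model, mode) {
    switch(model,
           lr = recipe_lasso(mode),
           rf50 = recipe_rf(mode, n_trees = 50L),
           rf200 = recipe_rf(mode, n_trees = 200L),
           tcn = recipe_tcn(mode),
           stop("unknown model recipe: ", model, call. = FALSE))
  }

  # ---- LOSO runs ----
  runs <- list()
  summary_rows <- list()
  for (mode in cfg$modes) {
    for (model in cfg$models) {
      K_values <- if (model == "tcn") cfg$K_list else 0L
      for (K in K_values) {
        key <- sprintf("%s_%s_K%d", model, mode, K)
        res <- tryCatch({
          r <- run_loso(cohort, make_recipe(model, mode), K_minutes = K,
                        seed = cfg$seed)
          log_stage("loso", key)
          r
        }, error = function(e) {
          log_stage("loso", sprintf("%s FAILED: %s", key, conditionMessage(e)))
          failed <<- c(failed, key)
          NULL
        })
        if (is.null(res)) next
        runs[[key]] <- res
        for (metric in c("auroc", "auprc")) {
          sm <- tryCatch(summarize_folds(res, metric, seed = cfg$seed),
                         error = function(e) NULL)
          if (!is.null(sm))
            summary_rows[[paste(key, metric)]] <- data.frame(
              model = model, mode = mode, K_minutes = K, metric = metric,
              median = sm$median, ci_low = sm$ci_low, ci_high = sm$ci_high,
              pooled = sm$pooled, n_folds = sm$n_folds,
              n_undefined = sm$n_undefined)
        }
      }
    }
  }
  results$runs <- runs
  folds_df <- do.call(rbind, lapply(runs, as.data.frame))
  utils::write.csv(folds_df, file.path(out_dir, "folds.csv"), row.names = FALSE)
  summary_df <- do.call(rbind, summary_rows)
  utils::write.csv(summary_df, file.path(out_dir, "model_summary.csv"), row.names = FALSE)
  results$summary <- summary_df

  # ---- calibration of the personalized model at the longest K ----
  cal_df <- NULL
  Kmax <- max(cfg$K_list)
  tcn_key <- sprintf("tcn_%s_K%d", cfg$modes[1], Kmax)
  if (!is.null(runs[[tcn_key]])) {
    cal_rows <- list()
    for (method in cfg$calibration_methods) {
      reports <- lapply(fold_list(runs[[tcn_key]]), function(f) {
        if (isTRUE(f$failed)) return(NULL)
        calibrate_fold(f, method)
      })
      reports <- Filter(Negate(is.null), reports)
      skipped <- vapply(reports, `[[`, logical(1), "skipped")
      ok <- reports[!skipped]
      cal_rows[[method]] <- data.frame(
        method = method, K_minutes = Kmax,
        median_brier = stats::median(vapply(ok, `[[`, numeric(1), "brier")),
        median_ece = stats::median(vapply(ok, `[[`, numeric(1), "ece")),
        median_auroc = stats::median(vapply(ok, `[[`, numeric(1), "auroc"), na.rm = TRUE),
        n_skipped = sum(skipped), n_folds = length(reports))
    }
    cal_df <- do.call(rbind, cal_rows)
    utils::write.csv(cal_df, file.path(out_dir, "calibration.csv"), row.names = FALSE)
    census <- skipped_fold_census(cohort, cfg$K_list)
    utils::write.csv(census, file.path(out_dir, "skipped_folds.csv"), row.names = FALSE)
    results$calibration <- cal_df
    results$skipped_folds <- census
    log_stage("calibration", "done")
  }

  # ---- per-surgery adaptation benefit (max vs min K) ----
  if (length(cfg$K_list) >= 2 && "tcn" %in% cfg$models) {
    Kmin <- min(cfg$K_list)
    khi <- sprintf("tcn_%s_K%d", cfg$modes[1], Kmax)
    klo <- sprintf("tcn_%s_K%d", cfg$modes[1], Kmin)
    if (!is.null(runs[[khi]]) && !is.null(runs[[klo]])) {
      delta <- per_surgery_delta(runs[[khi]], runs[[klo]])
      utils::write.csv(delta$table, file.path(out_dir, "delta_per_surgery.csv"),
                       row.names = FALSE)
      results$delta <- delta
      log_stage("delta", sprintf("%d improved / %d declined",
                                 delta$n_improved, delta$n_declined))
    }
  }

  # ---- ensembles over out-of-fold base predictions ----
  rf_key <- intersect(c(sprintf("rf200_%s_K0", cfg$modes[1]),
                        sprintf("rf50_%s_K0", cfg$modes[1])), names(runs))
  if (length(rf_key) && !is.null(runs[[tcn_key]])) {
    ens <- tryCatch({
      oof <- oof_table(runs[[rf_key[1]]], runs[[tcn_key]], cohort, cfg$modes[1])
      ens_rows <- lapply(cfg$ensemble_strategies, function(strategy) {
        p <- ensemble_oof_predictions(oof, strategy, seed = cfg$seed)
        data.frame(strategy = strategy,
                   pooled_auroc = auroc(oof$labels, p),
                   pooled_auprc = auprc(oof$labels, p),
                   p_vs_rf = wilcoxon_vs_base(oof, p, oof$p_rf),
                   p_vs_tl = wilcoxon_vs_base(oof, p, oof$p_tl))
      })
      do.call(rbind, ens_rows)
    }, error = function(e) {
      log_stage("ensemble", paste("FAILED:", conditionMessage(e)))
      failed <<- c(failed, "ensemble")
      NULL
    })
    if (!is.null(ens)) {
      utils::write.csv(ens, file.path(out_dir, "ensembles.csv"), row.names = FALSE)
      results$ensembles <- ens
      log_stage("ensemble", "done")
    }
  }

  # ---- compute cost ----
  cost <- tryCatch({
    entries <- list(tcn_aware = tcn_spec(48L), tcn_naive = tcn_spec(30L))
    fm <- pooled_standard_scale(assemble_matrix(cohort, cfg$modes[1]))
    for (trees in c(200L, 50L)) {
      if (any(grepl(sprintf("^rf%d_", trees), names(runs)))) {
        f <- fit_random_forest(fm, n_trees = trees, seed = cfg$seed)
        entries[[sprintf("rf%d", trees)]] <- f
      }
    }
    do.call(cost_report, entries)
  }, error = function(e) {
    failed <<- c(failed, "cost"); NULL
  })
  if (!is.null(cost)) {
    utils::write.csv(cost, file.path(out_dir, "cost_report.csv"), row.names = FALSE)
    results$cost <- cost
    log_stage("cost", "done")
  }

  # ---- manifest ----
  manifest <- list(
    package = "nocibench",
    version = as.character(utils::packageVersion("nocibench")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "output_dir")],
    failed_stages = failed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$failed_stages <- failed
  results$output_dir <- out_dir
  invisible(results)
}

# Leave-one-surgery-out ensemble evaluation on the out-of-fold table: each
# surgery's rows are predicted by a combiner trained on all other
# surgeries' rows.
ensemble_oof_predictions <- function(oof, strategy, seed = 1L) {
  p <- numeric(length(oof$labels))
  for (s in unique(oof$surgery_of_row)) {
    te <- oof$surgery_of_row == s
    tr <- !te
    p[te] <- switch(strategy,
      linear_fixed = blend_linear(oof$p_rf[te], oof$p_tl[te], w = 0.5),
      linear_regressed = {
        fit <- stats::lm(oof$labels[tr] ~ oof$p_rf[tr] + oof$p_tl[tr])
        co <- stats::coef(fit); co[is.na(co)] <- 0
        pmin(1, pmax(0, co[1] + co[2] * oof$p_rf[te] + co[3] * oof$p_tl[te]))
      },
      meta_logistic = ,
      meta_mlp = {
        m <- fit_meta(strategy, oof$p_rf[tr], oof$p_tl[tr], oof$labels[tr],
                      seed = seed)
        predict(m, oof$p_rf[te], oof$p_tl[te])
      },
      gatenet = {
        sc <- fit_scaler(oof$features[tr, , drop = FALSE])
        g <- fit_gatenet(scale_with(oof$features[tr, , drop = FALSE], sc),
                         oof$p_rf[tr], oof$p_tl[tr], oof$labels[tr], seed = seed)
        as.numeric(predict(g, scale_with(oof$features[te, , drop = FALSE], sc),
                           oof$p_rf[te], oof$p_tl[te]))
      },
      stop("unknown ensemble strategy: ", strategy, call. = FALSE))
  }
  p
}

# Paired Wilcoxon on per-surgery AUROCs, ensemble vs a base model.
wilcoxon_vs_base <- function(oof, p_ens, p_base) {
  ids <- unique(oof$surgery_of_row)
  a <- vapply(ids, function(s) auroc(oof$labels[oof$surgery_of_row == s],
                                     p_ens[oof$surgery_of_row == s]), numeric(1))
  b <- vapply(ids, function(s) auroc(oof$labels[oof$surgery_of_row == s],
                                     p_base[oof$surgery_of_row == s]), numeric(1))
  if (sum(!is.na(a) & !is.na(b) & a != b) == 0) return(1)
  wilcoxon_paired(a, b)
}
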