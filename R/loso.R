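#' Model recipes for the LOSO harness
#'
#' A recipe bundles a model family with its configuration so that
#' [run_loso()] can fit it inside each fold. `recipe_rf` and `recipe_lasso`
#' are the classical baselines; `recipe_tcn` is the transfer-learning model
#' and is the only personalizable recipe.
#'
#' @param mode `"aware"` (48-column design) or `"naive"` (30-column).
#' @param n_trees,max_depth,bootstrap_fraction,replace forest configuration
#'   (see [fit_random_forest()]).
#' @param spec optional [tcn_spec()]; defaults to the benchmark architecture
#'   for the chosen mode.
#' @param train a [train_config()] for base training.
#' @param finetune a [finetune_config()] template for personalization (its
#'   `K_minutes` is overridden by the harness).
#' @return an object of class `noci_recipe`.
#' @name recipes
NULL

#' @rdname recipes
#' @export
recipe_rf <- function(mode = c("aware", "naive"), n_trees = 200L,
                      max_depth = 50L, bootstrap_fraction = 0.9,
                      replace = TRUE) {
  mode <- match.arg(mode)
  structure(list(
    name = sprintf("rf%d_%s", n_trees, mode),
    mode = mode,
    personalizable = FALSE,
    fit = function(records, scaler, seed) {
      fm <- assemble_matrix(records, mode)
      if (is.null(scaler)) {
        fm <- pooled_standard_scale(fm)
        scaler <- fm$scaler
      } else fm <- apply_scaler(fm, scaler)
      model <- fit_random_forest(fm, n_trees = n_trees, max_depth = max_depth,
                                 bootstrap_fraction = bootstrap_fraction,
                                 replace = replace, seed = seed)
      list(model = model, scaler = scaler)
    },
    predict = function(fit, record) {
      X <- scale_with(record_feature_rows(record, mode), fit$scaler)
      predict_proba(fit$model, X)
    }
  ), class = "noci_recipe")
}

#' @rdname recipes
#' @export
recipe_lasso <- function(mode = c("aware", "naive")) {
  mode <- match.arg(mode)
  structure(list(
    name = sprintf("lr_%s", mode),
    mode = mode,
    personalizable = FALSE,
    fit = function(records, scaler, seed) {
      fm <- assemble_matrix(records, mode)
      if (is.null(scaler)) {
        fm <- pooled_standard_scale(fm)
        scaler <- fm$scaler
      } else fm <- apply_scaler(fm, scaler)
      list(model = fit_lasso_aic(fm), scaler = scaler)
    },
    predict = function(fit, record) {
      X <- scale_with(record_feature_rows(record, mode), fit$scaler)
      predict_proba(fit$model, X)
    }
  ), class = "noci_recipe")
}

#' @rdname recipes
#' @export
recipe_tcn <- function(mode = c("aware", "naive"), spec = NULL,
                       train = train_config(), finetune = finetune_config()) {
  mode <- match.arg(mode)
  if (is.null(spec)) spec <- tcn_spec(if (mode == "aware") 48L else 30L)
  structure(list(
    name = sprintf("tcn_%s", mode),
    mode = mode,
    personalizable = TRUE,
    spec = spec,
    fit = function(records, scaler, seed) {
      cfg <- train
      cfg$seed <- seed
      train_base(spec, records, cfg, scaler = scaler)
    },
    predict = function(fit, record) predict_windows(fit, record),
    personalize = function(fit, adaptation, K_minutes) {
      cfg <- finetune
      cfg$K_minutes <- K_minutes
      personalize(fit, adaptation, cfg)
    }
  ), class = "noci_recipe")
}

#' @export
print.noci_recipe <- function(x, ...) {
  cat(sprintf("Recipe %s (%s%s)\n", x$name, x$mode,
              if (x$personalizable) ", personalizable" else ""))
  invisible(x)
}

#' Leave-one-surgery-out evaluation
#'
#' Holds out each surgery in turn, fits the recipe on the remaining
#' surgeries, and scores the held-out surgery. With `K_minutes > 0` the
#' held-out surgery is split into an adaptation segment (first `12 * K`
#' windows) and an evaluation remainder; personalizable recipes fine-tune on
#' the adaptation segment, and every recipe is evaluated on the remainder
#' only (so personalized and static models are scored on identical
#' windows). Folds whose evaluation segment is single-class carry `NA`
#' metrics (counted, not dropped); a recipe failure marks the fold failed
#' with its reason and the run continues.
#'
#' For every personalized fold the harness re-checks the freeze contract:
#' convolution and batch-normalization tensors (including running
#' statistics) must be bit-identical between the base and personalized
#' models.
#'
#' @param cohort a `noci_cohort` or list of at least 2 `surgery_record`s.
#' @param recipe a `noci_recipe`.
#' @param K_minutes adaptation window in minutes; 0 = no adaptation split.
#' @param scale `"fold"` fits the standard scaler on each fold's training
#'   surgeries only (no leakage; the default); `"pooled"` fits it once on
#'   the entire cohort.
#' @param seed integer; fold `i` uses child seed `seed + i`.
#' @return a `loso_result`: list of per-fold results with fields
#'   `surgery_id`, `model_name`, `K_minutes`, `y_true`, `y_score`,
#'   `window_index`, `auroc`, `auprc`, `train_surgeries`, `failed`, and for
#'   personalized folds `adapt` (adaptation labels/scores) and `freeze_ok`.
#' @export
run_loso <- function(cohort, recipe, K_minutes = 0L,
                     scale = c("fold", "pooled"), seed = 1L) {
  stopifnot(inherits(recipe, "noci_recipe"))
  records <- if (inherits(cohort, "noci_cohort")) unclass(cohort) else cohort
  if (length(records) < 2L)
    stop("LOSO requires at least 2 surgeries", call. = FALSE)
  scale <- match.arg(scale)
  pooled_scaler <- NULL
  if (scale == "pooled") {
    pooled <- do.call(rbind, lapply(records, record_feature_rows, mode = recipe$mode))
    pooled_scaler <- fit_scaler(pooled)
  }
  ids <- vapply(records, `[[`, character(1), "surgery_id")
  folds <- vector("list", length(records))
  for (i in seq_along(records)) {
    held <- records[[i]]
    train_recs <- records[-i]
    fold <- list(surgery_id = held$surgery_id, model_name = recipe$name,
                 K_minutes = as.integer(K_minutes),
                 train_surgeries = ids[-i], failed = FALSE, reason = NULL)
    res <- tryCatch({
      fit <- recipe$fit(train_recs, pooled_scaler, seed + i)
      if (K_minutes > 0) {
        sp <- split_adaptation_evaluation(held, K_minutes)
        eval_rec <- sp$evaluation
        model_used <- fit
        if (recipe$personalizable) {
          model_used <- recipe$personalize(fit, sp$adaptation, K_minutes)
          fold$freeze_ok <- frozen_trunk_identical(fit, model_used)
        }
        fold$adapt <- list(
          y_true = sp$adaptation$label,
          y_score = recipe$predict(model_used, sp$adaptation),
          window_index = sp$adaptation$window_index)
        fold$y_score <- recipe$predict(model_used, eval_rec)
        fold$y_true <- eval_rec$label
        fold$window_index <- eval_rec$window_index
      } else {
        fold$y_score <- recipe$predict(fit, held)
        fold$y_true <- held$label
        fold$window_index <- held$window_index
      }
      fold$auroc <- auroc(fold$y_true, fold$y_score)
      fold$auprc <- auprc(fold$y_true, fold$y_score)
      fold
    }, error = function(e) {
      fold$failed <- TRUE
      fold$reason <- conditionMessage(e)
      fold
    })
    folds[[i]] <- res
  }
  structure(folds, class = "loso_result",
            recipe = recipe$name, K_minutes = K_minutes, scale = scale)
}

# Bit-identity check of the frozen trunk (conv + BN weights and running
# statistics) between base and personalized models.
frozen_trunk_identical <- function(base, personalized) {
  identical(base$params$Wc, personalized$params$Wc) &&
    identical(base$params$bc, personalized$params$bc) &&
    identical(base$params$gamma, personalized$params$gamma) &&
    identical(base$params$beta, personalized$params$beta) &&
    identical(base$run_mean, personalized$run_mean) &&
    identical(base$run_var, personalized$run_var)
}

#' @export
print.loso_result <- function(x, ...) {
  ff <- unclass(x)
  failed <- vapply(ff, function(f) isTRUE(f$failed), logical(1))
  aurocs <- vapply(ff[!failed], function(f) f$auroc %||% NA_real_, numeric(1))
  cat(sprintf("LOSO result: %s, K = %d min, %d folds (%d failed, %d undefined)\n",
              attr(x, "recipe"), attr(x, "K_minutes"), length(ff),
              sum(failed), sum(is.na(aurocs))))
  if (any(!is.na(aurocs)))
    cat(sprintf("  median AUROC %.3f\n", stats::median(aurocs, na.rm = TRUE)))
  invisible(x)
}

#' Tidy per-fold metric table
#'
#' @param x a `loso_result`.
#' @param ... unused.
#' @return data frame: surgery_id, model_name, K_minutes, auroc, auprc,
#'   n_eval_windows, failed.
#' @export
as.data.frame.loso_result <- function(x, ...) {
  ff <- unclass(x)
  data.frame(
    surgery_id = vapply(ff, `[[`, character(1), "surgery_id"),
    model_name = vapply(ff, `[[`, character(1), "model_name"),
    K_minutes = vapply(ff, `[[`, integer(1), "K_minutes"),
    auroc = vapply(ff, function(f) f$auroc %||% NA_real_, numeric(1)),
    auprc = vapply(ff, function(f) f$auprc %||% NA_real_, numeric(1)),
    n_eval_windows = vapply(ff, function(f) length(f$y_true %||% integer(0)), integer(1)),
    failed = vapply(ff, function(f) isTRUE(f$failed), logical(1))
  )
}
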