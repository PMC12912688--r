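#' Temporal convolutional network architecture specification
#'
#' The network is a single 1-D convolution (valid padding) across the
#' feature channels over a trailing temporal context, followed by batch
#' normalization, ReLU, global max-pooling over the remaining temporal
#' positions, and a two-layer dense head ending in a sigmoid unit.
#'
#' With the default `context_windows = 6` (30 s of trailing context) and
#' kernel size 6, the valid convolution has exactly one output position, so
#' the global max-pool is the identity.
#'
#' @param in_channels number of input feature channels: 48 drug-aware, 30
#'   drug-naive.
#' @param conv_filters number of convolution filters.
#' @param kernel_size convolution kernel length, in windows.
#' @param hidden_units width of the first dense layer.
#' @param context_windows temporal length of one input sample, in 5-s
#'   windows; must be at least `kernel_size`.
#' @return an object of class `tcn_spec`.
#' @export
tcn_spec <- function(in_channels, conv_filters = 64L, kernel_size = 6L,
                     hidden_units = 32L, context_windows = 6L) {
  if (context_windows < kernel_size)
    stop("shape error: context_windows must be >= kernel_size", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 hidden_units = as.integer(hidden_units),
                 context_windows = as.integer(context_windows)),
            class = "tcn_spec")
}

#' @export
print.tcn_spec <- function(x, ...) {
  cat(sprintf("TCN spec: conv1d(%d ch, %d filters, kernel %d) + BN + ReLU + max-pool + dense %d->%d->1\n",
              x$in_channels, x$conv_filters, x$kernel_size,
              x$conv_filters, x$hidden_units))
  cat(sprintf("  context %d windows, %d trainable parameters\n",
              x$context_windows, count_parameters(x)))
  invisible(x)
}

#' Closed-form trainable-parameter count
#'
#' Convolution weights and bias, batch-norm scale and shift, and the two
#' dense layers with biases:
#' `in_channels*kernel*filters + filters + 2*filters + filters*hidden +
#' hidden + hidden + 1`. The drug-aware benchmark architecture
#' (48, 64, 6, 32) has 20,737 trainable parameters; the drug-naive one
#' (30, 64, 6, 32) has 13,825.
#'
#' @param spec a [tcn_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "tcn_spec"))
  spec$in_channels * spec$kernel_size * spec$conv_filters + spec$conv_filters +  # conv W + b
    2L * spec$conv_filters +                                       # BN gamma + beta
    spec$conv_filters * spec$hidden_units + spec$hidden_units +    # dense-1
    spec$hidden_units + 1L                                         # dense-2
}

# Actual parameter total of a built network, counted from its tensors.
tcn_num_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Base-training configuration
#'
#' @param max_epochs epoch cap (benchmark: 12).
#' @param learning_rate Adam step size (benchmark: 1e-3).
#' @param batch_size minibatch size (benchmark: 128).
#' @param patience early-stopping patience, in epochs (benchmark: 3); must
#'   be less than `max_epochs`.
#' @param validation_fraction fraction of each training surgery's samples
#'   held out (surgery-stratified) to monitor validation loss.
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 12L, learning_rate = 1e-3,
                         batch_size = 128L, patience = 3L,
                         validation_fraction = 0.1, seed = 1L) {
  stopifnot(patience < max_epochs, learning_rate > 0, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Fine-tuning (personalization) configuration
#'
#' @param epochs fixed number of fine-tuning epochs (benchmark: 3; no early
#'   stopping).
#' @param learning_rate Adam step size (benchmark: 1e-4).
#' @param batch_size minibatch size (benchmark: 128).
#' @param K_minutes adaptation-window length in minutes (1, 2, 5 or 10).
#' @return an object of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 3L, learning_rate = 1e-4,
                            batch_size = 128L, K_minutes = 10L) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 K_minutes = as.integer(K_minutes)),
            class = "finetune_config")
}

#' Instantiate an untrained network
#'
#' @param spec a [tcn_spec()].
#' @param seed initialization seed.
#' @return an object of class `tcn` holding the parameter tensors, batch
#'   normalization running statistics, and the spec.
#' @export
build_tcn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tcn_spec"))
  structure(list(
    spec = spec,
    params = tcn_init_params(spec, seed),
    run_mean = rep(0, spec$conv_filters),
    run_var = rep(1, spec$conv_filters),
    scaler = NULL,
    mode = if (spec$in_channels == 48L) "aware" else "naive",
    pos_weight = 1,
    trained = FALSE
  ), class = "tcn")
}

#' @export
print.tcn <- function(x, ...) {
  cat(sprintf("TCN (%s): %d parameters, %s\n",
              x$mode, tcn_num_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Build the sample index structure for a list of records: pooled (scaled)
# row matrix, per-sample end index into it, label, and surgery id. Samples
# exist for every window t >= context (1-based).
tcn_samples <- function(records, mode, context, scaler) {
  rows <- lapply(records, record_feature_rows, mode = mode)
  n_each <- vapply(rows, nrow, integer(1))
  offsets <- cumsum(c(0L, n_each[-length(n_each)]))
  R <- scale_with(do.call(rbind, rows), scaler)
  tvec <- integer(0); y <- integer(0); sid <- character(0)
  for (i in seq_along(records)) {
    n <- n_each[i]
    if (n < context) next
    tt <- context:n
    tvec <- c(tvec, offsets[i] + tt)
    y <- c(y, records[[i]]$label[tt])
    sid <- c(sid, rep(records[[i]]$surgery_id, length(tt)))
  }
  list(R = R, tvec = tvec, y = y, surgery = sid)
}

#' Train the base (population) network
#'
#' Pools all windows from the training surgeries, standard-scales the design
#' (population mean/SD fitted on these surgeries), and trains with Adam on
#' binary cross-entropy weighted for the event prevalence (positive-class
#' weight `(1 - pi) / pi` for training prevalence `pi`). A
#' surgery-stratified validation split monitors loss for early stopping
#' (patience epochs without improvement); the best-epoch weights are
#' restored.
#'
#' @param spec a [tcn_spec()]; its `in_channels` selects the drug-aware (48)
#'   or drug-naive (30) design.
#' @param train_surgeries list of `surgery_record`s (the 100-of-101 pool in
#'   a LOSO fold).
#' @param config a [train_config()].
#' @param scaler optional pre-fitted scaler (e.g. cohort-wide); default fits
#'   on the training surgeries.
#' @return a fitted `tcn`.
#' @export
train_base <- function(spec, train_surgeries, config = train_config(),
                       scaler = NULL) {
  stopifnot(inherits(spec, "tcn_spec"), inherits(config, "train_config"))
  mode <- if (spec$in_channels == 48L) "aware" else "naive"
  if (is.null(scaler)) {
    pooled <- do.call(rbind, lapply(train_surgeries, record_feature_rows, mode = mode))
    scaler <- fit_scaler(pooled)
  }
  smp <- tcn_samples(train_surgeries, mode, spec$context_windows, scaler)
  if (length(unique(smp$y)) < 2L)
    stop("degenerate-labels error: pooled training labels contain a single class",
         call. = FALSE)
  set.seed(config$seed)
  model <- build_tcn(spec, seed = config$seed)
  model$scaler <- scaler

  # surgery-stratified validation split
  N <- length(smp$y)
  val <- logical(N)
  for (s in unique(smp$surgery)) {
    idx <- which(smp$surgery == s)
    n_val <- floor(config$validation_fraction * length(idx))
    if (n_val >= 1) val[sample(idx, n_val)] <- TRUE
  }
  if (length(unique(smp$y[!val])) < 2L) val[] <- FALSE  # degenerate split: train on all
  tr_idx <- which(!val); va_idx <- which(val)

  pi_hat <- mean(smp$y[tr_idx])
  pos_weight <- (1 - pi_hat) / pi_hat
  model$pos_weight <- pos_weight

  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params,
               run_mean = model$run_mean, run_var = model$run_var, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      fwd <- tcn_forward(model, smp$R, smp$tvec[bi], training = TRUE)
      # update running statistics
      model$run_mean <- (1 - BN_MOMENTUM) * model$run_mean + BN_MOMENTUM * fwd$cache$mu
      model$run_var <- (1 - BN_MOMENTUM) * model$run_var + BN_MOMENTUM * fwd$cache$v
      lb <- bce_weighted(fwd$prob, smp$y[bi], pos_weight)
      grads <- tcn_backward(model, fwd$cache, lb$dlogit)
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    monitor_idx <- if (length(va_idx)) va_idx else tr_idx
    mon <- tcn_forward(model, smp$R, smp$tvec[monitor_idx], training = FALSE)
    mloss <- bce_weighted(mon$prob, smp$y[monitor_idx], pos_weight)$loss
    if (mloss < best$loss - 1e-9) {
      best <- list(loss = mloss, params = model$params,
                   run_mean = model$run_mean, run_var = model$run_var,
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  model$run_mean <- best$run_mean
  model$run_var <- best$run_var
  model$epochs_run <- epoch
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' Personalize a base network on a patient's adaptation segment
#'
#' Freezes the convolutional and batch-normalization layers (weights and
#' running statistics are bit-identical before and after) and fine-tunes
#' only the two dense-head layers for a fixed number of epochs with no early
#' stopping. Batch normalization runs in inference mode (frozen running
#' statistics) throughout. The base model's prevalence weighting is reused.
#'
#' @param base a trained `tcn`.
#' @param adaptation a `surgery_record`, the first K minutes of the held-out
#'   surgery (see [split_adaptation_evaluation()]).
#' @param config a [finetune_config()].
#' @return the personalized `tcn`.
#' @export
personalize <- function(base, adaptation, config = finetune_config()) {
  stopifnot(inherits(base, "tcn"), inherits(adaptation, "surgery_record"),
            inherits(config, "finetune_config"))
  spec <- base$spec
  if (n_windows(adaptation) < spec$context_windows)
    stop(insufficient_data_error(sprintf(
      "adaptation segment has %d windows; context needs %d",
      n_windows(adaptation), spec$context_windows)))
  smp <- tcn_samples(list(adaptation), base$mode, spec$context_windows, base$scaler)
  # frozen trunk: pooled features computed once in inference mode
  trunk <- tcn_forward(base, smp$R, smp$tvec, training = FALSE)
  pool <- trunk$pool

  model <- base
  head <- model$params[c("W1", "b1", "W2", "b2")]
  state <- adam_init(head)
  set.seed(spec$in_channels + length(smp$y))  # deterministic shuffling
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(smp$y))
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      fwd <- head_forward(head, pool[bi, , drop = FALSE])
      lb <- bce_weighted(fwd$prob, smp$y[bi], model$pos_weight)
      grads <- head_backward(head, pool[bi, , drop = FALSE], fwd, lb$dlogit)
      upd <- adam_step(head, grads, state, config$learning_rate)
      head <- upd$params
      state <- upd$state
    }
  }
  model$params[c("W1", "b1", "W2", "b2")] <- head
  model$personalized <- TRUE
  model
}

#' Score every window of a surgery
#'
#' For each window `t >= context_windows - 1` (0-based) the model scores the
#' trailing context of `context_windows` windows; earlier windows receive
#' the first computable score (left-edge padding by repetition), so the
#' output length equals the record's window count.
#'
#' @param model a trained `tcn`.
#' @param record a `surgery_record` with at least `context_windows` windows.
#' @return numeric probability vector aligned to the record's windows.
#' @export
predict_windows <- function(model, record) {
  stopifnot(inherits(model, "tcn"), inherits(record, "surgery_record"))
  spec <- model$spec
  n <- n_windows(record)
  if (n < spec$context_windows)
    stop(insufficient_data_error(sprintf(
      "record has %d windows; context needs %d", n, spec$context_windows)))
  R <- scale_with(record_feature_rows(record, model$mode), model$scaler)
  tvec <- spec$context_windows:n
  probs <- numeric(length(tvec))
  chunk <- 4096L
  for (start in seq(1L, length(tvec), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(tvec))
    probs[idx] <- tcn_forward(model, R, tvec[idx], training = FALSE)$prob
  }
  c(rep(probs[1], spec$context_windows - 1L), probs)
}

#' @export
predict.tcn <- function(object, newdata, ...) predict_windows(object, newdata)
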