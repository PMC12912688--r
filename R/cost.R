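#' Analytic multiply-accumulate count for the TCN
#'
#' Per forward pass: the convolution contributes
#' `in_channels * kernel_size * conv_filters` MACs per output position
#' (one position at the default context), and the dense head contributes
#' `conv_filters * hidden_units + hidden_units * 1`. Bias additions and
#' activation functions are excluded. The benchmark drug-aware
#' architecture yields 18,432 conv + 2,080 dense = 20,512 MACs.
#'
#' @param spec a [tcn_spec()].
#' @return list with `conv_macs`, `dense_macs`, `total_macs`.
#' @export
tcn_macs <- function(spec) {
  stopifnot(inherits(spec, "tcn_spec"))
  positions <- spec$context_windows - spec$kernel_size + 1L
  conv <- spec$in_channels * spec$kernel_size * spec$conv_filters * positions
  dense <- spec$conv_filters * spec$hidden_units + spec$hidden_units * 1L
  list(conv_macs = conv, dense_macs = dense, total_macs = conv + dense)
}

#' Parameter memory footprint of the TCN
#'
#' FP32 precision: 4 bytes per trainable parameter; kilobytes use the
#' 1024-byte convention. The drug-aware architecture's 20,737 parameters
#' occupy 82,948 bytes = 81 KB; the drug-naive one 54 KB.
#'
#' @param spec a [tcn_spec()].
#' @return list with `parameters`, `bytes`, `kilobytes` (rounded to the
#'   nearest integer).
#' @export
tcn_parameter_memory <- function(spec) {
  params <- count_parameters(spec)
  bytes <- 4L * params
  list(parameters = params, bytes = bytes,
       kilobytes = as.integer(round(bytes / 1024)))
}

#' Forest inference cost and memory
#'
#' Node memory uses a 24-byte node record (feature index 4 B, threshold
#' 8 B, two child references 4 B each, leaf value 4 B); megabytes use the
#' decimal (10^6-byte) convention. Comparisons per sample =
#' `n_trees * depth` (one threshold comparison per level traversed).
#' Pass either a fitted [fit_random_forest()] model (node count and mean
#' attained tree depth, rounded, are extracted) or analytic values.
#'
#' @param forest optional `noci_forest`.
#' @param n_trees,nodes,depth analytic values (ignored when `forest`
#'   given, except `depth` which overrides if supplied).
#' @return list with `tree_nodes`, `node_memory_bytes`, `node_memory_mb`,
#'   `comparisons_per_sample`, `n_trees`, `depth`.
#' @export
forest_cost <- function(forest = NULL, n_trees = NULL, nodes = NULL,
                        depth = NULL) {
  if (!is.null(forest)) {
    stopifnot(inherits(forest, "noci_forest"))
    n_trees <- forest$n_trees
    nodes <- forest$node_count
    if (is.null(depth)) depth <- round(mean(forest_tree_depths(forest)))
  }
  if (any(c(n_trees, nodes, depth) < 0))
    stop("negative inputs to forest_cost", call. = FALSE)
  bytes <- 24 * nodes
  list(tree_nodes = nodes,
       node_memory_bytes = bytes,
       node_memory_mb = bytes / 1e6,
       comparisons_per_sample = n_trees * depth,
       n_trees = n_trees, depth = depth)
}

#' Tabulated compute-cost report
#'
#' One row per model. TCN entries ([tcn_spec()]) report parameters, FP32
#' memory and MACs; forest entries (`noci_forest` or the analytic list from
#' [forest_cost()]) report node counts, node memory and comparison counts.
#' The `ops_per_sample` column (MACs for networks, threshold comparisons
#' for forests) makes the instruction-count contrast directly readable
#' (units differ: floating-point MACs vs logical comparisons).
#' Conventions: KB = 1024 bytes (parameter memory), MB = 10^6 bytes (forest
#' node memory).
#'
#' @param ... named models: `tcn_spec`, `noci_forest`, or `forest_cost`
#'   output lists.
#' @return data frame of class `cost_report`.
#' @export
cost_report <- function(...) {
  models <- list(...)
  if (!length(models)) stop("cost_report needs at least one model", call. = FALSE)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model_", seq_along(models))
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (inherits(m, "tcn_spec")) {
      mem <- tcn_parameter_memory(m)
      macs <- tcn_macs(m)
      data.frame(model = nm, kind = "tcn",
                 trainable_parameters = mem$parameters,
                 parameter_memory_bytes = mem$bytes,
                 memory_kb = mem$kilobytes,
                 conv_macs = macs$conv_macs, dense_macs = macs$dense_macs,
                 total_macs = macs$total_macs,
                 tree_nodes = NA_integer_, node_memory_bytes = NA_real_,
                 comparisons_per_sample = NA_real_,
                 ops_per_sample = macs$total_macs)
    } else {
      fc <- if (inherits(m, "noci_forest")) forest_cost(m) else m
      data.frame(model = nm, kind = "forest",
                 trainable_parameters = NA_integer_,
                 parameter_memory_bytes = NA_real_, memory_kb = NA_integer_,
                 conv_macs = NA_real_, dense_macs = NA_real_,
                 total_macs = NA_real_,
                 tree_nodes = fc$tree_nodes,
                 node_memory_bytes = fc$node_memory_bytes,
                 comparisons_per_sample = fc$comparisons_per_sample,
                 ops_per_sample = fc$comparisons_per_sample)
    }
  })
  structure(do.call(rbind, rows), class = c("cost_report", "data.frame"))
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Compute-cost report (KB = 1024 bytes for parameters; MB = 10^6 bytes for nodes)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
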