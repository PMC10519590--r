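#' Default run configuration
#'
#' The fully resolved default configuration for [run_benchmark()]: model
#' hyperparameters at their published defaults (two 200-neuron GCN layers,
#' 500 epochs, Adam lr 0.01, L2 1e-4 on the first layer, dropout 0.7,
#' patience 10), 3-fold edge CV repeated 10 times, prior-graph threshold 0,
#' and a simulation block describing the LI archetype at 2000 cells.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    paths = list(expression = NULL, network = NULL, tf_list = NULL,
                 output_dir = NULL),
    preprocess = list(min_gene_cell_fraction = 0.1, min_cell_detected_genes = 1L,
                      scheme = "cpm", n_top_hvg = 500L, alpha = 0.01),
    prior = list(threshold = 0),
    model = list(hidden_dims = c(200L, 200L), epochs = 500L,
                 learning_rate = 0.01, l2_first_layer = 1e-4,
                 dropout_rate = 0.7, patience = 10L, dropout_input = TRUE,
                 decoder = "full", val_fraction = 0.1,
                 lambda_recon = 1, kappa = 3, neg_replicates = 8L,
                 min_epochs = 20L, feature_norm = "center_unit",
                 final_activation = "linear"),
    evaluation = list(k_folds = 3L, n_runs = 10L, universe = "all",
                      weight_cutoff = 0),
    simulation = list(network_kind = "LI", n_genes = NULL, n_cells = 2000L,
                      dropout_q = 0L, noise_sd = 0.3, hill_coefficient = 2),
    seed = 1L,
    log_level = "info"
  ), class = "run_config")
}

merge_config <- function(defaults, overrides, path = character()) {
  for (key in names(overrides)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key: %s", here))
    }
    value <- overrides[[key]]
    if (is.list(defaults[[key]]) && is.null(value)) next  # empty section: keep defaults
    if (is.list(defaults[[key]]) && !is.null(value)) {
      if (!is.list(value)) abort(sprintf("key %s must be a section.", here))
      defaults[[key]] <- merge_config(defaults[[key]], value, c(path, key))
    } else {
      defaults[key] <- list(value)  # keeps explicit NULLs instead of deleting
    }
  }
  defaults
}

#' Parse a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every missing key from
#' [default_run_config()], then applies flag-style overrides (a named list,
#' names using `section.key` dotted paths). Unknown keys are rejected with
#' their full path.
#'
#' @param path Optional YAML/JSON configuration file.
#' @param overrides Named list of dotted-path overrides, e.g.
#'   `list("model.epochs" = 100, "seed" = 7)`.
#' @return A fully resolved `run_config`.
#' @export
parse_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.null(raw)) config <- merge_config(config, raw)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    nested <- overrides[[key]]
    for (p in rev(parts)) nested <- stats::setNames(list(nested), p)
    config <- merge_config(config, nested)
  }
  structure(config, class = "run_config")
}

#' Write a resolved configuration
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' End-to-end benchmark driver
#'
#' Ties every stage together: loads the expression matrix, ground-truth
#' network and optional TF list from `config$paths` (or simulates a dataset
#' from `config$simulation` when no expression path is given), preprocesses,
#' builds the prior graph, trains and evaluates the graph autoencoder with
#' k-fold edge cross-validation repeated over seeded runs alongside the
#' absolute-Spearman baseline, and (when an output directory is configured)
#' writes the metric tables and the resolved configuration.
#'
#' @param config A `run_config` from [parse_run_config()].
#' @return The `grn_metrics` object (invisibly carries per-fold detail).
#' @export
run_benchmark <- function(config = default_run_config()) {
  seed <- as.integer(config$seed)
  if (is.null(config$paths$expression)) {
    sim <- simulate_dataset(sim_config(
      network_kind = config$simulation$network_kind,
      n_genes = config$simulation$n_genes,
      n_cells = config$simulation$n_cells,
      dropout_q = config$simulation$dropout_q,
      noise_sd = config$simulation$noise_sd,
      hill_coefficient = config$simulation$hill_coefficient,
      seed = seed))
    expr <- log_transform(sim$expr)
    truth <- sim$network
    tf_names <- NULL
  } else {
    expr <- read_expression(config$paths$expression)
    expr <- filter_genes_cells(expr,
                               config$preprocess$min_gene_cell_fraction,
                               config$preprocess$min_cell_detected_genes)
    expr <- normalize_log(expr, scheme = config$preprocess$scheme)
    tf_names <- if (!is.null(config$paths$tf_list)) {
      read_tf_list(config$paths$tf_list)
    }
    if (!is.null(tf_names)) {
      sel <- select_variable_genes(expr, tf_names,
                                   n_top = config$preprocess$n_top_hvg,
                                   alpha = config$preprocess$alpha)
      expr <- expression_matrix(
        unclass(expr)[sel$selected, , drop = FALSE],
        transform = transform_state(expr))
    }
    truth <- read_network(config$paths$network,
                          gene_universe = rownames(expr))
  }
  params <- gae_params(hidden_dims = config$model$hidden_dims,
                       epochs = config$model$epochs,
                       learning_rate = config$model$learning_rate,
                       l2_first_layer = config$model$l2_first_layer,
                       dropout_rate = config$model$dropout_rate,
                       patience = config$model$patience,
                       dropout_input = config$model$dropout_input,
                       decoder = config$model$decoder,
                       val_fraction = config$model$val_fraction,
                       lambda_recon = config$model$lambda_recon,
                       kappa = config$model$kappa,
                       neg_replicates = config$model$neg_replicates,
                       min_epochs = config$model$min_epochs,
                       feature_norm = config$model$feature_norm,
                       final_activation = config$model$final_activation,
                       seed = seed)
  metrics <- run_grn_cv(expr, truth, params = params,
                        k = config$evaluation$k_folds,
                        n_runs = config$evaluation$n_runs,
                        threshold = config$prior$threshold,
                        tf_names = if (identical(config$evaluation$universe, "tf"))
                          tf_names else NULL,
                        seed = seed)
  if (!is.null(config$paths$output_dir)) {
    write_metrics_report(metrics, config$paths$output_dir)
    write_run_config(config, file.path(config$paths$output_dir,
                                       "resolved-config.yaml"))
  }
  metrics
}
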