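# End-to-end experiment orchestration: configuration, the full
# methods x configurations x tasks sweep, tidy result export and
# averaged weight profiles.

#' Define an experiment configuration
#'
#' @param spec a [synth_spec()] describing the synthetic cohort, or `NULL`
#'   when `dataset_path` points at a dataset written by [write_dataset()].
#' @param dataset_path optional path to an on-disk dataset.
#' @param methods subset of `c("baseline", "mkl", "hgmfs", "smml")`.
#' @param configs modality configuration names (see [modality_configs()]).
#' @param tasks task kinds (see [task_spec()]).
#' @param grid_profile `"quick"` or `"full"` (see [default_grid()]).
#' @param seed master seed driving data generation and fold partitions.
#' @param snp_screen_k SNP features kept by the per-fold screen.
#' @param n_folds folds per cross-validation.
#' @param output_dir where [run_experiment()] writes its files.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(spec = synth_spec(),
                              dataset_path = NULL,
                              methods = c("baseline", "mkl", "hgmfs", "smml"),
                              configs = "MRI+PET+CSF+SNP",
                              tasks = c("AD_vs_MCI", "AD_vs_HC", "MCI_vs_HC", "multiclass"),
                              grid_profile = "quick",
                              seed = 1,
                              snp_screen_k = 189,
                              n_folds = 10,
                              output_dir = "mmfs_results") {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(configs %in% modality_configs()))
  tasks <- vapply(tasks, function(t) task_spec(t)$kind, character(1))
  structure(list(spec = spec, dataset_path = dataset_path, methods = methods,
                 configs = configs, tasks = unname(tasks),
                 grid_profile = grid_profile, seed = seed,
                 snp_screen_k = snp_screen_k, n_folds = n_folds,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' The full nine-configuration, four-method, four-task preset
#'
#' @param ... overrides passed to [experiment_config()].
#' @export
full_sweep_config <- function(...) {
  experiment_config(configs = modality_configs(), ...)
}

#' Read an experiment configuration from a JSON or YAML document
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @export
read_experiment_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$spec)) {
    obj$spec$n_per_class <- unlist(obj$spec$n_per_class)
    obj$spec$modality_dims <- unlist(obj$spec$modality_dims)
    obj$spec$informative_counts <- unlist(obj$spec$informative_counts)
    obj$spec$effect_sizes <- unlist(obj$spec$effect_sizes)
    obj$spec$snp_maf_range <- unlist(obj$spec$snp_maf_range)
    obj$spec <- do.call(synth_spec, obj$spec)
  }
  do.call(experiment_config, obj)
}

config_hash <- function(config) {
  # hash the scientific configuration only: the output path must not
  # change result provenance (reruns into different directories are
  # byte-identical)
  core <- unclass(config)
  core$output_dir <- NULL
  fnv1a(paste(utils::capture.output(utils::str(core)), collapse = "\n"))
}

#' Run the full experiment described by a configuration
#'
#' For every (method, modality configuration, task) combination, runs
#' [run_cv()] with the configured grid profile and seed, then writes to
#' `output_dir`:
#' \itemize{
#'   \item `results.csv` — tidy rows (method, config, task, fold, metric,
#'     value) with provenance columns (seed, chosen hyperparameters,
#'     config hash);
#'   \item `summary.csv` — one row per combination with
#'     `mean +/- sd` formatted metrics;
#'   \item `weights_<method>_<config>_<task>.csv` — per-feature averaged
#'     fold weights with modality annotations;
#'   \item `log.json` — machine-readable record of seeds and chosen
#'     hyperparameters.
#' }
#' Output is deterministic for a fixed configuration: rerunning produces
#' byte-identical files.
#'
#' @param config an `experiment_config`.
#' @param dataset optionally a pre-built `multimodal_dataset` (otherwise
#'   generated from `config$spec` or read from `config$dataset_path`).
#' @return Invisibly, a list with `results` (tidy data frame), `summary`,
#'   and the per-combination `cv_result` objects.
#' @export
run_experiment <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(dataset)) {
    dataset <- if (!is.null(config$dataset_path)) read_dataset(config$dataset_path)
               else generate_multimodal(config$spec)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  rows <- list(); summaries <- list(); cvs <- list(); log <- list()
  for (cf in config$configs) for (task in config$tasks) for (m in config$methods) {
    cv <- run_cv(dataset, cf, task, m,
                 grid = default_grid(m, config$grid_profile),
                 seed = config$seed, n_folds = config$n_folds,
                 snp_screen_k = config$snp_screen_k)
    key <- paste(m, cf, task, sep = "|")
    cvs[[key]] <- cv
    chosen_str <- paste(sprintf("%s=%g", names(cv$chosen), unlist(cv$chosen[1, ])),
                        collapse = ";")
    fm <- cv$folds_metrics
    long <- stats::reshape(fm, direction = "long",
                           varying = list(names(fm)[-1]),
                           v.names = "value", timevar = "metric",
                           times = names(fm)[-1], idvar = "fold")
    rows[[key]] <- data.frame(method = m, config = cf, task = task,
                              fold = long$fold, metric = long$metric,
                              value = long$value, seed = config$seed,
                              params = chosen_str, config_hash = hash,
                              row.names = NULL)
    summaries[[key]] <- data.frame(
      method = m, config = cf, task = task,
      accuracy = sprintf("%.1f +/- %.1f", cv$mean["accuracy"], cv$sd["accuracy"]),
      sensitivity = if (is.na(cv$mean["sensitivity"])) "" else
        sprintf("%.1f +/- %.1f", cv$mean["sensitivity"], cv$sd["sensitivity"]),
      specificity = if (is.na(cv$mean["specificity"])) "" else
        sprintf("%.1f +/- %.1f", cv$mean["specificity"], cv$sd["specificity"]),
      params = chosen_str, row.names = NULL)
    log[[key]] <- list(seed = config$seed, chosen = as.list(cv$chosen[1, ]),
                       config_hash = hash)
    export_weight_profiles(cv, config$output_dir)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL
  utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_df, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(log, file.path(config$output_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, summary = summary_df, cv_results = cvs))
}

#' Export the averaged per-feature weight profile of a CV run
#'
#' Writes `weights_<method>_<config>_<task>.csv` with the across-fold mean
#' weight of every feature in canonical modality order, annotated with its
#' modality (the format behind per-feature weight profile figures).
#'
#' @param cv a `cv_result`.
#' @param dir output directory.
#' @return The written file path, invisibly.
#' @export
export_weight_profiles <- function(cv, dir = ".") {
  stopifnot(inherits(cv, "cv_result"))
  modality <- rep(names(cv$block_dims), times = cv$block_dims)
  df <- data.frame(feature = cv$feature_names, modality = modality,
                   weight = cv$avg_weights, row.names = NULL)
  fn <- file.path(dir, sprintf("weights_%s_%s_%s.csv", cv$method,
                               gsub("\\+", "-", cv$config), cv$task))
  utils::write.csv(df, fn, row.names = FALSE)
  invisible(fn)
}
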