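# Classification protocol: modality configurations, task definitions,
# stratified 10-fold cross-validation with grid search, per-fold
# train-only preprocessing (SNP screening + normalization), selector
# fitting, element-wise feature weighting and linear SVM classification.

canonical_modalities <- function() c("MRI", "PET", "CSF", "SNP")

#' The nine canonical modality configurations
#'
#' Single modalities, each imaging/fluid modality plus SNP, the three
#' non-genetic modalities combined, and all four together.
#'
#' @return Character vector of configuration names.
#' @export
modality_configs <- function() {
  c("MRI", "PET", "CSF", "SNP", "MRI+SNP", "PET+SNP", "CSF+SNP",
    "MRI+PET+CSF", "MRI+PET+CSF+SNP")
}

#' Define a modality configuration
#'
#' @param members character vector of modalities (subset of MRI, PET, CSF,
#'   SNP) or a single `"A+B"` string; stored in canonical order
#'   MRI, PET, CSF, SNP.
#' @return Object of class `modality_config`.
#' @export
modality_config <- function(members) {
  if (length(members) == 1 && grepl("+", members, fixed = TRUE))
    members <- strsplit(members, "+", fixed = TRUE)[[1]]
  members <- unique(members)
  unknown <- setdiff(members, canonical_modalities())
  if (length(unknown)) stop("unknown modalities: ", paste(unknown, collapse = ", "))
  if (!length(members)) stop("configuration must contain at least one modality")
  members <- canonical_modalities()[canonical_modalities() %in% members]
  structure(list(name = paste(members, collapse = "+"), members = members),
            class = "modality_config")
}

#' Define a classification task
#'
#' Binary tasks compare two diagnostic groups with the first-named group as
#' the positive class (AD vs MCI, AD vs HC, MCI vs HC); the multiclass task
#' distinguishes all three labels through one-vs-rest scorers.
#'
#' @param kind one of `"AD_vs_MCI"`, `"AD_vs_HC"`, `"MCI_vs_HC"`,
#'   `"multiclass"`.
#' @return Object of class `task_spec` with `kind`, `classes` and (binary
#'   only) `positive`.
#' @export
task_spec <- function(kind = c("AD_vs_MCI", "AD_vs_HC", "MCI_vs_HC", "multiclass")) {
  kind <- match.arg(kind)
  if (kind == "multiclass") {
    structure(list(kind = kind, classes = class_levels(), positive = NULL),
              class = "task_spec")
  } else {
    parts <- strsplit(kind, "_vs_")[[1]]
    structure(list(kind = kind, classes = parts, positive = parts[1]),
              class = "task_spec")
  }
}

#' Concatenate the feature blocks of a configuration
#'
#' Columns follow the canonical modality order (MRI, PET, CSF, SNP) with
#' feature names preserved, e.g. 93 + 93 + 3 = 189 columns for
#' MRI+PET+CSF at the default dimensions and 378 for all four modalities.
#'
#' @param dataset a `multimodal_dataset`.
#' @param config a `modality_config` (or anything [modality_config()]
#'   accepts).
#' @return List with `X` (subjects x features), `feature_names` and
#'   `block_dims` (named vector of per-modality widths).
#' @export
build_config_matrix <- function(dataset, config) {
  if (!inherits(config, "modality_config")) config <- modality_config(config)
  missing <- setdiff(config$members, names(dataset$blocks))
  if (length(missing)) stop("dataset lacks modalities: ", paste(missing, collapse = ", "))
  blocks <- dataset$blocks[config$members]
  X <- do.call(cbind, blocks)
  list(X = X, feature_names = colnames(X),
       block_dims = vapply(blocks, ncol, integer(1)))
}

#' Stratified k-fold partition
#'
#' Permutes subjects within each class (seeded) and deals them round-robin
#' across folds, so per-fold class counts differ from balance by at most
#' one subject and every subject appears in exactly one test fold.
#'
#' @param labels factor of class labels.
#' @param k number of folds.
#' @param seed RNG seed for the within-class permutations.
#' @return Integer vector of fold ids (1..k), aligned with `labels`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (min(table(labels)) < k)
    stop("stratified folding needs at least ", k, " subjects in every class")
  fold <- integer(length(labels))
  perms <- with_seed(seed, lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx))]
  }))
  for (p in perms) fold[p] <- rep_len(seq_len(k), length(p))
  fold
}

#' Default hyperparameter grids
#'
#' The `"full"` profile spans `C` over `10^-3..10^3` and every selector
#' penalty over `10^-4..10^1` (log-spaced); the `"quick"` profile is the
#' small documented grid used throughout the package's own experiments and
#' tests, chosen to keep a full protocol run at interactive speed.
#'
#' @param method one of `"baseline"`, `"mkl"`, `"hgmfs"`, `"smml"`.
#' @param profile `"quick"` or `"full"`.
#' @return A data frame, one row per grid cell.
#' @export
default_grid <- function(method = c("baseline", "mkl", "hgmfs", "smml"),
                         profile = c("quick", "full")) {
  method <- match.arg(method)
  profile <- match.arg(profile)
  if (profile == "full") {
    Cs <- 10^(-3:3)
    pen <- 10^(-4:1)
    return(switch(method,
      baseline = expand.grid(C = Cs),
      mkl = expand.grid(C = Cs, mkl_C = 10^(-3:3)),
      hgmfs = expand.grid(C = Cs, lambda1 = pen, lambda2 = pen, lambda3 = pen),
      smml = expand.grid(C = Cs, gamma1 = pen, gamma2 = pen)
    ))
  }
  # quick: two selector cells per method, SVM cost fixed at 1 (the
  # selectors, not the SVM, dominate both runtime and performance here);
  # the baseline grid varies C since that is its only parameter
  switch(method,
    baseline = expand.grid(C = c(0.01, 1, 100)),
    mkl = expand.grid(C = 1, mkl_C = c(1, 100)),
    hgmfs = expand.grid(C = 1, lambda1 = c(0.01, 0.1), lambda2 = 0.01,
                        lambda3 = 1e-4),
    smml = expand.grid(C = 1, gamma1 = c(0.01, 0.1), gamma2 = 0.01)
  )
}

# ---- per-fold preprocessing -------------------------------------------------
# Everything is fitted on training rows only: the SNP screening scores, the
# per-modality normalizers (zscore for continuous blocks, minmax for SNP)
# and the final unit-ball normalizer on the concatenation.

preprocess_split <- function(dataset, config, train_idx, test_idx,
                             snp_screen_k = 189, lgd_m = 5) {
  if (!inherits(config, "modality_config")) config <- modality_config(config)
  tr_blocks <- list(); te_blocks <- list(); kept <- list(); norms <- list()
  screen <- NULL
  for (m in config$members) {
    B <- dataset$blocks[[m]]
    Btr <- B[train_idx, , drop = FALSE]
    Bte <- B[test_idx, , drop = FALSE]
    keep <- seq_len(ncol(B))
    if (is_snp_modality(m) && ncol(B) > snp_screen_k) {
      screen <- lgd_score(t(Btr), m = min(lgd_m, nrow(Btr)))
      keep <- sort(select_top_k(screen, snp_screen_k))
      Btr <- Btr[, keep, drop = FALSE]
      Bte <- Bte[, keep, drop = FALSE]
    }
    nz <- fit_normalizer(Btr, if (is_snp_modality(m)) "minmax" else "zscore")
    tr_blocks[[m]] <- apply_normalizer(Btr, nz)
    te_blocks[[m]] <- apply_normalizer(Bte, nz)
    kept[[m]] <- keep
    norms[[m]] <- nz
  }
  Xtr <- do.call(cbind, tr_blocks)
  Xte <- do.call(cbind, te_blocks)
  ub <- fit_normalizer(Xtr, "unitball")
  Xtr <- apply_normalizer(Xtr, ub)
  Xte <- apply_normalizer(Xte, ub)
  block_dims <- vapply(tr_blocks, ncol, integer(1))
  off <- c(0, cumsum(block_dims))
  blocks_tr <- lapply(seq_along(block_dims), function(i)
    Xtr[, (off[i] + 1):off[i + 1], drop = FALSE])
  names(blocks_tr) <- names(block_dims)
  list(Xtr = Xtr, Xte = Xte, blocks_tr = blocks_tr,
       block_dims = block_dims, kept = kept, normalizers = norms,
       unitball = ub, screen = screen, feature_names = colnames(Xtr))
}

# ---- selector dispatch ------------------------------------------------------
# Returns a per-feature weight vector for the processed design matrix.

fit_selector_weights <- function(method, pre, ytr, task, params) {
  d <- ncol(pre$Xtr)
  if (method == "baseline") return(rep(1, d))
  if (task$kind == "multiclass") {
    lv <- class_levels()
    if (method == "mkl") {
      # one-vs-rest fits; the weight profile is shared across the three
      # tasks (averaged), mirroring kernel weights common to all of them
      ws <- vapply(lv, function(cl) {
        yy <- ifelse(ytr == cl, 1, -1)
        mkl_fit(pre$Xtr, yy, C = params$mkl_C)$feature_weights
      }, numeric(d))
      return(rowMeans(ws))
    }
    if (method == "hgmfs") {
      Y <- t(vapply(lv, function(cl) ifelse(ytr == cl, 1, -1),
                    numeric(length(ytr))))
      fit <- hgmfs_fit(t(pre$Xtr), Y, lambda1 = params$lambda1,
                       lambda2 = params$lambda2, lambda3 = params$lambda3)
      w <- fit$feature_weights
      w[-fit$selected] <- 0
      return(w)
    }
    if (method == "smml") {
      fit <- smml_fit(pre$blocks_tr, factor(ytr, levels = lv),
                      gamma1 = params$gamma1, gamma2 = params$gamma2)
      w <- fit$feature_weights
      w[-fit$selected] <- 0
      return(w)
    }
  } else {
    yy <- ifelse(ytr == task$positive, 1, -1)
    if (method == "mkl") {
      return(mkl_fit(pre$Xtr, yy, C = params$mkl_C)$feature_weights)
    }
    if (method == "hgmfs") {
      fit <- hgmfs_fit(t(pre$Xtr), matrix(yy, 1), lambda1 = params$lambda1,
                       lambda2 = params$lambda2, lambda3 = params$lambda3)
      w <- fit$feature_weights
      w[-fit$selected] <- 0
      return(w)
    }
    if (method == "smml") {
      fit <- smml_fit(pre$blocks_tr,
                      factor(ifelse(yy == 1, task$classes[1], task$classes[2]),
                             levels = task$classes),
                      gamma1 = params$gamma1, gamma2 = params$gamma2)
      w <- fit$feature_weights
      w[-fit$selected] <- 0
      return(w)
    }
  }
  stop("unknown method: ", method)
}

eval_fold <- function(dataset, config, task, method, params, train_idx,
                      test_idx, snp_screen_k) {
  ytr <- dataset$labels[train_idx]
  yte <- dataset$labels[test_idx]
  pre <- preprocess_split(dataset, config, train_idx, test_idx, snp_screen_k)
  w <- fit_selector_weights(method, pre, ytr, task, params)
  Xtr <- apply_feature_weighting(pre$Xtr, w)
  Xte <- apply_feature_weighting(pre$Xte, w)
  if (task$kind == "multiclass") {
    models <- lapply(class_levels(), function(cl)
      train_svm(Xtr, factor(ifelse(ytr == cl, "pos", "rest"),
                            levels = c("pos", "rest")), C = params$C))
    names(models) <- class_levels()
    pred <- predict_multiclass(models, Xte)
    met <- compute_metrics(yte, pred)
  } else {
    ybin <- factor(as.character(ytr), levels = task$classes)
    fit <- train_svm(Xtr, ybin, C = params$C)
    pred <- predict(fit, Xte, type = "class")
    met <- compute_metrics(as.character(yte), as.character(pred),
                           positive_class = task$positive)
  }
  list(metrics = met, weights = w, feature_names = pre$feature_names,
       block_dims = pre$block_dims)
}

eval_cell <- function(dataset, config, task, method, params, folds,
                      snp_screen_k) {
  k <- max(folds)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    per_fold[[f]] <- eval_fold(dataset, config, task, method, params,
                               which(folds != f), which(folds == f),
                               snp_screen_k)
  }
  metrics <- do.call(rbind, lapply(per_fold, `[[`, "metrics"))
  weights <- do.call(cbind, lapply(per_fold, `[[`, "weights"))
  list(metrics = metrics, weights = weights,
       feature_names = per_fold[[1]]$feature_names,
       block_dims = per_fold[[1]]$block_dims)
}

#' Cross-validated evaluation of one method on one configuration and task
#'
#' The full protocol: subjects of the task's classes are split into
#' stratified folds; within each training fold the SNP block is screened to
#' its top `snp_screen_k` features by LGD score, continuous blocks are
#' z-scored and the SNP block min-max scaled (all train-fitted), the
#' concatenation is scaled to the training unit ball, the selector is
#' fitted, features are element-wise weighted, and a linear SVM (one per
#' class for the multiclass task, argmax prediction) is trained and scored
#' on the held-out fold.  Grid search evaluates every row of `grid` on the
#' same fold partition and reports the cell with the best mean accuracy
#' (ties: first cell); this mirrors the best-performance reporting
#' convention and is optimistically biased — set `nested = TRUE` for
#' nested selection where each outer fold chooses its cell on an inner
#' split of its training data.
#'
#' @param dataset a `multimodal_dataset`.
#' @param config a `modality_config` or its name (e.g. `"MRI+SNP"`).
#' @param task a `task_spec` or its kind (e.g. `"AD_vs_HC"`).
#' @param method `"baseline"`, `"mkl"`, `"hgmfs"` or `"smml"`.
#' @param grid data frame of hyperparameter cells; default
#'   `default_grid(method, "quick")`.  Column `C` is the SVM cost; selector
#'   columns are `mkl_C`, `lambda1..3`, `gamma1..2`.
#' @param seed seed for the fold partition (all other computation is
#'   deterministic given the data).
#' @param n_folds number of folds (default 10).
#' @param snp_screen_k SNP features kept by the unsupervised screen.
#' @param nested logical; nested cross-validation for hyperparameter
#'   choice.
#' @return Object of class `cv_result`: per-fold metrics, aggregate
#'   `mean` and `sd` (percent), `chosen` hyperparameters, per-fold and
#'   averaged weight vectors, the fold assignment and grid summary.
#' @export
run_cv <- function(dataset, config, task, method = c("baseline", "mkl", "hgmfs", "smml"),
                   grid = NULL, seed = 1, n_folds = 10, snp_screen_k = 189,
                   nested = FALSE) {
  method <- match.arg(method)
  if (!inherits(config, "modality_config")) config <- modality_config(config)
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  if (is.null(grid)) grid <- default_grid(method, "quick")
  if (!nrow(grid)) stop("empty hyperparameter grid")
  keep <- dataset$labels %in% task$classes
  ds <- subset_dataset(dataset, which(keep))
  folds <- stratified_folds(ds$labels, n_folds, seed)
  if (nested) return(run_cv_nested(ds, config, task, method, grid, folds,
                                   snp_screen_k, seed))
  cells <- lapply(seq_len(nrow(grid)), function(i)
    eval_cell(ds, config, task, method, as.list(grid[i, , drop = FALSE]),
              folds, snp_screen_k))
  mean_acc <- vapply(cells, function(cl) mean(cl$metrics[, "accuracy"]), numeric(1))
  best <- which.max(mean_acc)
  res <- cells[[best]]
  new_cv_result(res, grid[best, , drop = FALSE], folds, method, config, task,
                seed, data.frame(grid, mean_accuracy = mean_acc))
}

run_cv_nested <- function(ds, config, task, method, grid, folds,
                          snp_screen_k, seed) {
  k <- max(folds)
  per_fold <- vector("list", k)
  chosen <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    inner_ds <- subset_dataset(ds, tr)
    inner_folds <- stratified_folds(inner_ds$labels,
                                    min(5, min(table(inner_ds$labels))),
                                    seed + f)
    inner_acc <- vapply(seq_len(nrow(grid)), function(i) {
      cl <- eval_cell(inner_ds, config, task, method,
                      as.list(grid[i, , drop = FALSE]), inner_folds,
                      snp_screen_k)
      mean(cl$metrics[, "accuracy"])
    }, numeric(1))
    bi <- which.max(inner_acc)
    chosen[[f]] <- grid[bi, , drop = FALSE]
    per_fold[[f]] <- eval_fold(ds, config, task, method,
                               as.list(grid[bi, , drop = FALSE]),
                               tr, which(folds == f), snp_screen_k)
  }
  res <- list(metrics = do.call(rbind, lapply(per_fold, `[[`, "metrics")),
              weights = do.call(cbind, lapply(per_fold, `[[`, "weights")),
              feature_names = per_fold[[1]]$feature_names,
              block_dims = per_fold[[1]]$block_dims)
  new_cv_result(res, do.call(rbind, chosen), folds, method, config, task,
                seed, NULL)
}

subset_dataset <- function(dataset, idx) {
  structure(list(
    blocks = lapply(dataset$blocks, function(b) b[idx, , drop = FALSE]),
    labels = droplevels(dataset$labels[idx]),
    subject_ids = dataset$subject_ids[idx],
    informative_truth = dataset$informative_truth,
    snp_maf = dataset$snp_maf,
    spec = dataset$spec
  ), class = "multimodal_dataset")
}

new_cv_result <- function(res, chosen, folds, method, config, task, seed,
                          grid_summary) {
  rownames(res$metrics) <- NULL
  structure(list(
    folds_metrics = data.frame(fold = seq_len(nrow(res$metrics)), res$metrics),
    mean = colMeans(res$metrics),
    sd = apply(res$metrics, 2, stats::sd),
    chosen = chosen,
    fold_weights = res$weights,
    avg_weights = rowMeans(res$weights),
    feature_names = res$feature_names,
    block_dims = res$block_dims,
    fold_assignment = folds,
    method = method, config = config$name, task = task$kind,
    seed = seed, grid_summary = grid_summary
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result: %s on %s, task %s (%d folds, seed %d)\n",
              x$method, x$config, x$task, max(x$fold_assignment), x$seed))
  cat(sprintf("  accuracy %.1f +/- %.1f %%", x$mean["accuracy"], x$sd["accuracy"]))
  if (!is.na(x$mean["sensitivity"]))
    cat(sprintf("; sensitivity %.1f +/- %.1f; specificity %.1f +/- %.1f",
                x$mean["sensitivity"], x$sd["sensitivity"],
                x$mean["specificity"], x$sd["specificity"]))
  cat("\n  chosen:", paste(sprintf("%s=%g", names(x$chosen), unlist(x$chosen[1, ])),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  cat(sprintf("%s | %s | %s: %s\n", object$method, object$config, object$task,
              paste(sprintf("%s %.1f +/- %.1f", colnames(object$folds_metrics)[-1],
                            object$mean, object$sd), collapse = "; ")))
  invisible(object$folds_metrics)
}

#' @export
plot.cv_result <- function(x, ...) {
  bd <- x$block_dims
  plot_weight_profile(x$avg_weights, x$feature_names, block_dims = bd,
                      main = sprintf("%s average weights (%s, %s)",
                                     x$method, x$config, x$task), ...)
}

#' Concatenated positions of the planted informative features
#'
#' Maps the per-modality ground-truth indices of a synthetic dataset to
#' column positions of a configuration's concatenated design matrix
#' (before any SNP screening).
#'
#' @param dataset a synthetic `multimodal_dataset` with recorded truth.
#' @param config a `modality_config` or name.
#' @return Integer vector of planted column indices.
#' @export
planted_indices <- function(dataset, config) {
  if (!inherits(config, "modality_config")) config <- modality_config(config)
  if (is.null(dataset$informative_truth)) stop("dataset has no recorded truth")
  dims <- vapply(dataset$blocks[config$members], ncol, integer(1))
  off <- c(0, cumsum(dims))
  out <- integer(0)
  for (i in seq_along(config$members)) {
    m <- config$members[i]
    out <- c(out, dataset$informative_truth[[m]] + off[i])
  }
  out
}
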