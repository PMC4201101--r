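test_that("linear SVM agrees with an independent QP oracle", {
  set.seed(3)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    y <- c(1, 1, 1, -1, -1, -1)
    sv <- train_svm(X, y, C = 10)
    qp <- oracle_svm_qp(X, y, 10)
    expect_lt(abs(sv$objective - qp$objective), 1e-6)
  }
})

test_that("separable two-point problem and label-flip symmetry", {
  X <- matrix(c(-1, 1, -1, 1), 2, 2)
  y <- c(-1, 1)
  sv <- train_svm(X, y, C = 1e4)
  expect_equal(predict(sv, X) > 0, c(FALSE, TRUE))
  expect_lt(abs(predict(sv, matrix(0, 1, 2))), 1e-6)  # boundary through origin
  set.seed(10)
  Xr <- matrix(rnorm(30), 15, 2)
  yr <- ifelse(Xr[, 1] > 0.2, 1, -1)
  if (length(unique(yr)) < 2) yr[1] <- -yr[1]
  s1 <- train_svm(Xr, yr, C = 2)
  s2 <- train_svm(Xr, -yr, C = 2)
  expect_equal(predict(s1, Xr), -predict(s2, Xr), tolerance = 1e-6)
})

test_that("multiclass argmax prediction and class-order tie-break", {
  scorer <- function(v) structure(list(v = v), class = "const_scorer")
  assign("predict.const_scorer",
         function(object, newdata, type = "decision", ...)
           rep(object$v, nrow(as.matrix(newdata))),
         envir = globalenv())
  on.exit(rm("predict.const_scorer", envir = globalenv()))
  models <- list(HC = scorer(0.2), MCI = scorer(-0.1), AD = scorer(0.5))
  expect_equal(as.character(predict_multiclass(models, matrix(0, 1, 1))), "AD")
  models2 <- list(HC = scorer(0.3), MCI = scorer(0.3), AD = scorer(0.1))
  expect_equal(as.character(predict_multiclass(models2, matrix(0, 1, 1))), "HC")
})

test_that("multiclass prediction agrees with a brute-force score maximum", {
  set.seed(8)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- factor(sample(c("HC", "MCI", "AD"), 100, TRUE),
              levels = c("HC", "MCI", "AD"))
  models <- lapply(levels(y), function(cl)
    train_svm(X, factor(ifelse(y == cl, "pos", "rest"),
                        levels = c("pos", "rest")), C = 1))
  names(models) <- levels(y)
  got <- predict_multiclass(models, X)
  scores <- sapply(models, function(m) predict(m, X))
  want <- levels(y)[apply(scores, 1, which.max)]
  expect_equal(as.character(got), want)
})

test_that("metrics match the confusion-table definitions", {
  # TP=3 TN=4 FP=1 FN=2 -> 70 / 60 / 80
  y_true <- c(rep("AD", 5), rep("HC", 5))
  y_pred <- c("AD", "AD", "AD", "HC", "HC", "HC", "HC", "HC", "HC", "AD")
  m <- compute_metrics(y_true, y_pred, positive_class = "AD")
  expect_equal(unname(m), c(70, 60, 80))
  perfect <- compute_metrics(y_true, y_true, positive_class = "AD")
  expect_equal(unname(perfect), c(100, 100, 100))
  expect_warning(compute_metrics(rep("HC", 3), rep("HC", 3), positive_class = "AD"),
                 "undefined")
})

test_that("metrics agree with an independent tally on random confusions", {
  set.seed(12)
  y_true <- sample(c("AD", "HC"), 50, TRUE)
  y_pred <- sample(c("AD", "HC"), 50, TRUE)
  m <- compute_metrics(y_true, y_pred, "AD")
  tp <- sum(y_true == "AD" & y_pred == "AD"); fn <- sum(y_true == "AD" & y_pred == "HC")
  tn <- sum(y_true == "HC" & y_pred == "HC"); fp <- sum(y_true == "HC" & y_pred == "AD")
  expect_equal(unname(m), 100 * c((tp + tn) / 50, tp / (tp + fn), tn / (tn + fp)))
})

test_that("feature weighting is an element-wise column product", {
  X <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(drop(apply_feature_weighting(X, c(0, 0.5, 2))), c(0, 1, 6))
  expect_equal(apply_feature_weighting(X, rep(1, 3)), X)
  expect_error(apply_feature_weighting(X, 1:2), "length mismatch")
  # dropping zero-weight columns leaves SVM decisions unchanged
  set.seed(3)
  Xr <- matrix(rnorm(60), 20, 3)
  yr <- ifelse(Xr[, 1] > 0, 1, -1)
  w <- c(1.3, 0, 0.7)
  full <- train_svm(apply_feature_weighting(Xr, w), yr, C = 5)
  red <- train_svm(apply_feature_weighting(Xr[, c(1, 3)], w[c(1, 3)]), yr, C = 5)
  expect_equal(predict(full, apply_feature_weighting(Xr, w)),
               predict(red, apply_feature_weighting(Xr[, c(1, 3)], w[c(1, 3)])),
               tolerance = 1e-6)
})

test_that("configuration matrices concatenate in canonical order", {
  ds <- generate_multimodal(synth_spec(seed = 2))
  cm <- build_config_matrix(ds, "MRI+PET+CSF")
  expect_equal(ncol(cm$X), 189L)
  expect_equal(unname(cm$block_dims), c(93L, 93L, 3L))
  all4 <- build_config_matrix(ds, "MRI+PET+CSF+SNP")
  expect_equal(ncol(all4$X), 378L)
  csf <- build_config_matrix(ds, "CSF")
  expect_equal(ncol(csf$X), 3L)
  expect_true(all(grepl("^CSF", csf$feature_names)))
  # order is canonical regardless of how members are written
  cm2 <- build_config_matrix(ds, modality_config(c("SNP", "MRI")))
  expect_equal(cm2$feature_names,
               c(colnames(ds$blocks$MRI), colnames(ds$blocks$SNP)))
  expect_error(build_config_matrix(list(blocks = ds$blocks["MRI"]), "PET"),
               "lacks|unknown")
  expect_equal(length(modality_configs()), 9L)
})

test_that("stratified folds partition every subject with balanced classes", {
  set.seed(4)
  labels <- factor(rep(c("HC", "MCI", "AD"), times = c(47, 93, 49)),
                   levels = c("HC", "MCI", "AD"))
  folds <- stratified_folds(labels, 10, seed = 1)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 189L)
  counts <- table(folds, labels)
  for (cl in colnames(counts)) {
    expect_lte(max(counts[, cl]) - min(counts[, cl]), 1)
  }
  expect_error(stratified_folds(factor(rep("a", 5)), 10), "at least")
})

test_that("per-fold preprocessing fits on training rows only (no leakage)", {
  ds <- generate_multimodal(tiny_spec(seed = 6, n = 15))
  train_idx <- 1:30; test_idx <- 31:45
  pre <- mmfs:::preprocess_split(ds, modality_config("MRI+SNP"), train_idx, test_idx)
  # deleting the test rows entirely must reproduce every fitted statistic
  ds_train_only <- mmfs:::subset_dataset(ds, train_idx)
  pre2 <- mmfs:::preprocess_split(ds_train_only, modality_config("MRI+SNP"),
                                  1:30, integer(0))
  expect_identical(pre$normalizers, pre2$normalizers)
  expect_identical(pre$kept, pre2$kept)
  expect_identical(pre$unitball, pre2$unitball)
  expect_identical(pre$Xtr, pre2$Xtr)
})

test_that("cross-validation is deterministic and grid search picks by accuracy", {
  ds <- generate_multimodal(tiny_spec(seed = 9, n = 12))
  g <- data.frame(C = c(0.01, 1))
  cv1 <- run_cv(ds, "MRI", "AD_vs_HC", "baseline", grid = g, seed = 5)
  cv2 <- run_cv(ds, "MRI", "AD_vs_HC", "baseline", grid = g, seed = 5)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$folds_metrics), 10L)
  expect_true(all(cv1$folds_metrics$accuracy >= 0 & cv1$folds_metrics$accuracy <= 100))
  expect_equal(cv1$grid_summary$mean_accuracy[match(cv1$chosen$C, cv1$grid_summary$C)],
               max(cv1$grid_summary$mean_accuracy))
  # every subject in exactly one test fold
  expect_equal(sort(unique(cv1$fold_assignment)), 1:10)
})

test_that("pure-noise features give chance-level accuracy", {
  spec <- synth_spec(n_per_class = c(HC = 50, MCI = 12, AD = 50),
                     modality_dims = c(MRI = 30, SNP = 20),
                     informative_counts = c(MRI = 0, SNP = 0),
                     effect_sizes = c(MRI = 0, SNP = 0), seed = 31)
  ds <- generate_multimodal(spec)
  cv <- run_cv(ds, "MRI", "AD_vs_HC", "baseline", grid = data.frame(C = 1),
               seed = 2)
  # binomial 95% band around the majority rate (50%) for 100 subjects
  band <- 1.96 * sqrt(0.5 * 0.5 / 100) * 100
  expect_lt(abs(cv$mean["accuracy"] - 50), band + 1e-9)
})

test_that("strong planted signal yields high accuracy for every method", {
  spec <- synth_spec(n_per_class = c(HC = 15, MCI = 15, AD = 15),
                     modality_dims = c(MRI = 10, SNP = 15),
                     informative_counts = c(MRI = 4, SNP = 4),
                     effect_sizes = c(MRI = 2.5, SNP = 2), seed = 8)
  ds <- generate_multimodal(spec)
  for (m in c("baseline", "mkl", "hgmfs", "smml")) {
    g <- utils::head(default_grid(m, "quick"), 1)
    g$C <- 10
    cv <- run_cv(ds, "MRI+SNP", "AD_vs_HC", m, grid = g, seed = 3)
    expect_gte(cv$mean["accuracy"], 90)
  }
})

test_that("weight vectors have the configuration dimension and average correctly", {
  ds <- generate_multimodal(tiny_spec(seed = 10, n = 12))
  cv <- run_cv(ds, "MRI+PET+CSF+SNP", "AD_vs_HC", "hgmfs",
               grid = data.frame(C = 1, lambda1 = 0.05, lambda2 = 0.01,
                                 lambda3 = 0), seed = 1)
  expect_equal(length(cv$avg_weights), sum(vapply(ds$blocks, ncol, 1L)))
  expect_equal(cv$avg_weights, rowMeans(cv$fold_weights), tolerance = 1e-12)
  expect_equal(ncol(cv$fold_weights), 10L)
})
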