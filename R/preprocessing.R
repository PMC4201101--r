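# Unsupervised feature scores and train-fitted normalization schemes.
#
# Score functions follow the selector convention of features in rows:
# X is d x N (features x samples).  Normalizers follow the pipeline
# convention of subjects in rows (N x d), since they sit between the data
# matrices and the classifiers.

new_feature_scores <- function(scores, names = NULL) {
  stop_if_not_finite(scores, "scores")
  structure(list(
    scores = as.numeric(scores),
    # descending score, ties broken by ascending feature index
    ranking = order(-scores, seq_along(scores)),
    feature_names = names %||% sprintf("f%03d", seq_along(scores))
  ), class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  cat("Feature scores for", length(x$scores), "features; top ranked:\n")
  top <- utils::head(x$ranking, 5)
  print(stats::setNames(round(x$scores[top], 4), x$feature_names[top]))
  invisible(x)
}

#' @export
as.data.frame.feature_scores <- function(x, ...) {
  data.frame(feature = x$feature_names, score = x$scores,
             rank = match(seq_along(x$scores), x$ranking))
}

#' Laplacian score for unsupervised feature ranking
#'
#' Scores each feature by the ratio of its graph-Laplacian quadratic form to
#' its degree-weighted second moment, `s(k) = X_k L X_k' / (X_k D X_k')`,
#' where the sample similarity graph `W_ij = exp(-||x_i - x_j||^2 / sigma)`
#' is the dense heat kernel over all sample pairs, `D = diag(rowSums(W))`
#' and `L = D - W`.  Low scores indicate features that vary smoothly over
#' the sample similarity graph (locality preserving); the classical usage
#' selects features with minimal score.  The returned ranking is descending
#' by score (the package-wide convention); negate the scores before ranking
#' if minimal-score selection is wanted.
#'
#' The numerator is evaluated as `0.5 * sum_ij W_ij (X_ki - X_kj)^2`, which
#' is algebraically identical to the quadratic form and returns an exact
#' zero for constant features (the Laplacian annihilates constants).
#' Zero-denominator features score 0.
#'
#' @param X numeric matrix, features in rows (d x N), N >= 2.
#' @param sigma heat-kernel bandwidth (> 0).
#' @param centered if `TRUE`, degree-center each feature first
#'   (`X_k - (X_k D 1 / 1' D 1) 1`), the variant of He et al.'s original
#'   formulation; the default `FALSE` scores the raw feature.
#' @param W optional precomputed N x N similarity matrix; when supplied the
#'   graph is held fixed, making the score invariant to rescaling a single
#'   feature.
#' @return A `feature_scores` object.
#' @export
laplacian_score <- function(X, sigma = 1, centered = FALSE, W = NULL) {
  X <- as.matrix(X)
  stop_if_not_finite(X, "X")
  N <- ncol(X)
  if (N < 2) stop("laplacian_score needs at least 2 samples")
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(W)) {
    D2 <- as.matrix(stats::dist(t(X)))^2
    W <- exp(-D2 / sigma)
  }
  deg <- rowSums(W)
  scores <- numeric(nrow(X))
  for (k in seq_len(nrow(X))) {
    v <- X[k, ]
    if (centered) v <- v - sum(v * deg) / sum(deg)
    num <- 0.5 * sum(W * outer(v, v, "-")^2)
    den <- sum(deg * v^2)
    scores[k] <- if (den > 0) num / den else 0
  }
  new_feature_scores(scores, rownames(X))
}

#' Local/global discriminative (LGD) score
#'
#' Scores each feature by the ratio of its global variance to its summed
#' local variance: the numerator is the total sum of squares about the
#' feature mean, and the denominator accumulates, over every sample `j`,
#' the sum of squares of the `m` values nearest to `x_j(k)` about their own
#' mean.  Features that are locally flat but globally spread (i.e., form
#' well-separated value clusters) receive large scores.  Neighborhoods are
#' the `m` nearest values including the sample itself, distance ties broken
#' by ascending sample index.
#'
#' @param X numeric matrix, features in rows (d x N).
#' @param m neighborhood size (1 <= m <= N); default 5.
#' @param epsilon small positive guard added to the denominator so that
#'   locally constant features score finitely.
#' @return A `feature_scores` object.
#' @export
lgd_score <- function(X, m = 5, epsilon = 1e-8) {
  X <- as.matrix(X)
  stop_if_not_finite(X, "X")
  N <- ncol(X)
  if (N < 2) stop("lgd_score needs at least 2 samples")
  if (m < 1 || m > N) stop("neighborhood size m must satisfy 1 <= m <= N")
  if (epsilon <= 0) stop("epsilon must be positive")
  scores <- numeric(nrow(X))
  idx <- seq_len(N)
  for (k in seq_len(nrow(X))) {
    v <- X[k, ]
    num <- sum((v - mean(v))^2)
    den <- 0
    for (j in idx) {
      nb <- order(abs(v - v[j]), idx)[seq_len(m)]
      den <- den + sum((v[nb] - mean(v[nb]))^2)
    }
    scores[k] <- num / (den + epsilon)
  }
  new_feature_scores(scores, rownames(X))
}

#' Select the top-k ranked features
#'
#' @param scores a `feature_scores` object.
#' @param k number of features to keep (1 <= k <= d).
#' @return Integer vector: the first `k` entries of the deterministic
#'   ranking (descending score, index tie-break).
#' @export
select_top_k <- function(scores, k) {
  stopifnot(inherits(scores, "feature_scores"))
  d <- length(scores$scores)
  if (k < 1 || k > d) stop("k must be between 1 and ", d)
  scores$ranking[seq_len(k)]
}

#' Train-fitted feature normalization
#'
#' Three schemes, each with per-feature statistics estimated on training
#' rows only and a small `epsilon` guard in every denominator:
#' \describe{
#'   \item{zscore}{`(x - mean) / (sd + eps)` with the population standard
#'     deviation (`1/N` inside the root).}
#'   \item{minmax}{`(x - min) / (max - min + eps)`; applied to unseen rows
#'     the result may leave `[0, 1]`, which is expected.}
#'   \item{unitball}{`x / (||column||_2 + eps)`, scaling each feature to the
#'     training-data unit ball.}
#' }
#'
#' @param X_train numeric matrix, subjects in rows (N x d), N >= 1.
#' @param scheme one of `"zscore"`, `"minmax"`, `"unitball"`.
#' @param epsilon small positive constant for the denominators.
#' @return A `normalizer` object holding the scheme and fitted statistics.
#' @export
fit_normalizer <- function(X_train, scheme = c("zscore", "minmax", "unitball"),
                           epsilon = 1e-8) {
  scheme <- match.arg(scheme)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 1) stop("need at least one training row")
  stop_if_not_finite(X_train, "X_train")
  stats_list <- switch(scheme,
    zscore = {
      mu <- colMeans(X_train)
      sd_pop <- sqrt(colMeans(sweep(X_train, 2, mu)^2))
      list(mean = mu, sd = sd_pop)
    },
    minmax = list(min = apply(X_train, 2, min), max = apply(X_train, 2, max)),
    unitball = list(norm = sqrt(colSums(X_train^2)))
  )
  structure(list(scheme = scheme, stats = stats_list, epsilon = epsilon,
                 d = ncol(X_train), feature_names = colnames(X_train)),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param X matrix to transform (same feature count as the training data).
#' @param params a fitted `normalizer`.
#' @export
apply_normalizer <- function(X, params) {
  stopifnot(inherits(params, "normalizer"))
  X <- as.matrix(X)
  if (ncol(X) != params$d)
    stop("feature count mismatch: normalizer fitted on ", params$d,
         " features, data has ", ncol(X))
  eps <- params$epsilon
  s <- params$stats
  out <- switch(params$scheme,
    zscore = sweep(sweep(X, 2, s$mean), 2, s$sd + eps, "/"),
    minmax = sweep(sweep(X, 2, s$min), 2, s$max - s$min + eps, "/"),
    unitball = sweep(X, 2, s$norm + eps, "/")
  )
  dimnames(out) <- dimnames(X)
  out
}

#' @export
print.normalizer <- function(x, ...) {
  cat("Normalizer:", x$scheme, "fitted on", x$d, "features (epsilon ",
      format(x$epsilon), ")\n")
  invisible(x)
}

#' Serialize / restore a fitted normalizer as JSON (for audit trails)
#' @param params a `normalizer`; `path` file path.
#' @return `read_normalizer` returns the restored `normalizer`.
#' @keywords internal
#' @export
write_normalizer <- function(params, path) {
  stopifnot(inherits(params, "normalizer"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$stats <- lapply(obj$stats, as.numeric)
  structure(obj, class = "normalizer")
}

#' Export feature scores as a two-column CSV
#' @param scores a `feature_scores` object; `path` file path.
#' @export
export_scores <- function(scores, path) {
  stopifnot(inherits(scores, "feature_scores"))
  utils::write.csv(data.frame(feature = scores$feature_names,
                              score = scores$scores),
                   path, row.names = FALSE)
  invisible(path)
}
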