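# Soft-margin linear SVM via libsvm (e1071) with an exact active-set
# refinement.  libsvm terminates on a dual-gap tolerance; the refinement
# re-solves the KKT system on the active set implied by the approximate
# dual solution, which in practice lands on the exact optimum and is what
# lets objective values be compared against independent QP solutions at
# 1e-6 tolerances.

svm_primal_objective <- function(X, y, C, w, b) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
}

# Exact minimizer over b of the hinge sum for fixed w: the objective is
# piecewise linear and convex in b, so a breakpoint attains the minimum.
optimal_bias <- function(X, y, w) {
  f <- drop(X %*% w)
  br <- y - f
  obj <- vapply(br, function(b) sum(pmax(0, 1 - y * (f + b))), numeric(1))
  # deterministic among ties: smallest candidate bias
  cand <- br[obj <= min(obj) + 1e-12]
  min(cand)
}

# Re-solve the dual KKT system on the active set implied by `alpha`.
# Returns a refined alpha or NULL when the set is degenerate.
kkt_refine <- function(K, y, C, alpha, tol = 1e-6) {
  n <- length(y)
  free <- which(alpha > C * tol & alpha < C * (1 - tol))
  atC <- which(alpha >= C * (1 - tol))
  if (length(free) == 0) return(NULL)
  nf <- length(free)
  M <- matrix(0, nf + 1, nf + 1)
  M[1:nf, 1:nf] <- K[free, free, drop = FALSE] * (y[free] %o% y[free])
  M[1:nf, nf + 1] <- y[free]
  M[nf + 1, 1:nf] <- y[free]
  fC <- if (length(atC)) drop(K[free, atC, drop = FALSE] %*% (C * y[atC])) else 0
  rhs <- c(1 - y[free] * fC, -if (length(atC)) sum(C * y[atC]) else 0)
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  a2 <- numeric(n)
  a2[atC] <- C
  a2[free] <- sol[1:nf]
  if (any(a2 < -1e-8) || any(a2 > C + 1e-8)) return(NULL)
  pmin(pmax(a2, 0), C)
}

# Internal workhorse: y in {-1, +1}.  Returns w, b, alpha, objective.
# `refine = FALSE` skips the KKT polish (used inside iterative schemes
# where libsvm precision suffices and the polish would dominate runtime).
linear_svm <- function(X, y, C, tol = 1e-10, refine = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1 / +1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be positive")
  fit <- e1071::svm(X, factor(y, levels = c(1, -1)), scale = FALSE,
                    kernel = "linear", cost = C, tolerance = tol)
  alpha <- numeric(nrow(X))
  alpha[fit$index] <- abs(as.numeric(fit$coefs))
  w <- drop(t(X) %*% (alpha * y))
  b <- optimal_bias(X, y, w)
  obj <- svm_primal_objective(X, y, C, w, b)
  ref <- if (refine) kkt_refine(tcrossprod(X), y, C, alpha) else NULL
  if (!is.null(ref)) {
    w2 <- drop(t(X) %*% (ref * y))
    b2 <- optimal_bias(X, y, w2)
    obj2 <- svm_primal_objective(X, y, C, w2, b2)
    if (obj2 <= obj) {
      w <- w2; b <- b2; obj <- obj2; alpha <- ref
    }
  }
  list(w = w, b = b, alpha = alpha, objective = obj)
}

#' Train a soft-margin linear SVM
#'
#' The standard primal problem
#' `min 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b))`, solved in the
#' dual by libsvm and refined to the exact optimum on the implied active
#' set.  Decision values are `w'x + b`; the first factor level (or +1) is
#' the positive class.
#'
#' @param X numeric matrix, subjects in rows.
#' @param y labels: a factor with two levels (first level = positive) or a
#'   numeric vector in \{-1, +1\}.
#' @param C cost parameter (> 0).
#' @param tol libsvm termination tolerance.
#' @return An object of class `linear_svm` with elements `w`, `b`,
#'   `objective`, `levels` (NULL for numeric input) and `C`.
#' @export
train_svm <- function(X, y, C = 1, tol = 1e-10) {
  lv <- NULL
  if (is.factor(y)) {
    lv <- levels(droplevels(y))
    if (length(lv) != 2) stop("y must have exactly two classes")
    y <- ifelse(droplevels(y) == lv[1], 1, -1)
  }
  fit <- linear_svm(X, y, C, tol)
  structure(list(w = fit$w, b = fit$b, objective = fit$objective,
                 levels = lv, C = C), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) stop("feature count mismatch")
  f <- drop(newdata %*% object$w) + object$b
  if (type == "decision") return(f)
  if (is.null(object$levels)) return(ifelse(f >= 0, 1, -1))
  factor(ifelse(f >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM (C =", x$C, "),", length(x$w), "features, objective",
      format(x$objective), "\n")
  invisible(x)
}

#' One-vs-rest multiclass prediction by maximum decision value
#'
#' Given one binary scorer per class, assigns each sample to the class
#' whose decision value is largest; exact ties are broken by the fixed
#' class order of `models` (for the diagnostic labels, HC < MCI < AD).
#'
#' @param models named list of fitted `linear_svm` objects (or any objects
#'   with a numeric `predict(..., type = "decision")` method), one per
#'   class, in class order.
#' @param X matrix of samples to classify (subjects in rows).
#' @return Factor of predicted classes with levels `names(models)`.
#' @export
predict_multiclass <- function(models, X) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be a named list (one scorer per class)")
  if (any(vapply(models, is.null, logical(1)))) stop("missing scorer")
  scores <- vapply(models, function(m) as.numeric(predict(m, X, type = "decision")),
                   numeric(nrow(as.matrix(X))))
  scores <- matrix(scores, nrow = nrow(as.matrix(X)))
  pick <- apply(scores, 1, which.max)  # which.max: first maximum = class-order tie-break
  factor(names(models)[pick], levels = names(models))
}

#' Classification metrics as percentages
#'
#' Accuracy for any label set; sensitivity (`TP / (TP + FN)`) and
#' specificity (`TN / (TN + FP)`) for binary tasks with an explicit
#' positive class.  Undefined ratios (no positives or no negatives in
#' `y_true`) are returned as `NA` with a warning rather than silently 0.
#'
#' @param y_true,y_pred vectors of true and predicted labels.
#' @param positive_class the positive label for sensitivity/specificity;
#'   `NULL` (default) reports accuracy only.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)` in
#'   percent (sensitivity/specificity `NA` when no positive class given).
#' @export
compute_metrics <- function(y_true, y_pred, positive_class = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  acc <- 100 * mean(y_true == y_pred)
  sens <- spec <- NA_real_
  if (!is.null(positive_class)) {
    pos <- y_true == positive_class
    if (!any(pos)) {
      warning("no positive-class samples: sensitivity undefined")
    } else {
      sens <- 100 * mean(y_pred[pos] == positive_class)
    }
    if (all(pos)) {
      warning("no negative-class samples: specificity undefined")
    } else {
      spec <- 100 * mean(y_pred[!pos] != positive_class)
    }
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Element-wise feature weighting
#'
#' Multiplies each feature column by its learned selector weight (the
#' element-wise product of features and weights that precedes the SVM
#' stage).  Zero-weight features are retained as zero columns, which is
#' decision-equivalent to dropping them.
#'
#' @param X numeric matrix, subjects in rows.
#' @param weights numeric vector, one weight per column of `X`.
#' @return The weighted matrix.
#' @export
apply_feature_weighting <- function(X, weights) {
  X <- as.matrix(X)
  if (ncol(X) != length(weights)) stop("length mismatch between features and weights")
  sweep(X, 2, weights, "*")
}
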