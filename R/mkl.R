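#' Multiple kernel learning with simplex-constrained kernel weights
#'
#' Fits the SimpleMKL-style objective
#' \deqn{\min_{\beta, w, b} \sum_m \frac{\|w_m\|^2}{2\beta_m}
#'   + C \sum_i \max\{0, 1 - y_i(\sum_m w_m' x_i^{(m)} + b)\},
#'   \quad \beta_m \ge 0,\ \|\beta\|_1 \le 1,}
#' with one linear basis kernel per feature group.  By default every
#' feature is its own group (M = d singleton groups), so the learned
#' \eqn{\beta} is a per-feature kernel weight profile; a coarser grouping
#' (e.g., one kernel per modality) can be supplied via `groups`.
#'
#' The solver alternates two exact minimizations: (i) with \eqn{\beta}
#' fixed, the weighted-kernel SVM — equivalently a linear SVM on features
#' scaled by \eqn{\sqrt{\beta_m}} — solved by [train_svm()]'s refined
#' libsvm path; (ii) with `w` fixed, the closed-form simplex update
#' \eqn{\beta_m = \|w_m\| / \sum_k \|w_k\|}, the exact minimizer of
#' \eqn{\sum_m \|w_m\|^2 / (2\beta_m)} under the constraint.  Both steps
#' decrease the objective, so the recorded trace is non-increasing; the
#' iteration stops when the decrease falls below `tol`, when `max_iter`
#' alternations are reached, or when numerical noise would produce an
#' increase.  Groups with \eqn{\beta_m = 0} have \eqn{w_m = 0} and
#' contribute nothing (the 0/0 convention).
#'
#' @param X numeric matrix, subjects in rows (N x d).
#' @param y binary labels in \{-1, +1\} (or a 2-level factor, first level
#'   positive).
#' @param C SVM cost parameter (> 0).
#' @param groups list of integer vectors partitioning `1:d` into kernel
#'   groups; default singleton groups.
#' @param tol stop when the objective decrease per alternation drops below
#'   this value.
#' @param beta_tol additionally stop when no kernel weight moved by more
#'   than this between alternations (selection has stabilized).
#' @param dual_gap_tol relative duality-gap stopping criterion: with
#'   `S_m = (1/2) (alpha y)' K_m (alpha y)`, the alternation stops when
#'   `(max_m S_m - sum_m beta_m S_m) / |J|` falls below this value.  The
#'   default 0.01 is the tolerance conventionally used with SimpleMKL-type
#'   solvers; set it to 0 to force full convergence (the optimality tests
#'   do).
#' @param max_iter maximum number of alternations.
#' @param svm_tol termination tolerance of the inner SVM solver.
#' @param select_tol features with `feature_weights` above this threshold
#'   form the selected set.
#' @return An object of class `mkl` with elements `beta` (kernel weights),
#'   `w` (primal weights on the original feature scale, length d), `b`,
#'   `objective_trace`, `feature_weights` (`|w|` per feature, used for
#'   downstream element-wise weighting and plotting), `selected`, `groups`
#'   and `C`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' y <- ifelse(X[, 1] + rnorm(20, sd = 0.3) > 0, 1, -1)
#' fit <- mkl_fit(X, y, C = 1)
#' fit$beta
#' @export
mkl_fit <- function(X, y, C = 1, groups = NULL, tol = 1e-6, beta_tol = 1e-3,
                    dual_gap_tol = 0.01, max_iter = 100, svm_tol = 1e-8,
                    select_tol = 1e-6) {
  X <- as.matrix(X)
  if (is.factor(y)) {
    lv <- levels(droplevels(y))
    if (length(lv) != 2) stop("y must have exactly two classes")
    y <- ifelse(droplevels(y) == lv[1], 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    stop("y must contain both classes coded -1 / +1")
  if (C <= 0) stop("C must be positive")
  d <- ncol(X)
  if (is.null(groups)) groups <- as.list(seq_len(d))
  gidx <- sort(unlist(groups))
  if (!identical(as.integer(gidx), seq_len(d)))
    stop("groups must partition the feature indices 1..d")
  M <- length(groups)

  beta <- rep(1 / M, M)
  w <- numeric(d)
  b <- 0
  trace <- numeric(0)
  obj_of <- function(w, b, beta) {
    reg <- 0
    for (m in seq_len(M)) {
      nw2 <- sum(w[groups[[m]]]^2)
      if (beta[m] > 0) reg <- reg + nw2 / (2 * beta[m])
      else if (nw2 > 0) reg <- Inf
    }
    reg + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
  }

  obj <- Inf
  svm_step <- function(beta, refine) {
    scale_vec <- numeric(d)
    for (m in seq_len(M)) scale_vec[groups[[m]]] <- sqrt(beta[m])
    Xs <- sweep(X, 2, scale_vec, "*")
    fit <- linear_svm(Xs, y, C, svm_tol, refine = refine)
    list(w = fit$w * scale_vec,  # back to the Eq. objective's parametrization
         b = fit$b, alpha = fit$alpha)
  }
  for (it in seq_len(max_iter)) {
    st <- svm_step(beta, refine = FALSE)
    obj_new <- obj_of(st$w, st$b, beta)
    if (is.finite(obj) && obj_new > obj - .Machine$double.eps * abs(obj) && it > 1)
      break  # numerically converged; keep the monotone trace
    if (obj_new <= obj) {
      w <- st$w; b <- st$b
      obj <- obj_new
    }
    trace <- c(trace, obj)
    # duality-gap check: S_m for the *unscaled* basis kernels
    u <- drop(crossprod(X, st$alpha * y))
    S <- vapply(groups, function(g) 0.5 * sum(u[g]^2), numeric(1))
    gap <- max(S) - sum(beta * S)
    if (is.finite(obj) && obj > 0 && gap / obj < dual_gap_tol) break
    # (ii) closed-form beta update (exact minimizer for fixed w)
    gn <- vapply(groups, function(g) sqrt(sum(w[g]^2)), numeric(1))
    if (sum(gn) == 0) break  # all-zero weights: nothing further to reweight
    beta_new <- gn / sum(gn)
    obj_beta <- obj_of(w, b, beta_new)
    dec <- obj - obj_beta
    dbeta <- max(abs(beta_new - beta))
    beta <- beta_new
    obj <- obj_beta
    trace <- c(trace, obj)
    if (dec < tol || dbeta < beta_tol) break
  }
  # final polished solve at the converged kernel weights
  stf <- svm_step(beta, refine = TRUE)
  obj_f <- obj_of(stf$w, stf$b, beta)
  if (obj_f <= obj) {
    w <- stf$w; b <- stf$b; obj <- obj_f
    trace <- c(trace, obj)
  }

  fw <- abs(w)
  structure(list(beta = beta, w = w, b = b, groups = groups,
                 objective_trace = trace, feature_weights = fw,
                 selected = which(fw > select_tol), C = C,
                 feature_names = colnames(X)), class = "mkl")
}

#' @export
predict.mkl <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) stop("feature count mismatch")
  f <- drop(newdata %*% object$w) + object$b
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' @export
coef.mkl <- function(object, ...) {
  stats::setNames(object$w, object$feature_names)
}

#' @export
print.mkl <- function(x, ...) {
  cat("Multiple kernel learning fit:", length(x$groups), "kernels over",
      length(x$w), "features\n")
  cat("  ||beta||_1 =", format(sum(x$beta)),
      "; nonzero kernels:", sum(x$beta > 1e-8), "\n")
  cat("  final objective:", format(utils::tail(x$objective_trace, 1)),
      "after", length(x$objective_trace), "recorded steps\n")
  invisible(x)
}

#' @export
plot.mkl <- function(x, ...) {
  plot_weight_profile(x$feature_weights, x$feature_names,
                      main = "MKL per-feature weights |w|", ...)
}

#' Serialize an MKL model to JSON
#' @param model an `mkl` fit; `path` file path.
#' @export
mkl_to_json <- function(model, path) {
  stopifnot(inherits(model, "mkl"))
  jsonlite::write_json(list(beta = model$beta, w = model$w, b = model$b,
                            groups = model$groups, C = model$C),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Shared base-graphics weight profile with optional modality boundaries.
plot_weight_profile <- function(weights, names = NULL, block_dims = NULL,
                                main = "Feature weights", ...) {
  graphics::plot(seq_along(weights), weights, type = "h",
                 xlab = "feature index", ylab = "weight", main = main, ...)
  if (!is.null(block_dims)) {
    bounds <- cumsum(block_dims)
    graphics::abline(v = bounds[-length(bounds)] + 0.5, lty = 2, col = "grey50")
    mids <- bounds - block_dims / 2
    graphics::mtext(names(block_dims), side = 3, at = mids, cex = 0.8)
  }
  invisible(NULL)
}
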