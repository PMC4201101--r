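# Sparse multimodal learning: multiclass hinge loss over modality-blocked
# features with two structured-sparsity penalties,
#
#   min_W  sum_i sum_p (1 - y_pi w_p' x_i)_+
#        + gamma1 * sum_p sum_q ||w_p^q||_2     (per modality-class block)
#        + gamma2 * ||W||_{2,1}                 (per feature row)
#
# where W is d x L, w_p^q the block of class p restricted to modality q.
# The objective is convex; the solver is consensus ADMM with three copies
# (hinge scores, block-penalized copy, row-penalized copy), each with a
# closed-form proximal update.  ADMM iterates are not monotone in the
# primal objective, so the solver tracks the incumbent (best) iterate:
# the returned W and the recorded trace always refer to the best objective
# value seen, making the trace non-increasing by construction.

smml_objective <- function(W, X, Yb, block_index, gamma1, gamma2) {
  U <- crossprod(X, W)                   # N x L scores
  hinge <- sum(pmax(0, 1 - t(Yb) * U))
  g1 <- 0
  if (gamma1 > 0) {
    for (q in unique(block_index))
      g1 <- g1 + sum(sqrt(colSums(W[block_index == q, , drop = FALSE]^2)))
  }
  g2 <- if (gamma2 > 0) sum(sqrt(rowSums(W^2))) else 0
  hinge + gamma1 * g1 + gamma2 * g2
}

#' Sparse multimodal learning
#'
#' Fits the convex objective above: a one-vs-rest multiclass hinge data
#' term plus `gamma1` times the sum of Euclidean norms of every
#' (modality, class) coefficient block (group-wise view: whole modalities
#' can be switched off per class) and `gamma2` times the row-wise l2,1
#' norm of `W` (individual view: features are kept or dropped jointly
#' across classes).  There is no bias term; append a constant feature to
#' emulate one.
#'
#' The solver is consensus ADMM: auxiliary variables for the score matrix
#' `U = X'W` (hinge prox, elementwise closed form), a block copy (group
#' soft-thresholding) and a row copy (row soft-thresholding), with the `W`
#' update a cached Cholesky solve of `(XX' + 2I)`.  The best iterate by
#' true objective is retained and reported (see the file header note on
#' monotonicity).  On small instances the final value matches independent
#' convex solvers to high accuracy, as the test suite verifies.
#'
#' @param blocks named list of numeric matrices (subjects in rows), one per
#'   modality in canonical order; rows must align across blocks.
#' @param y class labels: a factor (length N, >= 2 levels), or an L x N
#'   matrix of \{-1, +1\} one-vs-rest targets with exactly one `+1` per
#'   column.
#' @param gamma1 weight of the per-(modality, class) block penalty.
#' @param gamma2 weight of the row-wise l2,1 penalty.
#' @param rho ADMM penalty parameter.
#' @param max_iter iteration cap.
#' @param tol stop when the incumbent objective has not improved by more
#'   than `tol` (relative) over the last `patience` iterations.
#' @param patience iterations without incumbent improvement before the
#'   solver stops; ADMM iterates oscillate around the optimum, so the
#'   incumbent can improve only every few dozen iterations near
#'   convergence.
#' @param select_tol rows of `W` with l2 norm above this are the selected
#'   features.
#' @return Object of class `smml`: `W` (d x L), `objective_trace`
#'   (incumbent values), `selected`, `feature_weights` (row norms),
#'   `block_norms` (modality x class matrix of block l2 norms),
#'   `block_index`, class `levels`, the gammas.
#' @examples
#' set.seed(1)
#' blocks <- list(A = matrix(rnorm(40), 20, 2), B = matrix(rnorm(60), 20, 3))
#' y <- factor(rep(c("HC", "AD"), each = 10), levels = c("HC", "AD"))
#' fit <- smml_fit(blocks, y, gamma1 = 0.5, gamma2 = 0.5)
#' smml_block_norms(fit)
#' @export
smml_fit <- function(blocks, y, gamma1 = 0.1, gamma2 = 0.1, rho = 1,
                     max_iter = 4000, tol = 1e-9, patience = 200,
                     select_tol = 1e-6) {
  if (is.matrix(blocks)) blocks <- list(all = blocks)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (gamma1 < 0 || gamma2 < 0) stop("gammas must be nonnegative")
  n <- nrow(blocks[[1]])
  if (!all(vapply(blocks, nrow, 1L) == n)) stop("blocks disagree on subject count")
  Xfull <- do.call(cbind, blocks)
  block_index <- rep(names(blocks), times = vapply(blocks, ncol, 1L))
  d <- ncol(Xfull)

  if (is.factor(y)) {
    lv <- levels(droplevels(y))
    if (length(lv) < 2) stop("need at least two classes")
    Yb <- t(vapply(lv, function(cl) ifelse(droplevels(y) == cl, 1, -1),
                   numeric(n)))
  } else {
    Yb <- as.matrix(y)
    if (ncol(Yb) != n) stop("Y matrix must be L x N")
    if (!all(Yb %in% c(-1, 1)) || !all(colSums(Yb == 1) == 1))
      stop("each column of the target matrix must have exactly one +1")
    lv <- rownames(Yb) %||% paste0("class", seq_len(nrow(Yb)))
  }
  L <- nrow(Yb)
  X <- t(Xfull)                          # d x N
  Ytn <- t(Yb)                           # N x L, aligns with U

  # cached factorization for the W update
  A <- tcrossprod(X) + diag(2, d)
  Rchol <- chol(A)

  W <- matrix(0, d, L)
  U <- matrix(0, n, L)
  V1 <- matrix(0, d, L); V2 <- matrix(0, d, L)
  Lu <- matrix(0, n, L); L1 <- matrix(0, d, L); L2 <- matrix(0, d, L)
  qlevels <- unique(block_index)

  best_obj <- smml_objective(W, X, Yb, block_index, gamma1, gamma2)
  best_W <- W
  trace <- best_obj
  last_improve <- 0
  for (it in seq_len(max_iter)) {
    # W update: quadratic consensus step
    rhs <- X %*% (U - Lu) + (V1 - L1) + (V2 - L2)
    W <- backsolve(Rchol, backsolve(Rchol, rhs, transpose = TRUE))
    XtW <- crossprod(X, W)
    # U update: elementwise hinge prox on z = y * u
    Au <- XtW + Lu
    z <- Ytn * Au
    zp <- ifelse(z >= 1, z, ifelse(z <= 1 - 1 / rho, z + 1 / rho, 1))
    U <- Ytn * zp
    # V1 update: (modality, class) block shrinkage
    A1 <- W + L1
    for (q in qlevels) {
      rows <- block_index == q
      sub <- A1[rows, , drop = FALSE]
      nrm <- sqrt(colSums(sub^2))
      shrink <- pmax(0, 1 - (gamma1 / rho) / pmax(nrm, .Machine$double.xmin))
      V1[rows, ] <- sweep(sub, 2, shrink, "*")
    }
    # V2 update: row shrinkage
    A2 <- W + L2
    nrm <- sqrt(rowSums(A2^2))
    shrink <- pmax(0, 1 - (gamma2 / rho) / pmax(nrm, .Machine$double.xmin))
    V2 <- A2 * shrink
    # dual ascent
    Lu <- Lu + XtW - U
    L1 <- L1 + W - V1
    L2 <- L2 + W - V2
    obj <- smml_objective(W, X, Yb, block_index, gamma1, gamma2)
    if (obj < best_obj - tol * max(1, abs(best_obj))) last_improve <- it
    if (obj < best_obj) { best_obj <- obj; best_W <- W }
    trace <- c(trace, best_obj)
    if (it - last_improve >= patience) break
  }

  W <- best_W
  fw <- sqrt(rowSums(W^2))
  bn <- matrix(0, length(qlevels), L,
               dimnames = list(qlevels, lv))
  for (qi in seq_along(qlevels))
    bn[qi, ] <- sqrt(colSums(W[block_index == qlevels[qi], , drop = FALSE]^2))
  structure(list(W = W, objective_trace = trace,
                 selected = which(fw > select_tol),
                 feature_weights = fw, block_norms = bn,
                 block_index = block_index, levels = lv,
                 gamma1 = gamma1, gamma2 = gamma2,
                 feature_names = colnames(Xfull)), class = "smml")
}

#' Per-(modality, class) block norms of a fitted SMML model
#'
#' The Euclidean norm of each modality's coefficient block in each class's
#' decision function: a zero block means that modality is unused for that
#' class.
#'
#' @param model a fitted `smml` object.
#' @return Nonnegative matrix, modalities x classes.
#' @export
smml_block_norms <- function(model) {
  stopifnot(inherits(model, "smml"))
  model$block_norms
}

#' @export
predict.smml <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- do.call(cbind, newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W)) stop("feature count mismatch")
  scores <- newdata %*% object$W         # N x L
  colnames(scores) <- object$levels
  if (type == "decision") return(scores)
  pick <- apply(scores, 1, which.max)
  factor(object$levels[pick], levels = object$levels)
}

#' @export
coef.smml <- function(object, ...) {
  W <- object$W
  rownames(W) <- object$feature_names
  colnames(W) <- object$levels
  W
}

#' @export
print.smml <- function(x, ...) {
  cat("SMML fit:", nrow(x$W), "features,", length(x$levels), "classes,",
      length(unique(x$block_index)), "modalities\n")
  cat("  gamma = (", x$gamma1, ",", x$gamma2, ");",
      length(x$selected), "rows selected\n")
  cat("  final objective:", format(utils::tail(x$objective_trace, 1)), "\n")
  invisible(x)
}

#' @export
plot.smml <- function(x, ...) {
  plot_weight_profile(x$feature_weights, x$feature_names,
                      block_dims = table(factor(x$block_index,
                                                levels = unique(x$block_index))),
                      main = "SMML row-norm weights", ...)
}

#' Serialize an SMML model to JSON (with explicit block boundaries)
#' @param model an `smml` fit; `path` file path.
#' @export
smml_to_json <- function(model, path) {
  stopifnot(inherits(model, "smml"))
  jsonlite::write_json(list(W = model$W, block_index = model$block_index,
                            levels = model$levels,
                            gamma = c(model$gamma1, model$gamma2)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
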