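# Independent brute-force oracles.  Each is written as the most literal
# possible transcription of the quantity it checks (explicit loops, no
# shared code with the package internals) so that agreement is a genuine
# dual-route check.

oracle_laplacian <- function(X, sigma) {
  N <- ncol(X)
  W <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N)
    W[i, j] <- exp(-sum((X[, i] - X[, j])^2) / sigma)
  D <- diag(rowSums(W))
  L <- D - W
  sapply(seq_len(nrow(X)), function(k) {
    v <- X[k, ]
    den <- drop(t(v) %*% D %*% v)
    if (den > 0) drop(t(v) %*% L %*% v) / den else 0
  })
}

oracle_lgd <- function(X, m, epsilon = 1e-8) {
  N <- ncol(X)
  sapply(seq_len(nrow(X)), function(k) {
    v <- X[k, ]
    num <- 0
    for (i in 1:N) num <- num + (v[i] - mean(v))^2
    den <- 0
    for (j in 1:N) {
      nb <- order(abs(v - v[j]), seq_len(N))[1:m]
      mbar <- mean(v[nb])
      for (i in nb) den <- den + (v[i] - mbar)^2
    }
    num / (den + epsilon)
  })
}

oracle_pairwise <- function(W, X, Y) {
  N <- ncol(X)
  out <- 0
  for (i in 1:N) for (j in 1:N) {
    r <- (Y[, i] - Y[, j]) - t(W) %*% (X[, i] - X[, j])
    out <- out + sum(r^2)
  }
  out
}

oracle_triplet <- function(W, X, Y) {
  N <- ncol(X)
  M <- W %*% t(W)
  out <- 0
  for (i in 1:N) for (j in 1:N) for (k in 1:N) {
    t1 <- sum((Y[, i] - Y[, j]) * (Y[, j] - Y[, k]))
    t2 <- drop(t(X[, i] - X[, j]) %*% M %*% (X[, j] - X[, k]))
    out <- out + (t1 - t2)^2
  }
  out
}

# Central finite differences of a scalar function of a matrix argument.
oracle_fd_grad <- function(fn, W, h = 1e-6) {
  G <- W * 0
  for (a in seq_len(nrow(W))) for (b in seq_len(ncol(W))) {
    Wp <- W; Wp[a, b] <- Wp[a, b] + h
    Wm <- W; Wm[a, b] <- Wm[a, b] - h
    G[a, b] <- (fn(Wp) - fn(Wm)) / (2 * h)
  }
  G
}

# Exact linear SVM through kernlab's interior-point QP, refined on its own
# implied active set (independent of the package's libsvm route).
oracle_svm_qp <- function(X, y, C) {
  N <- nrow(X)
  K <- tcrossprod(X)
  H <- (y %o% y) * K + diag(1e-12, N)
  sol <- kernlab::ipop(c = rep(-1, N), H = H, A = t(y), b = 0,
                       l = rep(0, N), u = rep(C, N), r = 0,
                       sigf = 12, maxiter = 400)
  a <- kernlab::primal(sol)
  # active-set re-solve: free SVs satisfy y_i f(x_i) = 1 exactly
  free <- which(a > C * 1e-5 & a < C * (1 - 1e-5))
  atC <- which(a >= C * (1 - 1e-5))
  if (length(free)) {
    nf <- length(free)
    M <- rbind(cbind(K[free, free, drop = FALSE] * (y[free] %o% y[free]), y[free]),
               c(y[free], 0))
    fC <- if (length(atC)) drop(K[free, atC, drop = FALSE] %*% (C * y[atC])) else 0
    rhs <- c(1 - y[free] * fC, -if (length(atC)) sum(C * y[atC]) else 0)
    sol2 <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (!is.null(sol2) && all(sol2[1:nf] > -1e-9) && all(sol2[1:nf] < C + 1e-9)) {
      a2 <- numeric(N); a2[atC] <- C; a2[free] <- pmin(pmax(sol2[1:nf], 0), C)
      a <- a2
    }
  }
  w <- drop(t(X) %*% (a * y))
  f <- drop(X %*% w)
  # exact bias: minimizer of the piecewise-linear hinge sum over b
  bs <- y - f
  hs <- sapply(bs, function(b) sum(pmax(0, 1 - y * (f + b))))
  b <- bs[which.min(hs)]
  list(w = w, b = b, objective = 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (f + b))))
}

# Coordinate-descent LASSO objective (glmnet) matched to
# ||W'X - Y||_F^2 + lambda1 ||W||_1 with one target row.
oracle_lasso_obj <- function(X, y, lambda1) {
  N <- ncol(X)
  g <- glmnet::glmnet(t(X), drop(y), family = "gaussian", alpha = 1,
                      standardize = FALSE, intercept = FALSE,
                      lambda = lambda1 / (2 * N), thresh = 1e-14)
  w <- as.numeric(stats::coef(g))[-1]
  sum((drop(crossprod(matrix(w), X)) - drop(y))^2) + lambda1 * sum(abs(w))
}

# Simple proximal-gradient descent with fixed small step, used for
# random-restart comparisons on the nonconvex full objective.
oracle_hgmfs_multistart <- function(X, Y, lambda1, lambda2, lambda3,
                                    n_starts = 50, iters = 3000, step = 1e-3,
                                    seed = 1) {
  obj <- function(W) mmfs:::hgmfs_objective(W, X, Y, lambda1, lambda2, lambda3)
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    W <- matrix(rnorm(nrow(X) * nrow(Y), sd = 0.5), nrow(X), nrow(Y))
    st <- step
    fW <- obj(W)
    for (i in seq_len(iters)) {
      G <- mmfs:::hgmfs_smooth_grad(W, X, Y, lambda2, lambda3)
      Wn <- mmfs:::soft_threshold(W - st * G, lambda1 * st)
      fn <- obj(Wn)
      if (is.finite(fn) && fn <= fW) {
        W <- Wn; fW <- fn
      } else {
        st <- st / 2  # descent safeguard on the quartic landscape
        if (st < 1e-12) break
      }
    }
    best <- min(best, fW)
  }
  best
}

# Smoothed-objective oracle for the SMML problem: Moreau-envelope hinge and
# perturbed group norms, minimized by BFGS with a continuation schedule on
# the smoothing parameter.  An entirely different algorithmic route from
# the package's ADMM.
oracle_smml_obj <- function(X, Yb, block_index, gamma1, gamma2) {
  d <- nrow(X); L <- nrow(Yb)
  qs <- unique(block_index)
  sobj <- function(wv, mu) {
    W <- matrix(wv, d, L)
    Z <- 1 - t(Yb) * crossprod(X, W)
    hinge <- sum(ifelse(Z <= 0, 0, ifelse(Z < mu, Z^2 / (2 * mu), Z - mu / 2)))
    g1t <- sum(sapply(qs, function(q)
      sum(sqrt(colSums(W[block_index == q, , drop = FALSE]^2) + mu^2) - mu)))
    g2t <- sum(sqrt(rowSums(W^2) + mu^2) - mu)
    hinge + gamma1 * g1t + gamma2 * g2t
  }
  sgrad <- function(wv, mu) {
    W <- matrix(wv, d, L)
    Z <- 1 - t(Yb) * crossprod(X, W)
    dz <- ifelse(Z <= 0, 0, ifelse(Z < mu, Z / mu, 1))
    Gh <- -X %*% (dz * t(Yb))
    G1 <- matrix(0, d, L)
    for (q in qs) {
      r <- block_index == q
      nn <- sqrt(colSums(W[r, , drop = FALSE]^2) + mu^2)
      G1[r, ] <- sweep(W[r, , drop = FALSE], 2, nn, "/")
    }
    G2 <- W / sqrt(rowSums(W^2) + mu^2)
    as.vector(Gh + gamma1 * G1 + gamma2 * G2)
  }
  wv <- rep(0, d * L)
  for (mu in 10^seq(-1, -7, by = -1)) {
    o <- stats::optim(wv, fn = sobj, gr = sgrad, mu = mu, method = "BFGS",
                      control = list(maxit = 3000, reltol = 1e-14))
    wv <- o$par
  }
  W <- matrix(wv, d, L)
  U <- crossprod(X, W)
  hinge <- sum(pmax(0, 1 - t(Yb) * U))
  g1 <- sum(sapply(qs, function(q)
    sum(sqrt(colSums(W[block_index == q, , drop = FALSE]^2)))))
  g2 <- sum(sqrt(rowSums(W^2)))
  hinge + gamma1 * g1 + gamma2 * g2
}

# Tiny dataset helper used across test files.
tiny_spec <- function(seed = 1, n = 20,
                      dims = c(MRI = 12, PET = 12, CSF = 3, SNP = 30),
                      info = c(MRI = 3, PET = 3, CSF = 1, SNP = 3),
                      eff = c(MRI = 1, PET = 1.2, CSF = 0.8, SNP = 0.6),
                      ...) {
  synth_spec(n_per_class = c(HC = n, MCI = n, AD = n), modality_dims = dims,
             informative_counts = info, effect_sizes = eff, seed = seed, ...)
}
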