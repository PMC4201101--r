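test_that("laplacian score matches the explicit dense-matrix oracle", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(2:10, 1); N <- sample(4:30, 1)
    X <- matrix(rnorm(d * N), d, N)
    sigma <- runif(1, 0.5, 3)
    got <- laplacian_score(X, sigma = sigma)$scores
    want <- oracle_laplacian(X, sigma)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("laplacian score: constants score exactly zero, ratios are scale invariant", {
  set.seed(3)
  X <- rbind(rep(2.5, 8), rnorm(8))
  fs <- laplacian_score(X, sigma = 1)
  expect_identical(fs$scores[1], 0)
  # with the sample graph held fixed, rescaling a feature leaves its score
  W <- exp(-as.matrix(stats::dist(t(X)))^2)
  s1 <- laplacian_score(X, W = W)$scores[2]
  X2 <- X; X2[2, ] <- -4.2 * X[2, ]
  s2 <- laplacian_score(X2, W = W)$scores[2]
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("laplacian score is invariant to sample ordering", {
  set.seed(14)
  X <- matrix(rnorm(5 * 12), 5, 12)
  perm <- sample(12)
  expect_equal(laplacian_score(X, sigma = 2)$scores,
               laplacian_score(X[, perm], sigma = 2)$scores, tolerance = 1e-12)
})

test_that("LGD score matches the brute-force double loop", {
  set.seed(8)
  for (rep in 1:20) {
    d <- sample(2:10, 1); N <- sample(4:30, 1)
    m <- sample(2:min(6, N), 1)
    X <- matrix(rnorm(d * N), d, N)
    expect_equal(lgd_score(X, m = m)$scores, oracle_lgd(X, m), tolerance = 1e-10)
  }
  # worked examples: locally constant / globally varying, and a hand case
  expect_equal(lgd_score(matrix(c(0, 0, 0, 10, 10, 10), 1), m = 3,
                         epsilon = 1e-8)$scores, 150 / 1e-8)
  expect_equal(lgd_score(matrix(rep(2, 4), 1), m = 2)$scores, 0)
  v <- c(1, 1, 1, 5, 5, 5)
  expect_equal(lgd_score(matrix(v, 1), m = 4)$scores,
               oracle_lgd(matrix(v, 1), 4), tolerance = 1e-12)
})

test_that("LGD score is invariant to sample ordering", {
  set.seed(15)
  X <- matrix(rnorm(4 * 15), 4, 15)
  perm <- sample(15)
  expect_equal(lgd_score(X, m = 4)$scores, lgd_score(X[, perm], m = 4)$scores,
               tolerance = 1e-12)
})

test_that("ranking is descending with deterministic index tie-break", {
  fs <- mmfs:::new_feature_scores(c(0.1, 0.9, 0.5))
  expect_equal(select_top_k(fs, 2), c(2L, 3L))
  ties <- mmfs:::new_feature_scores(c(1, 1, 1))
  expect_equal(select_top_k(ties, 2), c(1L, 2L))
  expect_equal(sort(select_top_k(fs, 3)), 1:3)
  expect_error(select_top_k(fs, 0), "k must")
  expect_error(select_top_k(fs, 4), "k must")
})

test_that("score functions reject degenerate input", {
  expect_error(lgd_score(matrix(1:6, 2), m = 5), "m must")
  expect_error(laplacian_score(matrix(1, 1, 1)), "2 samples")
  expect_error(laplacian_score(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("zscore normalization reproduces the hand-computed example", {
  nz <- fit_normalizer(matrix(c(1, 2, 3), 3, 1), "zscore", epsilon = 0)
  expect_equal(drop(apply_normalizer(matrix(c(1, 2, 3), 3, 1), nz)),
               c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  # population sd (1/N), not the sample sd
  expect_equal(nz$stats$sd, sqrt(2 / 3), tolerance = 1e-12)
})

test_that("minmax and unitball normalizations match their formulas", {
  nz <- fit_normalizer(matrix(c(1, 2, 3), 3, 1), "minmax", epsilon = 0)
  expect_equal(drop(apply_normalizer(matrix(c(1, 2, 3), 3, 1), nz)), c(0, 0.5, 1))
  nz2 <- fit_normalizer(matrix(c(3, 4), 2, 1), "unitball", epsilon = 0)
  expect_equal(drop(apply_normalizer(matrix(c(3, 4), 2, 1), nz2)), c(0.6, 0.8))
})

test_that("train-fitted statistics are self-consistent and reused on test data", {
  set.seed(33)
  Xtr <- matrix(rnorm(40 * 6), 40, 6)
  Xte <- matrix(rnorm(10 * 6) + 2, 10, 6)
  nz <- fit_normalizer(Xtr, "zscore")
  expect_equal(colMeans(apply_normalizer(Xtr, nz)), rep(0, 6), tolerance = 1e-8)
  nu <- fit_normalizer(Xtr, "unitball")
  expect_equal(sqrt(colSums(apply_normalizer(Xtr, nu)^2)), rep(1, 6),
               tolerance = 1e-6)
  # test rows transformed with train statistics may leave [0, 1] under minmax
  nm <- fit_normalizer(Xtr, "minmax")
  expect_true(any(apply_normalizer(Xte, nm) > 1))
  expect_error(apply_normalizer(Xte[, 1:3], nm), "mismatch")
})

test_that("re-applying unitball after the pipeline composition changes nothing", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4)
  z <- apply_normalizer(X, fit_normalizer(X, "zscore"))
  u1 <- apply_normalizer(z, fit_normalizer(z, "unitball"))
  u2 <- apply_normalizer(u1, fit_normalizer(u1, "unitball"))
  expect_equal(u1, u2, tolerance = 1e-6)
})

test_that("normalizer round trips through JSON", {
  nz <- fit_normalizer(matrix(rnorm(12), 4, 3), "zscore")
  path <- withr::local_tempfile(fileext = ".json")
  write_normalizer(nz, path)
  nz2 <- read_normalizer(path)
  expect_equal(nz2$stats$mean, nz$stats$mean, tolerance = 1e-12)
  expect_identical(nz2$scheme, nz$scheme)
})
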