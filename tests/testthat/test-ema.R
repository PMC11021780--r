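test_that("the E step is a row-normalized softmax over bases", {
  # singleton basis: every responsibility is 1
  X <- matrix(rnorm(3 * 10), 3, 10)
  A <- e_step(X, matrix(rnorm(3), 3, 1))
  expect_true(all(A == 1))
  # hand case: inner products (1, 0) -> softmax (0.7311, 0.2689)
  X <- matrix(c(1, 0), 2, 1)
  mu <- cbind(c(1, 0), c(0, 1))
  A <- e_step(X, mu)
  expect_equal(drop(A), c(0.7310586, 0.2689414), tolerance = 1e-6)
  # shift invariance: adding a constant basis direction common to all
  # inner products of a row leaves the row unchanged
  X <- matrix(rnorm(4 * 6), 4, 6)
  mu <- matrix(rnorm(4 * 3), 4, 3)
  shifted <- crossprod(X, mu) + 5
  ref <- icunet:::softmax_rows_(crossprod(X, mu))
  expect_equal(icunet:::softmax_rows_(shifted), ref, tolerance = 1e-12)
  # every row sums to one
  A <- e_step(matrix(rnorm(8 * 50), 8, 50), matrix(rnorm(8 * 5), 8, 5))
  expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  expect_error(e_step(matrix(c(NaN, 1), 2, 1), matrix(rnorm(2), 2, 1)),
               "non-finite")
})

test_that("the M step equals the brute-force weighted mean (with maintenance)", {
  withr::with_seed(31, {
    for (i in 1:25) {
      D <- sample(2:16, 1); N <- sample(2:16, 1); K <- sample(1:16, 1)
      X <- matrix(rnorm(D * N), D, N)
      A <- icunet:::softmax_rows_(matrix(rnorm(N * K), N, K))
      expect_lt(max(abs(m_step(X, A) - m_step_bruteforce(X, A))), 1e-6)
    }
  })
})

test_that("M-step degenerate weights behave as documented", {
  X <- matrix(c(1, 0, 0, 1, 2, 2), 2, 3)
  # one-hot responsibilities: each basis is the (normalized) mean of its rows
  A <- rbind(c(1, 0), c(1, 0), c(0, 1))
  mu <- m_step(X, A)
  m1 <- rowMeans(X[, 1:2])
  expect_equal(mu[, 1], m1 / sqrt(sum(m1^2)), tolerance = 1e-5)
  # uniform responsibilities: both bases collapse to the global mean direction
  A <- matrix(0.5, 3, 2)
  mu <- m_step(X, A)
  expect_equal(mu[, 1], mu[, 2], tolerance = 1e-12)
  # an all-zero responsibility column falls back to the previous basis
  prev <- icunet:::normalize_columns_(matrix(rnorm(4), 2, 2))
  A0 <- cbind(c(1, 1, 1), 0)
  mu <- m_step(X, A0, prev = prev)
  expect_equal(mu[, 2], prev[, 2])
})

test_that("EM iteration composes E and M steps and recovers separated clusters", {
  withr::with_seed(33, {
    X <- matrix(rnorm(4 * 20), 4, 20)
    mu0 <- icunet:::normalize_columns_(matrix(rnorm(4 * 3), 4, 3))
    one <- em_iterate(X, mu0, t = 1L)
    A1 <- e_step(X, mu0)
    expect_equal(one$mu, m_step(X, A1, prev = mu0), tolerance = 1e-12)
    expect_equal(one$A, A1, tolerance = 1e-12)

    # K = 4 well-separated unit-direction clusters, noise-free
    K <- 4; D <- 8; per <- 32
    centers <- diag(1, D)[, 1:K] * 10
    X <- centers[, rep(1:K, each = per)]
    mu0 <- icunet:::normalize_columns_(centers[, c(2, 1, 3, 4)] +
                                         matrix(rnorm(D * K, sd = 0.05), D, K))
    fit <- em_iterate(X, mu0, t = 3L)
    # each cluster's responsibility mass concentrates on a single basis
    for (k in 1:K) {
      rows <- (k - 1) * per + seq_len(per)
      expect_gte(max(colSums(fit$A[rows, , drop = FALSE])) / per, 0.95)
    }
  })
})

test_that("within-assignment reconstruction error is non-increasing over EM", {
  withr::with_seed(34, {
    K <- 4; D <- 8; per <- 32
    centers <- matrix(rnorm(D * K, sd = 3), D, K)
    X <- centers[, rep(1:K, each = per)]
    mu <- icunet:::normalize_columns_(matrix(rnorm(D * K), D, K))
    errs <- numeric(0)
    for (t in 1:4) {
      fit <- em_iterate(X, mu, t = 1L)
      A <- fit$A
      mu <- fit$mu
      errs <- c(errs, sum((X - reconstruct(mu, A))^2))
    }
    expect_true(all(diff(errs) <= 1e-8))
  })
})

test_that("reconstruction is the low-rank map mu A^T", {
  # K = 1, constant attention: every column is the basis
  mu <- matrix(c(1, 0), 2, 1)
  A <- matrix(1, 5, 1)
  Xt <- reconstruct(mu, A)
  expect_true(all(Xt[1, ] == 1) && all(Xt[2, ] == 0))
  # one-hot attention copies the assigned basis
  mu <- matrix(rnorm(6), 3, 2)
  A <- rbind(c(1, 0), c(0, 1), c(1, 0))
  Xt <- reconstruct(mu, A)
  expect_equal(Xt[, 3], mu[, 1])
  # rank of the reconstruction never exceeds K
  withr::with_seed(35, {
    X <- matrix(rnorm(12 * 100), 12, 100)
    mu0 <- icunet:::normalize_columns_(matrix(rnorm(12 * 4), 12, 4))
    fit <- em_iterate(X, mu0, t = 3L)
    sv <- svd(reconstruct(fit$mu, fit$A))$d
    expect_true(all(sv[-(1:4)] < 1e-6))
  })
})

test_that("the EMA module preserves shape, honours the residual, and is
           deterministic at inference", {
  withr::with_seed(36, {
    C <- 8
    cfg <- ema_config(C, n_bases = 4L)
    layer <- icunet:::init_ema_layer_(C, 4L)
    for (shp in list(c(4, 4, 4), c(2, 6, 4), c(16, 16, 16))) {
      x <- array(rnorm(prod(shp) * C), c(shp, C))
      out <- ema_forward(x, layer, cfg)
      expect_identical(dim(out$out), dim(x))
    }
    x <- array(rnorm(4^3 * C), c(4, 4, 4, C))
    # zero pointwise convolutions: pure residual identity
    zl <- layer
    zl$win[] <- 0; zl$bin[] <- 0; zl$wout[] <- 0; zl$bout[] <- 0
    expect_equal(ema_forward(x, zl, cfg)$out, x, tolerance = 1e-12)
    # inference does not mutate state and repeats exactly
    o1 <- ema_forward(x, layer, cfg, training = FALSE)
    o2 <- ema_forward(x, layer, cfg, training = FALSE)
    expect_identical(o1$out, o2$out)
    expect_identical(o1$layer$mu, layer$mu)
    # channel mismatch is rejected
    bad <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
    expect_error(ema_forward(bad, layer, cfg), "channel mismatch")
  })
})

test_that("global basis maintenance interpolates and renormalizes", {
  withr::with_seed(37, {
    state <- icunet:::normalize_columns_(matrix(rnorm(10 * 4), 10, 4))
    conv <- icunet:::normalize_columns_(matrix(rnorm(10 * 4), 10, 4))
    expect_equal(update_global_bases(state, conv, momentum = 1), state,
                 tolerance = 1e-12)
    expect_equal(update_global_bases(state, conv, momentum = 0), conv,
                 tolerance = 1e-12)
    for (mom in c(0.25, 0.5, 0.9)) {
      up <- update_global_bases(state, conv, momentum = mom)
      expect_equal(colSums(up^2), rep(1, 4), tolerance = 1e-10)
    }
  })
})
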