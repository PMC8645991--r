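test_that("pearson_edge handles collinear, anti-collinear and orthogonal cases", {
  expect_equal(pearson_edge(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_edge(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_edge(c(1, 0, -1, 0), c(0, 1, 0, -1)), 0.0)
  expect_error(pearson_edge(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_edge(1:2, 1:2), "length")
})

test_that("pearson_network matches the direct-formula oracle entrywise", {
  for (seed in 1:6) {
    ts <- rand_subject(seed, t = 40, n = 5)
    W <- pearson_network(ts)$weights
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(W[i, j], oracle_pearson(ts$signal[, i], ts$signal[, j]),
                   tolerance = 1e-12)
    }
    expect_equal(W, t(W), tolerance = 1e-15)
    expect_equal(diag(W), rep(0, 5))
  }
})

test_that("pearson_network is invariant under positive affine column rescaling", {
  ts <- rand_subject(3, t = 50, n = 4)
  W1 <- pearson_network(ts)$weights
  sig2 <- ts$signal
  sig2[, 2] <- 5.5 * sig2[, 2] + 100
  W2 <- pearson_network(subject_ts("s2", sig2))$weights
  expect_equal(W1, W2, tolerance = 1e-12)
})

test_that("duplicated columns give unit correlation; degenerate columns are named", {
  set.seed(4)
  sig <- matrix(rnorm(120), 40, 3)
  sig <- cbind(sig, sig[, 1])
  W <- pearson_network(subject_ts("dup", sig))$weights
  expect_equal(W[1, 4], 1.0)
  sig[, 2] <- 7
  expect_error(pearson_network(subject_ts("flat", sig,
                                          c("A", "BAD", "C", "D"))), "BAD")
})

test_that("independent columns at long T keep correlations below the Fisher bound", {
  set.seed(11)
  ts <- subject_ts("null", matrix(rnorm(2000 * 8), 2000, 8))
  W <- pearson_network(ts)$weights
  expect_lt(max(abs(W)), 4 / sqrt(2000))
})

test_that("sr_network returns the exact zero matrix above the lasso null threshold", {
  ts <- rand_subject(5, t = 60, n = 6)
  X <- scale(ts$signal)
  thr <- 2 * max(abs(crossprod(X) - diag(diag(crossprod(X)))))
  W <- sr_network(ts, lam = thr * 1.01)$weights
  expect_identical(W, matrix(0, 6, 6))
})

test_that("sr_network with two nodes and no penalty equals simple regression", {
  ts <- rand_subject(6, t = 80, n = 2)
  X <- scale(ts$signal)
  W <- sr_network(ts, lam = 0)$weights
  expect_equal(W[1, 2], sum(X[, 2] * X[, 1]) / sum(X[, 2]^2), tolerance = 1e-8)
  expect_equal(W[2, 1], sum(X[, 1] * X[, 2]) / sum(X[, 1]^2), tolerance = 1e-8)
})

test_that("sr_network objective beats W = 0 and matches the glmnet oracle across the grid", {
  skip_if_not_installed("glmnet")
  ts <- rand_subject(7, t = 100, n = 6)
  X <- scale(ts$signal)
  Tn <- nrow(X)
  for (lam in 2^seq(-5, 5, by = 2)) {
    W <- sr_network(ts, lam = lam)$weights
    obj <- oracle_sr_objective(X, W, lam)
    expect_lte(obj, oracle_sr_objective(X, matrix(0, 6, 6), lam) + 1e-9)
    # glmnet minimizes (1/(2T))||y - Xb||^2 + lam_g ||b||_1
    obj_oracle <- 0
    for (i in 1:6) {
      g <- glmnet::glmnet(X[, -i], X[, i], lambda = lam / (2 * Tn),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14)
      b <- as.numeric(g$beta)
      obj_oracle <- obj_oracle + sum((X[, i] - X[, -i] %*% b)^2) + lam * sum(abs(b))
    }
    expect_equal(oracle_sr_objective(X, W, lam), obj_oracle, tolerance = 1e-5)
  }
})

test_that("sr_network support shrinks monotonically along the penalty grid", {
  ts <- rand_subject(8, t = 80, n = 8)
  nnz <- vapply(2^(-5:5), function(l) sum(sr_network(ts, l)$weights != 0), 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("sr_network recovers planted precision-structure edges", {
  # Gaussian data with 3 true partial-correlation edges among 5 ROIs;
  # the symmetrized support must contain >= 2 of them on average
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5))
  Omega <- diag(5)
  Omega[edges] <- Omega[edges[, c(2, 1)]] <- -0.45
  Sigma <- solve(Omega)
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(500 * 5), 500, 5) %*% chol(Sigma)
    W <- sr_network(subject_ts("g", X), lam = 2^4)$weights
    S <- (W + t(W)) / 2
    hits <- hits + sum(S[edges] != 0)
  }
  expect_gte(hits / 20, 2)
})

test_that("granger_pair matches the lm() oracle and is nonnegative", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(120); y <- 0.4 * c(0, x[-120]) + rnorm(120)
    for (p in 1:2) {
      got <- granger_pair(x, y, p)
      expect_equal(got$f_value, oracle_granger(x, y, p), tolerance = 1e-10)
      expect_gte(got$f_value, 0)
      expect_lte(got$unrestricted_residual_variance,
                 got$restricted_residual_variance + 1e-10)
    }
  }
})

test_that("granger_pair: null pairs are near zero, planted causality is detected", {
  set.seed(21)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(granger_pair(x, y, 1)$f_value, 0.01)
  x2 <- rnorm(2000)
  y2 <- 0.8 * c(0, x2[-2000]) + rnorm(2000)
  f_xy <- granger_pair(x2, y2, 1)$f_value
  f_yx <- granger_pair(y2, x2, 1)$f_value
  expect_gt(f_xy, 0.1)
  expect_gt(f_xy, f_yx)
})

test_that("granger_pair rejects degenerate inputs and ignores level shifts", {
  set.seed(2)
  y <- rnorm(50)
  expect_error(granger_pair(rep(1, 50), y), "zero variance")
  x <- rnorm(50)
  a <- granger_pair(x, y, 1)$f_value
  b <- granger_pair(x + 100, y - 3, 1)$f_value
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("gcm_network equals per-pair granger_pair calls and flags null data", {
  ts <- rand_subject(9, t = 150, n = 5)
  W <- gcm_network(ts, p = 1)$weights
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(W[i, j],
                 granger_pair(ts$signal[, i], ts$signal[, j], 1)$f_value,
                 tolerance = 1e-12)
  }
  set.seed(31)
  big <- subject_ts("null", matrix(rnorm(5000 * 4), 5000, 4))
  expect_lt(max(gcm_network(big)$weights), 0.01)
})

test_that("gcm_network ranks a planted causal chain above all other edges", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    T <- 2000
    e <- matrix(rnorm(T * 3), T, 3)
    X <- matrix(0, T, 3)
    for (t in 2:T) {
      X[t, 1] <- 0.3 * X[t - 1, 1] + e[t, 1]
      X[t, 2] <- 0.5 * X[t - 1, 1] + 0.3 * X[t - 1, 2] + e[t, 2]
      X[t, 3] <- 0.5 * X[t - 1, 2] + 0.3 * X[t - 1, 3] + e[t, 3]
    }
    W <- gcm_network(subject_ts("chain", X))$weights
    planted <- c(W[1, 2], W[2, 3])
    others <- W[W != 0 & !(row(W) == 1 & col(W) == 2) & !(row(W) == 2 & col(W) == 3)]
    wins <- wins + (min(planted) > max(others))
  }
  expect_gte(wins, 18)
})

test_that("higher-order gcm_network agrees with the per-pair path", {
  ts <- rand_subject(10, t = 80, n = 4)
  W2 <- gcm_network(ts, p = 2)$weights
  expect_equal(W2[3, 1],
               granger_pair(ts$signal[, 3], ts$signal[, 1], 2)$f_value,
               tolerance = 1e-12)
})
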