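test_that("stepwise selection matches exhaustive rule application on small designs", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 30
    X <- matrix(rnorm(n * 5), n, 5)
    y <- ifelse(X[, 1] + 0.8 * X[, 4] + rnorm(n) > 0, 1, -1)
    got <- stepwise_select(X, y)$selected
    want <- brute_stepwise(X, y)
    expect_identical(got, want, info = paste("seed", seed))
  }
  # D = 6 with continuous response
  set.seed(99)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X[, 2] - 0.5 * X[, 5] + rnorm(40)
  expect_identical(stepwise_select(X, y)$selected, brute_stepwise(X, y))
})

test_that("stepwise finds a dominant predictor among decoys and rejects pure noise", {
  set.seed(11)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6) # columns 1,2,4,5,6 are decoys
  y <- X[, 3] + 0.01 * rnorm(n)
  m <- stepwise_select(X, y, p_in = 0.05)
  expect_true(3L %in% m$selected)
  expect_identical(m$selected[1], 3L)

  # nothing passes a near-zero entry threshold when y is independent of X
  set.seed(12)
  X0 <- matrix(rnorm(60 * 8), 60, 8)
  y0 <- rnorm(60)
  expect_length(stepwise_select(X0, y0, p_in = 1e-12)$selected, 0)
})

test_that("stepwise selection depends on column content, not decoy order", {
  set.seed(21)
  n <- 60
  signal <- rnorm(n)
  decoys <- matrix(rnorm(n * 4), n, 4)
  y <- 2 * signal + rnorm(n, sd = 0.5)
  X1 <- cbind(signal, decoys)            # signal in column 1
  X2 <- cbind(decoys[, c(3, 1)], signal, decoys[, c(4, 2)]) # permuted decoys
  sel1 <- stepwise_select(X1, y)$selected
  sel2 <- stepwise_select(X2, y)$selected
  # map selected indices back to content: signal column must be picked in both
  expect_true(1L %in% sel1)
  expect_true(3L %in% sel2)
  expect_equal(length(sel1), length(sel2))
})

test_that("stepwise handles degenerate columns, caps, and replays its trace", {
  set.seed(31)
  X <- cbind(rnorm(40), rep(1, 40), rnorm(40)) # constant column 2
  y <- X[, 1] + rnorm(40, sd = 0.2)
  expect_warning(m <- stepwise_select(X, y), "constant")
  expect_false(2L %in% m$selected)

  set.seed(32)
  Xb <- matrix(rnorm(50 * 8), 50, 8)
  yb <- Xb[, 1] + Xb[, 2] + Xb[, 3] + rnorm(50, sd = 0.1)
  m1 <- stepwise_select(Xb, yb, max_features = 2)
  expect_lte(length(m1$selected), 2)

  # the trace replays to the same selected set
  m2 <- stepwise_select(Xb, yb)
  replay <- integer(0)
  for (i in seq_len(nrow(m2$trace))) {
    if (m2$trace$action[i] == "add") replay <- c(replay, m2$trace$index[i])
    else replay <- setdiff(replay, m2$trace$index[i])
  }
  expect_identical(replay, m2$selected)
})

test_that("apply_stepwise restricts columns in selection order", {
  set.seed(41)
  X <- matrix(rnorm(50 * 6), 50, 6)
  m <- structure(list(selected = c(3L), D = 6L), class = "stepwise_model")
  expect_equal(apply_stepwise(m, X), X[, 3, drop = FALSE])
  m2 <- structure(list(selected = c(5L, 2L), D = 6L), class = "stepwise_model")
  expect_equal(apply_stepwise(m2, X), X[, c(5, 2)])
  m0 <- structure(list(selected = integer(0), D = 6L), class = "stepwise_model")
  expect_error(apply_stepwise(m0, X), "zero features")
  # the generic transform maps an empty selection to an n x 0 matrix instead
  expect_equal(dim(transform_dimred(m0, X)), c(50L, 0L))
})

test_that("PCA recovers dominant directions with orthonormal components", {
  set.seed(51)
  n <- 200
  t <- rnorm(n, sd = 3)
  X <- cbind(t, t) + matrix(rnorm(2 * n, sd = 0.01), n, 2)
  p <- pca_fit(X, 2)
  expect_equal(abs(p$components[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-3)
  expect_gt(p$components[which.max(abs(p$components[, 1])), 1], 0) # sign fix

  set.seed(52)
  X2 <- matrix(rnorm(100 * 12), 100, 12)
  p2 <- pca_fit(X2, 12)
  expect_lt(max(abs(crossprod(p2$components) - diag(12))), 1e-8)
  expect_true(all(diff(p2$eigenvalues) <= 1e-10))
  expect_true(all(p2$eigenvalues >= -1e-10))
  # eigenvalue sum conserves the total variance of the centered data
  expect_equal(p2$total_variance, sum(diag(cov(X2))), tolerance = 1e-8)
  # scores of the training data have diagonal covariance = eigenvalues
  Z <- pca_transform(p2, X2)
  expect_equal(cov(Z), diag(p2$eigenvalues), tolerance = 1e-8)
  # full-rank projection preserves pairwise distances of centered rows
  Xc <- scale(X2, scale = FALSE)
  expect_equal(as.matrix(dist(Z)), as.matrix(dist(Xc)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # refits are bit-stable (deterministic sign convention)
  expect_identical(pca_fit(X2, 5)$components, pca_fit(X2, 5)$components)

  expect_error(pca_fit(X2, 0), "M must be")
  expect_error(pca_fit(X2, 13), "M must be")
})

test_that("the control condition passes features through unchanged", {
  X <- matrix(rnorm(20), 5, 4)
  expect_identical(no_reduction(X), X)
  m <- fit_dimred(X, rep(c(1, -1), length.out = 5), "none")
  expect_identical(transform_dimred(m, X), X)
  expect_equal(ncol(transform_dimred(m, X)), 4)
})
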