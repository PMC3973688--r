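test_that("LDA weights solve Sigma w = mu_t - mu_n, with pseudo-inverse when singular", {
  set.seed(1)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- rep(c(TRUE, FALSE), 100)
  fit <- lda_fit(X, y)
  resid <- fit$covariance %*% fit$weights - (fit$mean_target - fit$mean_nontarget)
  expect_lt(max(abs(resid)), 1e-8)
  expect_true(isSymmetric(fit$covariance, tol = 1e-12))

  # duplicated feature column: singular covariance; weights must match the
  # minimal-norm solution of an independent SVD pseudo-inverse
  Xd <- cbind(X, X[, 1])
  fd <- lda_fit(Xd, y)
  expect_true(all(is.finite(fd$weights)))
  S <- cov(Xd)
  d <- colMeans(Xd[y, ]) - colMeans(Xd[!y, ])
  w_oracle <- as.vector(svd_pinv(S) %*% d)
  expect_equal(fd$weights, w_oracle, tolerance = 1e-6)

  # total covariance is pooled over all rows ignoring class
  expect_equal(fit$covariance, cov(X), tolerance = 1e-12)
  # the within-class option differs once class means differ
  X2 <- X; X2[y, 1] <- X2[y, 1] + 5
  ft <- lda_fit(X2, y, covariance = "total")
  fw <- lda_fit(X2, y, covariance = "within")
  expect_gt(max(abs(ft$covariance - fw$covariance)), 0.1)

  expect_error(lda_fit(X, rep(TRUE, 200)), "both target and non-target")
})

test_that("letter decisions use row/column argmax with deterministic tie-breaks", {
  m <- default_letter_matrix()
  s <- rep(0, 12); s[2] <- 3; s[9] <- 5
  expect_identical(predict_letter(s, m), "N") # column 2, row 3
  # all-equal scores fall back to the top-left cell (lowest codes)
  expect_identical(predict_letter(rep(1, 12), m), m[1, 1])
  # adding a constant to all 12 scores never changes the decision
  expect_identical(predict_letter(s + 17.3, m), "N")
  expect_error(predict_letter(c(s, 0), m))
})

test_that("K = 1, j = 1 scores reduce to w . x per code", {
  s <- tiny_session(n_letters = 3)
  f <- preprocess_session(s)
  tr <- subset_features(f, letters = 1:2)
  te <- subset_features(f, letters = 3)
  m <- train_ensemble(tr, partition_spec(1, 1), dimred = "none")
  S <- score_letter(m, te, j = 1)
  w <- m$learners[[1]]$lda$weights
  rows <- te$labels$sequence == 1
  manual <- vapply(1:12, function(i)
    sum(te$X[rows & te$labels$code == i, , drop = FALSE] %*% w), numeric(1))
  expect_equal(unname(S), manual, tolerance = 1e-10)
})

test_that("B = K ensembles decide identically to a single classifier for all conditions", {
  s <- tiny_session(n_letters = 8)
  f <- preprocess_session(s)
  tr <- subset_features(f, letters = 1:5)
  te <- subset_features(f, letters = 6:8)
  for (dr in c("none", "stepwise", "pca")) {
    ens <- train_ensemble(tr, partition_spec(5, 5), dimred = dr)
    single <- train_ensemble(tr, partition_spec(1, 1), dimred = dr)
    for (j in c(1, 3)) {
      expect_identical(predict_speller(ens, te, j), predict_speller(single, te, j),
                       info = paste(dr, "j =", j))
    }
    # scores differ by exactly the factor K
    l6 <- subset_features(te, letters = 6)
    expect_equal(score_letter(ens, l6, 3), 5 * score_letter(single, l6, 3),
                 tolerance = 1e-8)
  }
})

test_that("B = 1 ensembles decide identically to an independent naive-partitioning coding", {
  s <- tiny_session(n_letters = 9, seed = 13)
  f <- preprocess_session(s)
  tr <- subset_features(f, letters = 1:6)
  te <- subset_features(f, letters = 7:9)
  for (dr in c("none", "stepwise", "pca")) {
    ens <- train_ensemble(tr, partition_spec(3, 1), dimred = dr)
    got <- predict_speller(ens, te, j = 3)
    want <- naive_ensemble_predict(tr, te, K = 3, dimred = dr,
                                   truth_matrix = s$letter_matrix, j = 3)
    expect_identical(got, want, info = dr)
  }
})

test_that("positive rescaling of all weight vectors never changes decisions", {
  s <- tiny_session(n_letters = 7, seed = 5)
  f <- preprocess_session(s)
  tr <- subset_features(f, letters = 1:5)
  te <- subset_features(f, letters = 6:7)
  for (dr in c("none", "stepwise", "pca")) {
    m <- train_ensemble(tr, partition_spec(5, 3), dimred = dr)
    m2 <- m
    for (k in seq_along(m2$learners))
      m2$learners[[k]]$lda$weights <- 4.21 * m2$learners[[k]]$lda$weights
    expect_identical(predict_speller(m, te, 3), predict_speller(m2, te, 3),
                     info = dr)
  }
})

test_that("a zero-feature stepwise learner contributes nothing, with a warning", {
  s <- tiny_session(n_letters = 5, seed = 17,
                    model = p300_model(p300_amplitude = 0, vep_amplitude = 0))
  f <- preprocess_session(s)
  # on pure noise nothing can pass a near-zero entry threshold
  expect_warning(
    m <- train_ensemble(f, partition_spec(1, 1), dimred = "stepwise",
                        p_in = 1e-12),
    "zero features")
  S <- score_letter(m, subset_features(f, letters = 1), j = 3)
  expect_true(all(S == 0))
  # the all-zero score table falls back to the deterministic tie-break
  expect_identical(predict_letter(S, s$letter_matrix), s$letter_matrix[1, 1])
})

test_that("scoring validates sequence completeness and availability", {
  s <- tiny_session(n_letters = 4)
  f <- preprocess_session(s)
  m <- train_ensemble(subset_features(f, letters = 1:3), partition_spec(1, 1),
                      dimred = "none")
  l4 <- subset_features(f, letters = 4)
  expect_error(score_letter(m, l4, j = 99), "exceeds")
  broken <- l4
  keep <- !(broken$labels$sequence == 1 & broken$labels$code == 5)
  broken <- subset_features(broken, rows = which(keep))
  expect_error(score_letter(m, broken, j = 1), "incomplete")
  expect_error(score_letter(m, f, j = 1), "exactly one letter")
})
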