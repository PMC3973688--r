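# Small shared fixtures and independent oracles, built in code.

# compact session: 4 channels at 64 Hz, 3 sequences/letter -- keeps epochs and
# feature dimension small for structural tests
tiny_config <- function(n_sequences = 3) {
  speller_config(fs = 64, n_channels = 4, n_sequences = n_sequences)
}

tiny_session <- function(n_letters = 8, seed = 3, model = p300_model(noise_sigma = 8),
                         config = tiny_config()) {
  simulate_session(config, model, n_letters = n_letters, seed = seed)
}

# literal exhaustive application of the stepwise add/remove rules, re-fitting
# every candidate model from scratch with lm()/anova() -- independent of the
# package's residual-update implementation
brute_stepwise <- function(X, y, p_in = 0.10, p_out = 0.15) {
  sel <- integer(0)
  D <- ncol(X)
  fit_lm <- function(cols) {
    if (length(cols) == 0L) lm(y ~ 1, data = data.frame(y = y))
    else lm(y ~ ., data = data.frame(y = y, X[, cols, drop = FALSE]))
  }
  repeat {
    changed <- FALSE
    repeat { # forward
      cand <- setdiff(seq_len(D), sel)
      if (!length(cand) || nrow(X) - length(sel) - 2 <= 0) break
      f_red <- fit_lm(sel)
      ps <- vapply(cand, function(j)
        anova(f_red, fit_lm(c(sel, j)))[2, "Pr(>F)"], numeric(1))
      j <- cand[which.min(ps)]
      if (min(ps) < p_in) { sel <- c(sel, j); changed <- TRUE } else break
    }
    repeat { # backward
      if (!length(sel)) break
      f_full <- fit_lm(sel)
      ps <- vapply(seq_along(sel), function(k)
        anova(fit_lm(sel[-k]), f_full)[2, "Pr(>F)"], numeric(1))
      k <- which.max(ps)
      if (ps[k] > p_out) { sel <- sel[-k]; changed <- TRUE } else break
    }
    if (!changed) break
  }
  as.integer(sel)
}

# SVD-based Moore-Penrose pseudo-inverse, written out independently of MASS
svd_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# independently coded naive-partitioning ensemble: splits the training
# letters into K contiguous groups by hand, fits its own LDA per group
# (explicit covariance / pseudo-inverse), and sums scores with plain loops
naive_ensemble_predict <- function(train_fs, test_fs, K, dimred, truth_matrix,
                                   j, p_in = 0.10, p_out = 0.15) {
  letters <- unique(train_fs$labels$letter)
  L <- length(letters)
  sizes <- rep(L %/% K, K)
  if (L %% K) sizes[seq_len(L %% K)] <- sizes[seq_len(L %% K)] + 1L
  grp <- rep(seq_len(K), times = sizes)
  learners <- lapply(seq_len(K), function(k) {
    rows <- train_fs$labels$letter %in% letters[grp == k]
    Xk <- train_fs$X[rows, , drop = FALSE]
    yk <- train_fs$labels$is_target[rows]
    tr <- switch(dimred,
      none = NULL,
      stepwise = stepwise_select(Xk, ifelse(yk, 1, -1), p_in, p_out),
      pca = pca_fit(Xk, max(1L, min(nrow(Xk) - 1L, ncol(Xk) %/% 4L))))
    Zk <- switch(dimred,
      none = Xk,
      stepwise = Xk[, tr$selected, drop = FALSE],
      pca = pca_transform(tr, Xk))
    if (ncol(Zk) == 0L) return(list(tr = tr, w = numeric(0)))
    S <- stats::cov(Zk)
    d <- colMeans(Zk[yk, , drop = FALSE]) - colMeans(Zk[!yk, , drop = FALSE])
    w <- as.vector(svd_pinv(S) %*% d)
    list(tr = tr, w = w)
  })
  test_letters <- unique(test_fs$labels$letter)
  vapply(test_letters, function(l) {
    rows <- which(test_fs$labels$letter == l & test_fs$labels$sequence <= j)
    S12 <- numeric(12)
    for (r in rows) {
      x <- test_fs$X[r, , drop = FALSE]
      for (k in seq_len(K)) {
        if (length(learners[[k]]$w) == 0L) next
        tr <- learners[[k]]$tr
        z <- switch(dimred,
          none = x,
          stepwise = x[, tr$selected, drop = FALSE],
          pca = pca_transform(tr, x))
        S12[test_fs$labels$code[r]] <- S12[test_fs$labels$code[r]] +
          sum(z * learners[[k]]$w)
      }
    }
    col <- which.max(S12[1:6]); row <- which.max(S12[7:12])
    truth_matrix[row, col]
  }, character(1))
}
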