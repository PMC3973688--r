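#' Train one LDA weak learner
#'
#' Fits the discriminant weight vector `w` solving `Sigma w = mu_t - mu_n`,
#' where by default `Sigma` is the *total* covariance matrix pooled over all
#' target and non-target rows of the partition (ignoring class) and
#' `mu_t`/`mu_n` are the class means. When `Sigma` is numerically singular
#' (reciprocal condition number below 1e-12) the Moore-Penrose pseudo-inverse
#' is used, giving the minimal-norm least-squares solution.
#'
#' @param X n x d (possibly dimension-reduced) feature matrix.
#' @param y Class labels: logical `is_target`, or numeric with positive =
#'   target.
#' @param inverse_method "auto" (solve, falling back to pseudo-inverse when
#'   singular), "solve", "pinv", or "ridge".
#' @param ridge Ridge coefficient (relative to the mean diagonal of `Sigma`)
#'   for `inverse_method = "ridge"`.
#' @param covariance "total" pools all rows ignoring class; "within" pools
#'   the per-class covariances (sensitivity option).
#' @return An object of class `lda_fit`: `weights`, `mean_target`,
#'   `mean_nontarget`, `covariance` (the matrix), `inverse_method`.
#' @export
lda_fit <- function(X, y, inverse_method = c("auto", "solve", "pinv", "ridge"),
                    ridge = 1e-6, covariance = c("total", "within")) {
  inverse_method <- match.arg(inverse_method)
  covariance <- match.arg(covariance)
  X <- as.matrix(X)
  tgt <- if (is.logical(y)) y else y > 0
  if (!any(tgt) || all(tgt))
    stop("both target and non-target epochs are required to fit a weak learner")
  if (ncol(X) == 0L)
    return(structure(list(weights = numeric(0), mean_target = numeric(0),
                          mean_nontarget = numeric(0),
                          covariance = matrix(0, 0, 0),
                          inverse_method = inverse_method),
                     class = "lda_fit"))
  mu_t <- colMeans(X[tgt, , drop = FALSE])
  mu_n <- colMeans(X[!tgt, , drop = FALSE])
  Sigma <- switch(covariance,
    total = stats::cov(X),
    within = {
      n1 <- sum(tgt); n0 <- sum(!tgt)
      ((n1 - 1) * stats::cov(X[tgt, , drop = FALSE]) +
       (n0 - 1) * stats::cov(X[!tgt, , drop = FALSE])) / (n1 + n0 - 2)
    })
  d <- mu_t - mu_n
  w <- switch(inverse_method,
    solve = solve(Sigma, d),
    pinv = as.vector(MASS::ginv(Sigma) %*% d),
    ridge = solve(Sigma + ridge * mean(diag(Sigma)) * diag(ncol(X)), d),
    auto = {
      rc <- tryCatch(rcond(Sigma), error = function(e) 0)
      if (is.finite(rc) && rc > 1e-12)
        tryCatch(solve(Sigma, d),
                 error = function(e) as.vector(MASS::ginv(Sigma) %*% d))
      else as.vector(MASS::ginv(Sigma) %*% d)
    })
  structure(list(weights = as.vector(w), mean_target = mu_t,
                 mean_nontarget = mu_n, covariance = Sigma,
                 inverse_method = inverse_method),
            class = "lda_fit")
}

#' Train an overlapped-partitioning LDA ensemble
#'
#' The time-ordered training epochs are cut into K letter-aligned blocks,
#' expanded into K circularly overlapped partitions of B blocks each, and a
#' dimension-reduction transform plus an LDA weight vector are fitted on each
#' partition. Training data are used only here; scoring never refits.
#'
#' A stepwise transform that selects zero features makes its weak learner
#' contribute nothing to the scores (with a warning).
#'
#' @param train A `feature_set` of time-ordered training epochs with letter
#'   labels.
#' @param spec A [partition_spec()].
#' @param dimred "stepwise", "pca" or "none".
#' @param inverse_method Passed to [lda_fit()].
#' @param covariance Passed to [lda_fit()].
#' @param ... Further arguments to [fit_dimred()] (`p_in`, `p_out`,
#'   `max_features`, `n_pcs`).
#' @return An object of class `p300_ensemble`: `learners` (K lists with
#'   `transform` and `lda`), `spec`, `dimred`, `D`.
#' @export
#' @examples
#' s <- simulate_session(n_letters = 5, seed = 1)
#' f <- preprocess_session(s)
#' m <- train_ensemble(f, partition_spec(K = 5, B = 3), dimred = "stepwise")
train_ensemble <- function(train, spec, dimred = c("none", "stepwise", "pca"),
                           inverse_method = "auto", covariance = "total", ...) {
  dimred <- match.arg(dimred)
  stopifnot(inherits(train, "feature_set"), inherits(spec, "partition_spec"))
  blocks <- make_blocks(train$labels$letter, spec$K)
  parts <- overlapped_partitions(blocks, spec$B)
  learners <- lapply(seq_along(parts), function(k) {
    idx <- parts[[k]]
    Xk <- train$X[idx, , drop = FALSE]
    yk <- train$labels$is_target[idx]
    if (!any(yk) || all(yk))
      stop(sprintf("partition %d does not contain both classes", k))
    tr <- fit_dimred(Xk, ifelse(yk, 1, -1), condition = dimred, ...)
    Zk <- transform_dimred(tr, Xk)
    if (ncol(Zk) == 0L)
      warning(sprintf("partition %d: stepwise selected zero features; this weak learner contributes nothing", k))
    list(transform = tr,
         lda = lda_fit(Zk, yk, inverse_method = inverse_method,
                       covariance = covariance))
  })
  structure(list(learners = learners, spec = spec, dimred = dimred,
                 D = ncol(train$X)),
            class = "p300_ensemble")
}

# per-epoch score summed over all weak learners:
# s(x) = sum_k w_k . T_k(x)
epoch_scores <- function(model, X) {
  s <- numeric(nrow(X))
  for (ln in model$learners) {
    if (length(ln$lda$weights) == 0L) next
    s <- s + as.vector(transform_dimred(ln$transform, X) %*% ln$lda$weights)
  }
  s
}

# validate that a one-letter feature_set has complete sequences 1..j
check_sequences <- function(labels, j) {
  if (length(unique(labels$letter)) != 1L)
    stop("score_letter expects the epochs of exactly one letter")
  avail <- sort(unique(labels$sequence))
  if (j > length(avail))
    stop(sprintf("j = %d exceeds the %d available sequences", j, length(avail)))
  for (s in avail[seq_len(j)]) {
    cds <- sort(labels$code[labels$sequence == s])
    if (!identical(as.integer(cds), 1:12))
      stop(sprintf("sequence %d is incomplete (codes 1..12 must each appear once)", s))
  }
  avail[seq_len(j)]
}

#' Score the 12 intensification codes for one letter
#'
#' For each code i, the score is the sum over weak learners k and the first j
#' recorded sequences s of `w_k . x_{i,s,k}`, where `x_{i,s,k}` is the epoch
#' of (code i, sequence s) transformed by partition k's dimension-reduction
#' model. Scores are decision-invariant under positive rescaling of all
#' weight vectors.
#'
#' @param model A [train_ensemble()] model.
#' @param fset A `feature_set` containing one letter's epochs with complete
#'   sequences.
#' @param j Number of sequences to use (the first j in recorded order).
#' @return Named numeric vector of 12 scores (names "1".."12").
#' @export
score_letter <- function(model, fset, j = max(fset$labels$sequence)) {
  stopifnot(inherits(model, "p300_ensemble"), inherits(fset, "feature_set"))
  use_seq <- check_sequences(fset$labels, j)
  keep <- fset$labels$sequence %in% use_seq
  s_ep <- epoch_scores(model, fset$X[keep, , drop = FALSE])
  codes <- fset$labels$code[keep]
  S <- vapply(1:12, function(i) sum(s_ep[codes == i]), numeric(1))
  names(S) <- as.character(1:12)
  S
}

#' Decide a letter from 12 code scores
#'
#' The predicted column is the argmax over codes 1--6 and the predicted row
#' the argmax over codes 7--12; ties break toward the lowest code. The
#' (column, row) pair indexes the symbol in the matrix, so adding a constant
#' to all 12 scores never changes the decision.
#'
#' @param scores Numeric vector of 12 finite scores (codes 1..12).
#' @param letter_matrix 6x6 character matrix.
#' @return The predicted symbol.
#' @export
predict_letter <- function(scores, letter_matrix = default_letter_matrix()) {
  stopifnot(length(scores) == 12, all(is.finite(scores)))
  col <- which.max(scores[1:6])
  row <- which.max(scores[7:12])
  letter_matrix[row, col]
}

#' Predict every letter in a feature set
#'
#' @param model A [train_ensemble()] model.
#' @param fset A `feature_set` (any number of letters, complete sequences).
#' @param j Sequences per letter to use.
#' @param letter_matrix 6x6 character matrix for the decision.
#' @return Character vector of predicted symbols, one per letter, in the
#'   recorded letter order.
#' @export
predict_speller <- function(model, fset, j = max(fset$labels$sequence),
                            letter_matrix = default_letter_matrix()) {
  letters <- unique(fset$labels$letter)
  vapply(letters, function(l) {
    predict_letter(score_letter(model, subset_features(fset, letters = l), j),
                   letter_matrix)
  }, character(1))
}

#' @export
print.p300_ensemble <- function(x, ...) {
  cat(sprintf("<p300_ensemble> K = %d, B = %d, dimred = %s, D = %d\n",
              x$spec$K, x$spec$B, x$dimred, x$D))
  invisible(x)
}
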