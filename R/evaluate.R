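#' Letter classification accuracy
#'
#' @param predictions Character vector of predicted symbols.
#' @param truths Character vector of true symbols (same length).
#' @return Accuracy in percent, `100 * matches / letters`.
#' @export
letter_accuracy <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (length(predictions) == 0L) stop("no letters to score")
  100 * mean(predictions == truths)
}

# scores for one letter at every j in j_range at once (cumulative over
# sequences), avoiding a rescore per j; returns |j_range| x 12 matrix
letter_scores_by_j <- function(model, fset_letter, j_range) {
  jmax <- max(j_range)
  use_seq <- check_sequences(fset_letter$labels, jmax)
  keep <- fset_letter$labels$sequence %in% use_seq
  s_ep <- epoch_scores(model, fset_letter$X[keep, , drop = FALSE])
  codes <- fset_letter$labels$code[keep]
  seqs <- fset_letter$labels$sequence[keep]
  seq_rank <- match(seqs, use_seq) # 1..jmax in recorded order
  per_seq <- matrix(0, jmax, 12)   # score mass contributed by each sequence
  for (i in seq_along(s_ep))
    per_seq[seq_rank[i], codes[i]] <- per_seq[seq_rank[i], codes[i]] + s_ep[i]
  cum <- apply(per_seq, 2, cumsum)
  if (jmax == 1L) cum <- matrix(cum, 1, 12)
  cum[j_range, , drop = FALSE]
}

#' Run a p/q cross-validation experiment over a condition grid
#'
#' For every fold of a [pq_splits()] design and every `(K, B, dimred)`
#' condition, an ensemble is trained on the fold's training letters and every
#' test letter is predicted at every number of sequences in `j_range`
#' (scoring is truncated at j; one model per fold, never retrained per j).
#' The same folds are reused across conditions, so comparisons are paired.
#' Correct predictions are accumulated over folds into `z` out of `Z` test
#' letters.
#'
#' @param fset A `feature_set` of a whole multi-letter recording, epochs in
#'   recorded time order.
#' @param truths Character vector: the true symbol of each letter, indexed by
#'   the letter labels in `fset` (e.g. `session$targets$symbol`).
#' @param conditions data.frame with columns `K`, `B`, `dimred`.
#' @param p,q p/q cross-validation parameters (see [pq_splits()]).
#' @param j_range Sequence counts to evaluate (default 1..15).
#' @param letter_matrix 6x6 decision matrix.
#' @param ... Passed to [train_ensemble()] (e.g. `p_in`, `n_pcs`).
#' @return data.frame with one row per (condition, j): `K`, `B`, `dimred`,
#'   `j`, `z` (correct letters), `Z` (total test letters), `accuracy` (%).
#' @export
#' @examples
#' \donttest{
#' s <- simulate_session(n_letters = 10, seed = 7)
#' f <- preprocess_session(s)
#' grid <- data.frame(K = 5, B = c(1, 3, 5), dimred = "stepwise")
#' run_experiment(f, s$targets$symbol, grid, p = 1, q = 2, j_range = c(5, 15))
#' }
run_experiment <- function(fset, truths, conditions, p, q,
                           j_range = 1:15,
                           letter_matrix = default_letter_matrix(), ...) {
  stopifnot(inherits(fset, "feature_set"),
            all(c("K", "B", "dimred") %in% names(conditions)))
  letters <- unique(fset$labels$letter)
  splits <- pq_splits(letters, p, q)
  nc <- nrow(conditions)
  z <- matrix(0L, nc, length(j_range))
  for (fold in splits$folds) {
    train_fs <- subset_features(fset, letters = fold$train)
    for (ci in seq_len(nc)) {
      model <- train_ensemble(train_fs,
                              partition_spec(conditions$K[ci], conditions$B[ci]),
                              dimred = as.character(conditions$dimred[ci]), ...)
      for (l in fold$test) {
        sc <- letter_scores_by_j(model, subset_features(fset, letters = l),
                                 j_range)
        pred <- apply(sc, 1, predict_letter, letter_matrix = letter_matrix)
        z[ci, ] <- z[ci, ] + as.integer(pred == truths[l])
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nc), function(ci)
    data.frame(K = conditions$K[ci], B = conditions$B[ci],
               dimred = as.character(conditions$dimred[ci]),
               j = j_range, z = z[ci, ], Z = splits$Z,
               stringsAsFactors = FALSE)))
  out$accuracy <- 100 * out$z / out$Z
  out
}

#' Wolpaw information transfer rate
#'
#' Bits per selection `log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1))`
#' (with `0 log2 0 = 0`), optionally scaled to bits per minute by the
#' selection time `T` in seconds. At chance (`P = 1/N`) the rate is zero; at
#' `P = 1` it is `log2(N)`.
#'
#' @param P Accuracy as a proportion in [0, 1].
#' @param N Number of alternatives (36 for the 6x6 speller).
#' @param T_select Seconds per selection; when `NA` (default) only bits per
#'   selection are meaningful.
#' @return Named numeric vector `c(bits_per_selection, bits_per_min)`.
#' @export
#' @examples
#' wolpaw_itr(1, 36)          # log2(36) = 5.17 bits/selection
#' wolpaw_itr(0.714, 36)      # ~2.84 bits/selection
wolpaw_itr <- function(P, N = 36, T_select = NA) {
  stopifnot(P >= 0, P <= 1, N >= 2, is.na(T_select) || T_select > 0)
  bits <- log2(N)
  if (P > 0) bits <- bits + P * log2(P)
  if (P < 1) bits <- bits + (1 - P) * log2((1 - P) / (N - 1))
  c(bits_per_selection = bits,
    bits_per_min = if (is.na(T_select)) NA_real_ else 60 / T_select * bits)
}
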