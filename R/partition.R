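#' Overlapped-partitioning specification
#'
#' `K` is both the number of blocks the time-ordered training data are cut
#' into and the number of weak learners; `B` is the degree of overlap, i.e.
#' how many consecutive blocks (on a circular arrangement) form each
#' partition. `B = 1` is naive (disjoint) partitioning; `B = K` makes every
#' partition a copy of the full training set, collapsing the ensemble to a
#' single classifier.
#'
#' @param K Number of blocks / weak learners (>= 1).
#' @param B Degree of overlap, 1 <= B <= K.
#' @return An object of class `partition_spec`.
#' @export
partition_spec <- function(K, B) {
  K <- as.integer(K); B <- as.integer(B)
  if (K < 1L) stop("K must be >= 1")
  if (B < 1L || B > K) stop("B must satisfy 1 <= B <= K")
  structure(list(K = K, B = B), class = "partition_spec")
}

#' Cut time-ordered training epochs into K contiguous blocks
#'
#' Blocks are aligned on letter boundaries: the letters (in recorded order)
#' are distributed over K contiguous blocks as evenly as possible (block
#' letter counts differ by at most 1, earlier blocks take the remainder).
#' Epoch-level splitting that would cut through a letter is refused.
#'
#' @param letter Integer vector: the letter index of every training epoch, in
#'   recorded time order (e.g. `fset$labels$letter`).
#' @param K Number of blocks; must not exceed the number of letters.
#' @return List of K integer vectors of epoch indices (time-ordered,
#'   disjoint, covering all epochs).
#' @export
make_blocks <- function(letter, K) {
  K <- as.integer(K)
  letters <- unique(letter) # recorded order
  L <- length(letters)
  if (K > L)
    stop(sprintf("K = %d exceeds the number of training letters (%d)", K, L))
  sizes <- rep(L %/% K, K)
  if (L %% K) sizes[seq_len(L %% K)] <- sizes[seq_len(L %% K)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(K), function(k)
    which(letter %in% letters[starts[k]:ends[k]]))
}

#' Form K overlapped partitions from K blocks
#'
#' Assuming the blocks are aligned around a circle, partition k is the union
#' of blocks k, k+1, ..., k+B-1 (with wraparound). Every block appears in
#' exactly B partitions.
#'
#' @param blocks List of K index vectors from [make_blocks()].
#' @param B Degree of overlap, 1 <= B <= K.
#' @return List of K integer vectors (partition k in block order).
#' @export
#' @examples
#' b <- make_blocks(rep(1:5, each = 2), K = 5)
#' p <- overlapped_partitions(b, B = 3) # partition 4 = blocks 4, 5, 1
overlapped_partitions <- function(blocks, B) {
  K <- length(blocks)
  B <- as.integer(B)
  if (B < 1L || B > K) stop("B must satisfy 1 <= B <= K")
  lapply(seq_len(K), function(k)
    unlist(blocks[(k - 1L + seq_len(B) - 1L) %% K + 1L], use.names = FALSE))
}

#' Per-partition training size under equal blocks
#'
#' With equal block sizes each partition holds `total_epochs * B / K` epochs
#' (e.g. 900 epochs, K = 5, B = 3 -> 540 per weak learner). For unequal
#' blocks take the exact sizes from [overlapped_partitions()] instead.
#'
#' @param total_epochs Total training epochs.
#' @param K Number of blocks.
#' @param B Degree of overlap.
#' @return Numeric scalar `total_epochs * B / K`.
#' @export
partition_sizes <- function(total_epochs, K, B) {
  stopifnot(1 <= B, B <= K)
  total_epochs * B / K
}

#' p/q cross-validation splits over letters
#'
#' The letters (in recorded order) are divided into q equal, time-ordered
#' groups arranged circularly. Fold i (i = 1..q) trains on the p consecutive
#' groups starting at group i and tests on the single group that follows
#' them. Each group -- hence each letter -- is tested exactly once across the
#' q folds; `p = q - 1` reproduces conventional q-fold cross-validation,
#' while small p (e.g. 1/10) evaluates classifiers under scarce training
#' data without shrinking the test set.
#'
#' @param letters Vector of letter identifiers in recorded order; its length
#'   must be divisible by q.
#' @param p Number of training groups per fold, 1 <= p <= q - 1.
#' @param q Number of folds / groups.
#' @return An object of class `cv_splits`: `p`, `q`, `Z` (total test
#'   letters), and `folds`, a list of q `list(train =, test =)` letter-id
#'   vectors.
#' @export
#' @examples
#' s <- pq_splits(1:50, p = 1, q = 10) # each fold: 5 training letters
pq_splits <- function(letters, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  L <- length(letters)
  if (q < 2L) stop("q must be >= 2")
  if (L %% q != 0L)
    stop(sprintf("number of letters (%d) is not divisible by q = %d", L, q))
  if (p < 1L || p > q - 1L) stop("p must satisfy 1 <= p <= q - 1")
  groups <- split(letters, rep(seq_len(q), each = L %/% q))
  folds <- lapply(seq_len(q), function(i) {
    tr <- (i - 1L + seq_len(p) - 1L) %% q + 1L
    te <- (i - 1L + p) %% q + 1L
    list(train = unlist(groups[tr], use.names = FALSE),
         test = unlist(groups[te], use.names = FALSE))
  })
  structure(list(p = p, q = q, Z = L, folds = folds), class = "cv_splits")
}
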