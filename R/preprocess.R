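#' ERP preprocessing configuration
#'
#' Parameters of the fixed pipeline trim -> baseline -> smooth -> decimate ->
#' vectorize. Epoch length is `floor(epoch_ms * fs / 1000)` samples from each
#' flash onset; the baseline window is the `floor(baseline_ms * fs / 1000)`
#' samples immediately before the onset. Smoothing is a trailing (causal)
#' moving average of `ma_window` samples with the window truncated at the
#' epoch start; decimation keeps every `decim`-th smoothed sample starting
#' at the first.
#'
#' With the defaults (700 ms epoch, 100 ms baseline, window 3, stride 3) an
#' 8-channel 128 Hz recording yields 89-sample epochs, 30 retained samples and
#' a 240-dimensional feature vector; with `ma_window = 18, decim = 12` a
#' 64-channel 240 Hz recording yields 168-sample epochs, 14 retained samples
#' and 896 dimensions.
#'
#' @param epoch_ms Epoch length after onset (ms).
#' @param baseline_ms Pre-onset baseline window (ms).
#' @param ma_window Moving-average width in samples (>= 1).
#' @param decim Decimation stride in samples (>= 1).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(epoch_ms = 700, baseline_ms = 100,
                           ma_window = 3, decim = 3) {
  stopifnot(epoch_ms > 0, baseline_ms > 0, ma_window >= 1, decim >= 1)
  structure(list(epoch_ms = epoch_ms, baseline_ms = baseline_ms,
                 ma_window = as.integer(ma_window), decim = as.integer(decim)),
            class = "preproc_config")
}

#' Extract per-intensification ERP epochs
#'
#' Trims the continuous signal from each flash onset to `epoch_ms`, and keeps
#' the `baseline_ms` pre-stimulus window of every epoch for baseline
#' correction.
#'
#' @param session A `speller_session` (or any list with `signal`, `fs`,
#'   `events` in the same layout).
#' @param cfg A [preproc_config()].
#' @return An object of class `epoch_set`: `epochs` (events x channels x
#'   samples array, uV), `baselines` (events x channels x baseline samples),
#'   `labels` (data.frame `letter`, `sequence`, `code`, `is_target`), `fs`.
#' @export
extract_epochs <- function(session, cfg = preproc_config()) {
  sig <- session$signal
  fs <- session$fs
  ev <- session$events
  n_ep <- as.integer(floor(cfg$epoch_ms * fs / 1000))
  n_bl <- as.integer(floor(cfg$baseline_ms * fs / 1000))
  n <- nrow(sig); C <- ncol(sig); nE <- nrow(ev)
  bad <- which(ev$onset - n_bl < 1L | ev$onset + n_ep - 1L > n)
  if (length(bad))
    stop(sprintf("event %d (onset sample %d) is too close to a signal boundary for a %d-sample epoch with a %d-sample baseline",
                 bad[1], ev$onset[bad[1]], n_ep, n_bl))
  idx <- outer(ev$onset, 0:(n_ep - 1L), "+")
  idx_bl <- outer(ev$onset, -(n_bl:1), "+")
  epochs <- array(0, c(nE, C, n_ep))
  baselines <- array(0, c(nE, C, n_bl))
  for (ch in seq_len(C)) {
    epochs[, ch, ] <- sig[, ch][idx]
    baselines[, ch, ] <- sig[, ch][idx_bl]
  }
  structure(list(epochs = epochs, baselines = baselines,
                 labels = ev[, c("letter", "sequence", "code", "is_target")],
                 fs = fs),
            class = "epoch_set")
}

#' Subtract the pre-stimulus baseline
#'
#' For every epoch and channel, the mean of that channel's baseline window is
#' subtracted from every sample of the epoch. Adding a constant offset to a
#' channel's raw signal therefore leaves the corrected epoch unchanged.
#'
#' @param es An [extract_epochs()] `epoch_set`.
#' @return The `epoch_set` with corrected epochs.
#' @export
baseline_correct <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(es$baselines)) stop("epoch_set carries no baseline windows")
  stopifnot(dim(es$baselines)[1:2] == dim(es$epochs)[1:2])
  bm <- rowMeans(es$baselines, dims = 2) # events x channels
  es$epochs <- es$epochs - as.vector(bm) # recycled over the sample dimension
  es
}

# trailing moving average along columns of a (rows x samples) matrix,
# window truncated at the left edge so output length equals input length
trailing_ma <- function(M, w) {
  S <- ncol(M)
  if (w == 1L) return(M)
  cs <- M
  for (s in 2:S) cs[, s] <- cs[, s - 1L] + M[, s]
  out <- M
  for (s in seq_len(S)) {
    if (s <= w) out[, s] <- cs[, s] / s
    else out[, s] <- (cs[, s] - cs[, s - w]) / w
  }
  out
}

#' Smooth and decimate epochs
#'
#' Per channel: trailing moving average of width `ma_window` (truncated at the
#' epoch start, so output length equals input length), then retain samples at
#' 0-based indices `0, decim, 2 * decim, ...`.
#'
#' @param es An `epoch_set`.
#' @param ma_window Moving-average width in samples.
#' @param decim Decimation stride.
#' @return The `epoch_set` with smoothed, decimated epochs (baselines are
#'   dropped: they have served their purpose).
#' @export
smooth_downsample <- function(es, ma_window = 3, decim = 3) {
  stopifnot(inherits(es, "epoch_set"), ma_window >= 1, decim >= 1)
  d <- dim(es$epochs)
  if (ma_window > d[3])
    stop(sprintf("ma_window (%d) exceeds the epoch length (%d samples)",
                 ma_window, d[3]))
  M <- matrix(es$epochs, nrow = d[1] * d[2], ncol = d[3])
  M <- trailing_ma(M, as.integer(ma_window))
  keep <- seq(1L, d[3], by = as.integer(decim))
  es$epochs <- array(M[, keep, drop = FALSE], c(d[1], d[2], length(keep)))
  es$baselines <- NULL
  es
}

#' Vectorize epochs into feature rows
#'
#' Channel-major concatenation: channel 1's samples, then channel 2's, and so
#' on; the feature dimension is `channels * samples`. Labels are carried
#' through unchanged.
#'
#' @param es An `epoch_set`.
#' @return An object of class `feature_set`: `X` (events x D matrix), `labels`,
#'   `n_channels`, `n_samples`, `fs`.
#' @export
vectorize_epochs <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  X <- t(matrix(aperm(es$epochs, c(3, 2, 1)), nrow = d[3] * d[2], ncol = d[1]))
  structure(list(X = X, labels = es$labels,
                 n_channels = d[2], n_samples = d[3], fs = es$fs),
            class = "feature_set")
}

#' Undo vectorization
#'
#' Reshapes a `feature_set` back into an epochs x channels x samples array.
#'
#' @param fset A [vectorize_epochs()] `feature_set`.
#' @return An `epoch_set` (without baselines).
#' @export
devectorize_epochs <- function(fset) {
  stopifnot(inherits(fset, "feature_set"))
  C <- fset$n_channels; S <- fset$n_samples; nE <- nrow(fset$X)
  e <- aperm(array(t(fset$X), c(S, C, nE)), c(3, 2, 1))
  structure(list(epochs = e, baselines = NULL, labels = fset$labels,
                 fs = fset$fs), class = "epoch_set")
}

#' Full preprocessing pipeline
#'
#' Fixed order: trim -> baseline-correct -> smooth -> decimate -> vectorize.
#'
#' @param session A `speller_session`.
#' @param cfg A [preproc_config()].
#' @return A `feature_set`.
#' @export
#' @examples
#' s <- simulate_session(n_letters = 1, seed = 1)
#' f <- preprocess_session(s)
#' dim(f$X) # 180 epochs x 240 features
preprocess_session <- function(session, cfg = preproc_config()) {
  es <- extract_epochs(session, cfg)
  es <- baseline_correct(es)
  es <- smooth_downsample(es, cfg$ma_window, cfg$decim)
  vectorize_epochs(es)
}

#' Subset a feature set by letters or rows
#'
#' Restricts a `feature_set` to the epochs of the given letters (or to
#' arbitrary row indices), e.g. to carve out the training and test letters
#' of a cross-validation fold.
#'
#' @param fset A `feature_set`.
#' @param letters Letter indices to keep (matched against
#'   `fset$labels$letter`).
#' @param rows Alternatively, explicit epoch row indices.
#' @return The restricted `feature_set`.
#' @export
subset_features <- function(fset, letters = NULL, rows = NULL) {
  if (is.null(rows)) rows <- which(fset$labels$letter %in% letters)
  fset$X <- fset$X[rows, , drop = FALSE]
  fset$labels <- fset$labels[rows, , drop = FALSE]
  fset
}
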