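#' ERP generative model for the speller simulator
#'
#' Parameters of the synthetic EEG: a P300-like positive deflection added to
#' target epochs, a small visual evoked response common to every flash,
#' stationary AR(1) background noise, and an optional linear amplitude drift
#' across letters (nonstationarity, e.g. habituation).
#'
#' All amplitudes are in microvolts. The P300 bump is a half-cosine (Hann)
#' window of length `p300_width_ms` peaking `p300_latency_ms` after the flash
#' onset, with per-event Gaussian latency jitter. Per-channel background noise
#' is AR(1) with marginal standard deviation `noise_sigma`; channels are
#' independent by default. Output is fully determined by `(schedule, model,
#' config)` including `seed`.
#'
#' @param p300_amplitude Peak P300 amplitude (uV), >= 0.
#' @param p300_latency_ms P300 peak latency after flash onset (ms).
#' @param latency_jitter_ms SD of per-event Gaussian latency jitter (ms).
#' @param p300_width_ms Full width of the half-cosine bump (ms).
#' @param topography Per-channel weights of the P300 (recycled/validated
#'   against the session's channel count at synthesis). `NULL` selects a
#'   posterior-weighted profile for the standard 8-channel montage, or all 1s.
#' @param vep_amplitude Amplitude of the common flash response (uV), >= 0.
#' @param vep_latency_ms Latency of the common flash response (ms).
#' @param vep_width_ms Width of the common flash response (ms).
#' @param noise_sigma Marginal SD of the background noise (uV).
#' @param noise_ar1 AR(1) coefficient in [0, 1).
#' @param drift_rate Relative P300 amplitude change per letter; letter l
#'   (1-based) is scaled by `1 + drift_rate * (l - 1)`. Default 0 (stationary).
#' @param seed Integer RNG seed; fully determines the synthesized signal.
#'
#' @return An object of class `p300_model`.
#' @export
p300_model <- function(p300_amplitude = 5, p300_latency_ms = 300,
                       latency_jitter_ms = 30, p300_width_ms = 300,
                       topography = NULL,
                       vep_amplitude = 1, vep_latency_ms = 120,
                       vep_width_ms = 100,
                       noise_sigma = 10, noise_ar1 = 0.9,
                       drift_rate = 0, seed = 1L) {
  stopifnot(p300_amplitude >= 0, vep_amplitude >= 0, noise_sigma >= 0,
            noise_ar1 >= 0, noise_ar1 < 1, p300_width_ms > 0, vep_width_ms > 0,
            latency_jitter_ms >= 0, is.finite(drift_rate))
  if (!is.null(topography) && !all(is.finite(topography)))
    stop("topography weights must be finite")
  structure(list(p300_amplitude = p300_amplitude,
                 p300_latency_ms = p300_latency_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 p300_width_ms = p300_width_ms, topography = topography,
                 vep_amplitude = vep_amplitude, vep_latency_ms = vep_latency_ms,
                 vep_width_ms = vep_width_ms, noise_sigma = noise_sigma,
                 noise_ar1 = noise_ar1, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "p300_model")
}

#' Stimulus schedule for a speller session
#'
#' Lays out the row/column oddball protocol: for each target letter,
#' `n_sequences` sequences, each a uniform random permutation of the 12
#' intensification codes, with consecutive onsets separated by the SOA
#' (`round((flash_ms + blank_ms) * fs / 1000)` samples). Each letter block is
#' preceded by a `target_ms` cue period and followed by a `feedback_ms` gap,
#' so every onset has room for a pre-stimulus baseline and a 700 ms epoch.
#' Exactly 2 of the 12 codes per sequence are target codes (the target's row
#' and column).
#'
#' @param config A [speller_config()].
#' @param letters Character vector of target symbols, one per letter to spell;
#'   all must occur in the configured matrix.
#' @param seed Integer RNG seed for the permutations.
#'
#' @return An object of class `stimulus_schedule`: a list with
#'   `events` (data.frame: `onset` 1-based sample, `code` 1--12,
#'   `sequence` 1-based within letter, `letter` 1-based, `is_target`),
#'   `targets` (data.frame: `letter`, `symbol`, `column_code`, `row_code`),
#'   `n_samples` (session length), and `config`.
#' @export
#' @examples
#' sch <- make_schedule(speller_config(), "A", seed = 1)
#' nrow(sch$events) # 180 intensifications: 12 codes x 15 sequences
make_schedule <- function(config, letters, seed = 1L) {
  stopifnot(inherits(config, "speller_config"), length(letters) >= 1)
  tc <- lapply(letters, target_codes, letter_matrix = config$letter_matrix)
  soa <- soa_samples(config)
  lead <- as.integer(round(config$target_ms * config$fs / 1000))
  trail <- as.integer(round(config$feedback_ms * config$fs / 1000))
  # a 700 ms epoch and a 100 ms baseline must always fit; enforce via margins
  lead <- max(lead, as.integer(ceiling(0.1 * config$fs)) + 1L)
  trail <- max(trail, as.integer(ceiling(0.7 * config$fs)) + soa)
  n_seq <- config$n_sequences
  n_ev_letter <- 12L * n_seq
  codes <- withr::with_seed(seed,
    unlist(lapply(seq_along(letters), function(l)
      unlist(lapply(seq_len(n_seq), function(s) sample.int(12L)))))
  )
  letter_idx <- rep(seq_along(letters), each = n_ev_letter)
  seq_idx <- rep(rep(seq_len(n_seq), each = 12L), times = length(letters))
  block_len <- lead + (n_ev_letter - 1L) * soa + trail
  block_start <- (seq_along(letters) - 1L) * block_len # 0-based
  onset <- block_start[letter_idx] + lead +
    (rep(seq_len(n_ev_letter), times = length(letters)) - 1L) * soa + 1L
  tcols <- vapply(tc, `[[`, integer(1), "column_code")
  trows <- vapply(tc, `[[`, integer(1), "row_code")
  is_target <- codes == tcols[letter_idx] | codes == trows[letter_idx]
  events <- data.frame(onset = as.integer(onset), code = as.integer(codes),
                       sequence = as.integer(seq_idx),
                       letter = as.integer(letter_idx),
                       is_target = is_target)
  targets <- data.frame(letter = seq_along(letters),
                        symbol = as.character(letters),
                        column_code = tcols, row_code = trows,
                        stringsAsFactors = FALSE)
  structure(list(events = events, targets = targets,
                 n_samples = length(letters) * block_len, config = config),
            class = "stimulus_schedule")
}

# half-cosine (Hann) bump of unit peak amplitude, `width` samples long
hann_bump <- function(width) {
  t <- seq_len(width)
  0.5 * (1 - cos(2 * pi * (t - 0.5) / width))
}

default_topography <- function(config) {
  if (config$n_channels == 8 &&
      identical(config$channels, c("Fz", "Cz", "P3", "Pz", "P4", "PO7", "Oz", "PO8")))
    c(0.5, 0.8, 0.9, 1.0, 0.9, 0.6, 0.5, 0.6)
  else rep(1, config$n_channels)
}

#' Synthesize a speller session recording
#'
#' Generates continuous multichannel EEG for a [make_schedule()] schedule
#' under a [p300_model()]: per-channel AR(1) Gaussian background noise, a
#' small common flash response added at every intensification, and for
#' target-code intensifications an additional P300 bump peaking at the
#' (jittered) P300 latency, scaled by the channel topography and by the drift
#' factor `1 + drift_rate * (letter - 1)`. Responses of temporally adjacent
#' flashes superpose on the continuous signal, reproducing the overlap
#' structure of a 175 ms SOA with 700 ms analysis windows.
#'
#' @param schedule A [make_schedule()] schedule.
#' @param model A [p300_model()]; `model$seed` determines the noise and jitter.
#' @param config Speller configuration; defaults to the schedule's.
#'
#' @return An object of class `speller_session`: `signal` (samples x channels
#'   matrix, uV), `fs`, `channels`, `letter_matrix`, `events`, `targets`,
#'   `config`, `model`.
#' @export
synthesize_session <- function(schedule, model, config = schedule$config) {
  stopifnot(inherits(schedule, "stimulus_schedule"), inherits(model, "p300_model"))
  fs <- config$fs
  n <- schedule$n_samples
  C <- config$n_channels
  topo <- model$topography
  if (is.null(topo)) topo <- default_topography(config)
  if (length(topo) != C)
    stop(sprintf("topography has %d weights but the session has %d channels",
                 length(topo), C))
  ev <- schedule$events
  ms2smp <- function(ms) round(ms * fs / 1000)
  sig <- withr::with_seed(model$seed, {
    if (model$noise_sigma > 0) {
      innov_sd <- model$noise_sigma * sqrt(1 - model$noise_ar1^2)
      e <- matrix(stats::rnorm(n * C, sd = innov_sd), n, C)
      if (model$noise_ar1 > 0)
        e <- apply(e, 2, function(x)
          as.numeric(stats::filter(x, model$noise_ar1, method = "recursive")))
      e
    } else matrix(0, n, C)
  })
  jit <- withr::with_seed(model$seed + 1L,
    stats::rnorm(nrow(ev), sd = model$latency_jitter_ms))

  # accumulate evoked responses per channel as vectors (in-place subassignment)
  evoked1 <- numeric(n) # common flash response, identical on every channel
  if (model$vep_amplitude > 0) {
    vw <- max(2L, ms2smp(model$vep_width_ms))
    vshape <- model$vep_amplitude * hann_bump(vw)
    voff <- as.integer(ms2smp(model$vep_latency_ms - model$vep_width_ms / 2))
    for (i in seq_len(nrow(ev))) {
      start <- ev$onset[i] + voff
      lo <- max(1L, start); hi <- min(n, start + vw - 1L)
      if (hi >= lo)
        evoked1[lo:hi] <- evoked1[lo:hi] + vshape[(lo - start + 1L):(hi - start + 1L)]
    }
  }
  p300 <- numeric(n) # unit-topography P300 train, scaled per channel below
  if (model$p300_amplitude > 0) {
    pw <- max(2L, ms2smp(model$p300_width_ms))
    pshape <- hann_bump(pw)
    for (i in which(ev$is_target)) {
      peak_ms <- model$p300_latency_ms + jit[i]
      start <- ev$onset[i] + as.integer(ms2smp(peak_ms - model$p300_width_ms / 2))
      amp <- model$p300_amplitude * (1 + model$drift_rate * (ev$letter[i] - 1))
      lo <- max(1L, start); hi <- min(n, start + pw - 1L)
      if (hi >= lo)
        p300[lo:hi] <- p300[lo:hi] + amp * pshape[(lo - start + 1L):(hi - start + 1L)]
    }
  }
  sig <- sig + evoked1 + p300 %o% topo
  if (!all(is.finite(sig))) stop("synthesized signal contains non-finite values")
  structure(list(signal = sig, fs = fs, channels = config$channels,
                 letter_matrix = config$letter_matrix,
                 events = ev, targets = schedule$targets,
                 config = config, model = model),
            class = "speller_session")
}

#' Simulate a complete speller session
#'
#' Convenience wrapper: draws `n_letters` target symbols uniformly from the
#' matrix (unless `letters` is given), builds the schedule, and synthesizes
#' the recording. The schedule permutations use `seed` and the signal uses
#' `seed + 1`, so the session is fully reproducible from
#' `(config, model, seed)`.
#'
#' @param config A [speller_config()].
#' @param model A [p300_model()]; its `seed` field is overridden.
#' @param n_letters Number of letters to spell (ignored when `letters` given).
#' @param letters Optional explicit target symbols.
#' @param seed Integer seed.
#' @return A `speller_session` (see [synthesize_session()]).
#' @export
simulate_session <- function(config = speller_config(), model = p300_model(),
                             n_letters = 5, letters = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(letters))
    letters <- withr::with_seed(seed + 2L,
      sample(as.vector(config$letter_matrix), n_letters, replace = TRUE))
  sch <- make_schedule(config, letters, seed = seed)
  model$seed <- seed + 1L
  synthesize_session(sch, model, config)
}

#' @export
print.speller_session <- function(x, ...) {
  cat(sprintf("<speller_session> %d letters, %d events, %d samples x %d channels @ %g Hz\n",
              nrow(x$targets), nrow(x$events), nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}
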