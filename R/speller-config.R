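#' Default 6x6 speller letter matrix
#'
#' The standard row/column speller layout: rows "ABCDEF", "GHIJKL", "MNOPQR",
#' "STUVWX", "YZ1234", "56789_". Columns carry intensification codes 1--6,
#' rows carry codes 7--12 (row r has code r + 6).
#'
#' @return A 6x6 character matrix of single symbols.
#' @export
#' @examples
#' default_letter_matrix()[3, 2] # "N": column code 2, row code 9
default_letter_matrix <- function() {
  rows <- c("ABCDEF", "GHIJKL", "MNOPQR", "STUVWX", "YZ1234", "56789_")
  do.call(rbind, strsplit(rows, ""))
}

#' Speller stimulus and acquisition configuration
#'
#' Bundles the stimulus-protocol and recording parameters of a row/column
#' P300 speller session. The stimulus onset asynchrony (SOA) is
#' `flash_ms + blank_ms`; one *sequence* is 12 intensifications (each row and
#' each column once, in random order), and a letter is spelled with
#' `n_sequences` sequences, i.e. `12 * n_sequences` intensifications.
#'
#' @param letter_matrix 6x6 character matrix of symbols
#'   (default [default_letter_matrix()]).
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of EEG channels.
#' @param channels Optional character vector of channel names; defaults to the
#'   standard 8-channel P300 montage (Fz, Cz, P3, Pz, P4, PO7, Oz, PO8) when
#'   `n_channels == 8`, otherwise "Ch1".."Chn".
#' @param flash_ms Intensification (flash) duration in ms.
#' @param blank_ms Blank duration between flashes in ms.
#' @param n_sequences Sequences per letter (>= 1).
#' @param target_ms Target-cue presentation duration in ms (lead-in before the
#'   first flash of a letter).
#' @param feedback_ms Feedback presentation duration in ms (gap after the last
#'   flash of a letter).
#'
#' @return An object of class `speller_config`.
#' @export
#' @examples
#' cfg <- speller_config() # 128 Hz, 8 channels, 100 ms flash + 75 ms blank
#' soa_samples(cfg)        # 22 samples at 128 Hz
speller_config <- function(letter_matrix = default_letter_matrix(),
                           fs = 128, n_channels = 8, channels = NULL,
                           flash_ms = 100, blank_ms = 75, n_sequences = 15,
                           target_ms = 3000, feedback_ms = 1000) {
  if (!is.matrix(letter_matrix) || !all(dim(letter_matrix) == c(6L, 6L)))
    stop("letter_matrix must be a 6x6 character matrix")
  if (anyDuplicated(letter_matrix))
    stop("letter_matrix symbols must be unique")
  stopifnot(fs > 0, n_channels >= 1, flash_ms > 0, blank_ms >= 0,
            n_sequences >= 1, target_ms >= 0, feedback_ms >= 0)
  if (is.null(channels)) {
    channels <- if (n_channels == 8)
      c("Fz", "Cz", "P3", "Pz", "P4", "PO7", "Oz", "PO8")
    else paste0("Ch", seq_len(n_channels))
  }
  stopifnot(length(channels) == n_channels)
  structure(list(letter_matrix = letter_matrix, fs = fs,
                 n_channels = as.integer(n_channels), channels = channels,
                 flash_ms = flash_ms, blank_ms = blank_ms,
                 n_sequences = as.integer(n_sequences),
                 target_ms = target_ms, feedback_ms = feedback_ms),
            class = "speller_config")
}

#' Stimulus onset asynchrony in samples
#'
#' @param config A [speller_config()].
#' @return Integer number of samples between consecutive flash onsets,
#'   `round((flash_ms + blank_ms) * fs / 1000)`.
#' @export
soa_samples <- function(config) {
  as.integer(round((config$flash_ms + config$blank_ms) * config$fs / 1000))
}

#' Intensification codes of a target symbol
#'
#' Maps a symbol to the pair of codes that flash it: its column (code 1--6)
#' and its row (code 7--12; row r has code r + 6).
#'
#' @param symbol Single character present exactly once in the matrix.
#' @param letter_matrix 6x6 character matrix.
#' @return Named integer vector `c(column_code, row_code)`.
#' @export
#' @examples
#' target_codes("N", default_letter_matrix()) # column 2, row 3 -> c(2, 9)
target_codes <- function(symbol, letter_matrix = default_letter_matrix()) {
  hit <- which(letter_matrix == symbol)
  if (length(hit) == 0L)
    stop(sprintf("symbol '%s' is not in the letter matrix", symbol))
  if (length(hit) > 1L)
    stop(sprintf("symbol '%s' occurs more than once in the letter matrix", symbol))
  row <- (hit - 1L) %% 6L + 1L
  col <- (hit - 1L) %/% 6L + 1L
  c(column_code = col, row_code = row + 6L)
}

#' Symbol at a (column code, row code) cell
#'
#' Inverse of [target_codes()].
#'
#' @param column_code Integer in 1..6.
#' @param row_code Integer in 7..12.
#' @param letter_matrix 6x6 character matrix.
#' @return The symbol at that cell.
#' @export
code_to_symbol <- function(column_code, row_code,
                           letter_matrix = default_letter_matrix()) {
  stopifnot(column_code %in% 1:6, row_code %in% 7:12)
  letter_matrix[row_code - 6L, column_code]
}
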