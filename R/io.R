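#' Write a speller session bundle to disk
#'
#' The on-disk format is a directory with `meta.json` (fs, channels, matrix
#' rows, protocol durations, signal format and shape), the continuous signal
#' as either `signal.tsv` (one row per sample, one column per channel) or
#' `signal.f32` (row-major samples x channels, little-endian float32),
#' `events.tsv` (`onset_sample`, `code`, `sequence_index`, `letter_index`,
#' `is_target`) and `targets.tsv` (`letter_index`, `symbol`). Serialized
#' sample, sequence and letter indices are 0-based; in-memory R objects are
#' 1-based.
#'
#' @param session A `speller_session`.
#' @param dir Directory to create/write into.
#' @param signal_format "tsv" (plain text) or "f32" (binary float32).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir, signal_format = c("tsv", "f32")) {
  signal_format <- match.arg(signal_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  meta <- list(fs = session$fs,
               channels = session$channels,
               matrix_rows = apply(session$letter_matrix, 1, paste, collapse = ""),
               flash_ms = cfg$flash_ms, blank_ms = cfg$blank_ms,
               n_sequences = cfg$n_sequences,
               target_ms = cfg$target_ms, feedback_ms = cfg$feedback_ms,
               n_samples = nrow(session$signal),
               n_channels = ncol(session$signal),
               signal_format = signal_format,
               index_base = 0)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (signal_format == "tsv") {
    data.table::fwrite(data.table::as.data.table(session$signal),
                       file.path(dir, "signal.tsv"), sep = "\t",
                       col.names = FALSE)
  } else {
    con <- file(file.path(dir, "signal.f32"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(session$signal)), con, size = 4, endian = "little")
  }
  ev <- session$events
  data.table::fwrite(data.frame(onset_sample = ev$onset - 1L,
                                code = ev$code,
                                sequence_index = ev$sequence - 1L,
                                letter_index = ev$letter - 1L,
                                is_target = as.integer(ev$is_target)),
                     file.path(dir, "events.tsv"), sep = "\t")
  data.table::fwrite(data.frame(letter_index = session$targets$letter - 1L,
                                symbol = session$targets$symbol),
                     file.path(dir, "targets.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a speller session bundle
#'
#' Inverse of [write_session_bundle()].
#'
#' @param dir Bundle directory.
#' @return A `speller_session`.
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  lm <- do.call(rbind, strsplit(meta$matrix_rows, ""))
  if (identical(meta$signal_format, "f32")) {
    con <- file(file.path(dir, "signal.f32"), "rb")
    on.exit(close(con))
    raw <- readBin(con, numeric(), n = meta$n_samples * meta$n_channels,
                   size = 4, endian = "little")
    sig <- matrix(raw, nrow = meta$n_samples, ncol = meta$n_channels,
                  byrow = TRUE)
  } else {
    sig <- as.matrix(data.table::fread(file.path(dir, "signal.tsv"),
                                       sep = "\t", header = FALSE))
    dimnames(sig) <- NULL
  }
  evd <- data.table::fread(file.path(dir, "events.tsv"), sep = "\t")
  events <- data.frame(onset = evd$onset_sample + 1L,
                       code = as.integer(evd$code),
                       sequence = evd$sequence_index + 1L,
                       letter = evd$letter_index + 1L,
                       is_target = as.logical(evd$is_target))
  tgd <- data.table::fread(file.path(dir, "targets.tsv"), sep = "\t",
                           colClasses = list(character = "symbol"))
  tc <- lapply(tgd$symbol, target_codes, letter_matrix = lm)
  targets <- data.frame(letter = tgd$letter_index + 1L,
                        symbol = as.character(tgd$symbol),
                        column_code = vapply(tc, `[[`, integer(1), "column_code"),
                        row_code = vapply(tc, `[[`, integer(1), "row_code"),
                        stringsAsFactors = FALSE)
  cfg <- speller_config(letter_matrix = lm, fs = meta$fs,
                        n_channels = meta$n_channels,
                        channels = meta$channels,
                        flash_ms = meta$flash_ms, blank_ms = meta$blank_ms,
                        n_sequences = meta$n_sequences,
                        target_ms = meta$target_ms,
                        feedback_ms = meta$feedback_ms)
  structure(list(signal = sig, fs = meta$fs, channels = meta$channels,
                 letter_matrix = lm, events = events, targets = targets,
                 config = cfg, model = NULL),
            class = "speller_session")
}
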