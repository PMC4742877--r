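# Plain-text I/O for EEG matrices, event lists and tap logs.

#' Read a delimited EEG matrix with a sidecar event file
#'
#' The EEG file is a headered delimited table with one row per sample and
#' one column per channel; the event file is a CSV with columns
#' `onset_sample` (1-based) and `trial_type`.
#'
#' @param eeg_path Path to the delimited EEG matrix.
#' @param events_path Path to the events CSV.
#' @param rate_hz Sampling rate of the recording.
#' @param sep Field separator of the EEG file (default ",").
#' @return List with `recording` (channels x samples matrix), `rate_hz`,
#'   `onsets_s`, `events` (data frame).
#' @export
read_eeg_delim <- function(eeg_path, events_path, rate_hz, sep = ",") {
  m <- as.matrix(utils::read.table(eeg_path, header = TRUE, sep = sep))
  storage.mode(m) <- "double"
  ev <- utils::read.csv(events_path)
  stopifnot(all(c("onset_sample", "trial_type") %in% names(ev)))
  list(recording = t(m), rate_hz = rate_hz,
       onsets_s = (ev$onset_sample - 1L) / rate_hz, events = ev)
}

#' Write an EEG recording as a delimited matrix plus events CSV
#'
#' @param recording Channels x samples matrix.
#' @param rate_hz Sampling rate.
#' @param onsets_s Stimulus onsets in seconds.
#' @param eeg_path,events_path Output paths.
#' @export
write_eeg_delim <- function(recording, rate_hz, onsets_s,
                            eeg_path, events_path) {
  m <- t(recording)
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), eeg_path, row.names = FALSE)
  utils::write.csv(
    data.frame(onset_sample = round(onsets_s * rate_hz) + 1L,
               trial_type = "stim"),
    events_path, row.names = FALSE)
  invisible(eeg_path)
}

#' Read tap logs from CSV
#'
#' Expects columns `trial_id` and `tap_ms`; returns a list of tap-time
#' vectors, one per trial.
#'
#' @param path Path to the taps CSV.
#' @return Named list of numeric vectors.
#' @export
read_taps_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("trial_id", "tap_ms") %in% names(df)))
  split(df$tap_ms, df$trial_id)
}

#' Write tap logs to CSV
#'
#' @param taps Named list of tap-time vectors (ms).
#' @param path Output path.
#' @export
write_taps_csv <- function(taps, path) {
  df <- do.call(rbind, lapply(names(taps), function(id)
    data.frame(trial_id = id, tap_ms = taps[[id]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
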