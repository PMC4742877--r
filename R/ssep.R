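# SSEP extraction: filtering, epoching, spectra, neighbor-bin noise
# subtraction, channel averaging, and the two entrainment indices.
#
# EEG recordings are represented as numeric matrices with one row per
# channel and one column per sample, plus an explicit sampling rate.

#' Zero-phase Butterworth high-pass filter
#'
#' Removes slow drifts with a 0.1 Hz high-pass Butterworth filter applied
#' forward and backward (zero phase distortion).  The filter is order 2 in
#' each direction (effective order 4), which is numerically stable at the
#' very low relative cutoff involved.
#'
#' @param x Numeric vector, or channels-by-samples matrix.
#' @param rate_hz Sampling rate in Hz.
#' @param cutoff_hz High-pass cutoff (default 0.1).
#' @param order Butterworth order per direction (default 2).
#' @return Filtered data, same shape as `x`.
#' @export
highpass_filter <- function(x, rate_hz, cutoff_hz = 0.1, order = 2) {
  if (length(x) == 0L) stop("empty input")
  if (cutoff_hz >= rate_hz / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "high")
  if (is.matrix(x)) {
    t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Epoch a recording around stimulus onsets and average across trials
#'
#' Extracts one epoch per stimulus onset over `window_s` (default +1 to
#' +33 s relative to onset; the first second after onset is discarded to
#' skip onset-evoked transients and let the steady-state response build
#' up), then averages the epochs sample-by-sample per channel.  Trials
#' flagged in `exclude_trials` (e.g. tempo-change probe trials) are dropped
#' before averaging.
#'
#' @param x Channels-by-samples matrix (a vector is treated as one channel).
#' @param rate_hz Sampling rate in Hz.
#' @param onsets_s Stimulus onset times in seconds.
#' @param window_s Epoch window relative to onset, default `c(1, 33)`.
#' @param exclude_trials Logical vector (length = number of onsets) flagging
#'   trials to exclude, or NULL.
#' @return Channels-by-samples matrix of the averaged epoch, with
#'   attributes `rate_hz` and `n_trials`.
#' @export
epoch_and_average <- function(x, rate_hz, onsets_s, window_s = c(1, 33),
                              exclude_trials = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (length(onsets_s) < 1L) stop("at least one onset required")
  if (!is.null(exclude_trials)) {
    stopifnot(length(exclude_trials) == length(onsets_s))
    onsets_s <- onsets_s[!exclude_trials]
  }
  if (length(onsets_s) == 0L) stop("no usable trials after exclusion")
  n_samp <- round((window_s[2] - window_s[1]) * rate_hz)
  starts <- round((onsets_s + window_s[1]) * rate_hz) + 1L
  if (any(starts < 1L) || any(starts + n_samp - 1L > ncol(x)))
    stop("epoch window exceeds recording bounds")
  avg <- matrix(0, nrow = nrow(x), ncol = n_samp)
  for (s in starts) avg <- avg + x[, s:(s + n_samp - 1L), drop = FALSE]
  avg <- avg / length(starts)
  attr(avg, "rate_hz") <- rate_hz
  attr(avg, "n_trials") <- length(starts)
  avg
}

#' Single-sided amplitude spectrum
#'
#' Discrete Fourier transform scaled so that a sinusoid of amplitude A
#' whose frequency falls exactly on a bin yields amplitude A at that bin
#' (amplitudes in the input's units, e.g. microvolts).  The bin spacing is
#' the reciprocal of the epoch duration: a 32-s epoch gives 1/32 =
#' 0.03125 Hz per bin.
#'
#' @param x Numeric vector or channels-by-samples matrix (e.g. an averaged
#'   epoch).
#' @param rate_hz Sampling rate in Hz (taken from the `rate_hz` attribute
#'   of `x` if present).
#' @return An object of class `amplitude_spectrum`: list with `freq_hz`,
#'   `amp` (channels-by-bins matrix), `bin_hz`, `rate_hz`,
#'   `corrected = FALSE`.
#' @export
amplitude_spectrum <- function(x, rate_hz = attr(x, "rate_hz")) {
  if (is.null(rate_hz)) stop("rate_hz required")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) == 0L) stop("empty epoch")
  if (!all(is.finite(x))) stop("non-finite samples")
  n <- ncol(x)
  nb <- floor(n / 2) + 1L
  amp <- t(apply(x, 1L, function(ch) {
    a <- Mod(stats::fft(ch))[seq_len(nb)] / n
    a[2:nb] <- 2 * a[2:nb]
    if (n %% 2L == 0L) a[nb] <- a[nb] / 2
    a
  }))
  structure(
    list(freq_hz = (seq_len(nb) - 1L) * rate_hz / n,
         amp = amp, bin_hz = rate_hz / n, rate_hz = rate_hz,
         corrected = FALSE),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum: %d channel(s), %d bins, %.5g Hz/bin%s>\n",
              nrow(x$amp), ncol(x$amp), x$bin_hz,
              if (x$corrected) ", noise-subtracted" else ""))
  invisible(x)
}

#' Neighbor-bin noise subtraction
#'
#' Estimates the broadband background under each spectral bin as the mean
#' amplitude of neighboring bins whose center offsets lie within
#' `offset_hz` on either side (default 0.09 to 0.15 Hz, i.e. offsets of 3
#' and 4 bins at 0.03125 Hz spacing -- 2 bins per side), and subtracts it.
#' The immediately adjacent bins are thereby excluded, so a narrowband
#' peak's own leakage does not inflate the background estimate.  Corrected
#' amplitudes can be negative; at pure-noise bins they are zero on average.
#' Bins too close to the spectrum edge for a full stencil are set to NA.
#'
#' @param spectrum An `amplitude_spectrum` with `corrected = FALSE`.
#' @param offset_hz Two-sided neighbor window `c(lo, hi)` in Hz.
#' @return The spectrum with background-subtracted `amp` and
#'   `corrected = TRUE`.
#' @export
subtract_noise <- function(spectrum, offset_hz = c(0.09, 0.15)) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  if (isTRUE(spectrum$corrected)) stop("spectrum is already noise-subtracted")
  db <- spectrum$bin_hz
  k <- seq_len(ceiling(offset_hz[2] / db) + 1L)
  eps <- 1e-9
  off <- k[k * db >= offset_hz[1] - eps & k * db <= offset_hz[2] + eps]
  if (length(off) == 0L)
    stop("no neighbor bins fall inside the offset window at this resolution")
  amp <- spectrum$amp
  nb <- ncol(amp)
  corrected <- matrix(NA_real_, nrow(amp), nb)
  kmax <- max(off)
  if (nb - kmax < kmax + 1L)
    stop("spectrum too short for the noise-subtraction stencil")
  valid <- (kmax + 1L):(nb - kmax)
  stencil <- c(-rev(off), off)
  for (j in valid) {
    bg <- rowMeans(amp[, j + stencil, drop = FALSE])
    corrected[, j] <- amp[, j] - bg
  }
  spectrum$amp <- corrected
  spectrum$corrected <- TRUE
  spectrum$noise_offsets_bins <- off
  spectrum
}

#' Average a spectrum across channels
#'
#' Unweighted mean over scalp channels; channels in `exclude_channels`
#' (e.g. eye electrodes) are dropped first.
#'
#' @param spectrum An `amplitude_spectrum`.
#' @param exclude_channels Integer indices of channels to exclude, or NULL.
#' @return The spectrum reduced to a single channel.
#' @export
channel_average <- function(spectrum, exclude_channels = NULL) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  keep <- setdiff(seq_len(nrow(spectrum$amp)), exclude_channels)
  if (length(keep) == 0L) stop("no channels left to average")
  spectrum$amp <- matrix(colMeans(spectrum$amp[keep, , drop = FALSE]),
                         nrow = 1L)
  spectrum
}

#' Read the SSEP profile at the 12 expected frequencies
#'
#' Reads the (noise-subtracted, channel-averaged) amplitude at the bin
#' nearest each of the 12 envelope frequencies of the given tempo.  The
#' 3rd element is the beat-frequency SSEP.
#'
#' @param spectrum A single-channel `amplitude_spectrum`.
#' @param tempo A `tempo_spec`.
#' @param rhythm Optional rhythm label ("unsyncopated"/"syncopated") carried
#'   along for bookkeeping.
#' @return An object of class `ssep_profile`: list with `amp_uv` (length
#'   12), `freq_hz` (nominal expected frequencies), `bin_freq_hz` (bin
#'   centers actually read), `beat_index = 3`, `tempo`, `rhythm`.
#' @export
extract_profile <- function(spectrum, tempo, rhythm = NA_character_) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"),
            inherits(tempo, "tempo_spec"))
  if (nrow(spectrum$amp) != 1L)
    stop("extract_profile expects a channel-averaged (single-profile) spectrum")
  freqs <- expected_frequencies(tempo)
  idx <- round(freqs / spectrum$bin_hz) + 1L
  if (any(idx < 1L) || any(idx > ncol(spectrum$amp)))
    stop("expected frequency outside the spectrum range")
  if (any(abs(spectrum$freq_hz[idx] - freqs) > spectrum$bin_hz / 2 + 1e-9))
    stop("expected frequency farther than half a bin from any bin center")
  amp <- spectrum$amp[1L, idx]
  if (anyNA(amp))
    stop("expected frequency falls on a bin without a valid noise estimate")
  structure(
    list(amp_uv = amp, freq_hz = freqs, bin_freq_hz = spectrum$freq_hz[idx],
         beat_index = 3L, tempo = tempo, rhythm = rhythm),
    class = "ssep_profile"
  )
}

#' @export
print.ssep_profile <- function(x, ...) {
  cat(sprintf("<ssep_profile: %s, tempo %d (beat %.3g Hz), beat amp %.3g uV>\n",
              x$rhythm, x$tempo$tempo, x$tempo$beat_hz,
              x$amp_uv[x$beat_index]))
  invisible(x)
}

#' Beat-selectivity z-score
#'
#' Expresses how much the beat-frequency SSEP stands out from the full set
#' of 12 SSEPs of a condition: `z = (x - mu) / sigma`, where `x` is the
#' beat amplitude and `mu`, `sigma` are the mean and standard deviation of
#' the 12 amplitudes.  `sigma` is the population (n-divisor) standard
#' deviation: the z-score is descriptive of this fixed set of 12 peaks,
#' not an inference to a larger population; set `pop_sd = FALSE` for the
#' sample (n-1) convention.
#'
#' @param profile An `ssep_profile` (or a bare numeric vector of 12
#'   amplitudes).
#' @param pop_sd Use the population SD (default TRUE).
#' @return The z-score (unitless).
#' @export
selectivity_zscore <- function(profile, pop_sd = TRUE) {
  amps <- if (inherits(profile, "ssep_profile")) profile$amp_uv else profile
  beat_i <- if (inherits(profile, "ssep_profile")) profile$beat_index else 3L
  stopifnot(length(amps) == 12L)
  s <- if (pop_sd) sd_pop(amps) else stats::sd(amps)
  if (s == 0) stop("selectivity z-score undefined: all 12 amplitudes equal")
  (amps[beat_i] - mean(amps)) / s
}

#' Endogenous-entrainment index
#'
#' Beat-frequency SSEP amplitude of the syncopated rhythm minus that of the
#' unsyncopated rhythm at the same tempo.  Beats of the syncopated rhythm
#' are mostly unmarked by sound (1/3 vs 3/3 beats toned), so its beat SSEP
#' reflects mostly endogenous beat generation; the higher the difference,
#' the more endogenous entrainment.
#'
#' @param sync_profile,unsync_profile `ssep_profile`s of the syncopated and
#'   unsyncopated rhythm at the same tempo.
#' @return Amplitude difference in microvolts.
#' @export
endogenous_index <- function(sync_profile, unsync_profile) {
  stopifnot(inherits(sync_profile, "ssep_profile"),
            inherits(unsync_profile, "ssep_profile"))
  if (sync_profile$tempo$event_ms != unsync_profile$tempo$event_ms)
    stop("profiles must share the same tempo")
  sync_profile$amp_uv[sync_profile$beat_index] -
    unsync_profile$amp_uv[unsync_profile$beat_index]
}

#' Aggregate per-condition entrainment measures
#'
#' Collapses a per-condition table (2 rhythms x 4 tempi) into the summary
#' indices used downstream: mean beat amplitude, mean selectivity z-score,
#' the endogenous index per tempo and its mean, the mean non-beat
#' amplitude, and slow/fast tempo aggregates (slow = mean over the 0.6 and
#' 1.25 Hz beat tempi, fast = mean over the 2.5 and 3.8 Hz ones).
#'
#' @param conditions Data frame with one row per condition and columns
#'   `rhythm` ("unsyncopated"/"syncopated"), `tempo` (1..4), `beat_amp_uv`,
#'   `z_beat`, `nonbeat_amp_uv`.
#' @param require_complete Error when any of the 8 conditions is missing
#'   (default TRUE); set FALSE to aggregate over a declared subset.
#' @return A list of class `entrainment_indices` with fields
#'   `mean_beat_amp_uv`, `mean_selectivity`, `mean_nonbeat_amp_uv`,
#'   `endo_by_tempo`, `endo_mean_uv`, and `slow`/`fast` sublists
#'   (`beat_amp_uv`, `selectivity`, `nonbeat_amp_uv`, `endo_uv`).
#' @export
aggregate_indices <- function(conditions, require_complete = TRUE) {
  needed <- c("rhythm", "tempo", "beat_amp_uv", "z_beat", "nonbeat_amp_uv")
  stopifnot(all(needed %in% names(conditions)))
  if (require_complete) {
    have <- with(conditions, paste(rhythm, tempo))
    want <- as.vector(outer(c("unsyncopated", "syncopated"), 1:4, paste))
    if (!all(want %in% have))
      stop("missing conditions: ", paste(setdiff(want, have), collapse = ", "))
  }
  slow_tempi <- c(1L, 2L)  # beat 0.625 and 1.25 Hz
  fast_tempi <- c(3L, 4L)  # beat 2.5 and ~3.8 Hz
  endo_of <- function(tempi) {
    sub <- conditions[conditions$tempo %in% tempi, ]
    vapply(sort(unique(sub$tempo)), function(tp) {
      s <- sub$beat_amp_uv[sub$tempo == tp & sub$rhythm == "syncopated"]
      u <- sub$beat_amp_uv[sub$tempo == tp & sub$rhythm == "unsyncopated"]
      if (length(s) == 1L && length(u) == 1L) s - u else NA_real_
    }, numeric(1))
  }
  pick <- function(tempi, col) mean(conditions[[col]][conditions$tempo %in% tempi])
  endo_by_tempo <- endo_of(sort(unique(conditions$tempo)))
  names(endo_by_tempo) <- sort(unique(conditions$tempo))
  structure(list(
    mean_beat_amp_uv = mean(conditions$beat_amp_uv),
    mean_selectivity = mean(conditions$z_beat),
    mean_nonbeat_amp_uv = mean(conditions$nonbeat_amp_uv),
    endo_by_tempo = endo_by_tempo,
    endo_mean_uv = mean(endo_by_tempo, na.rm = TRUE),
    slow = list(beat_amp_uv = pick(slow_tempi, "beat_amp_uv"),
                selectivity = pick(slow_tempi, "z_beat"),
                nonbeat_amp_uv = pick(slow_tempi, "nonbeat_amp_uv"),
                endo_uv = mean(endo_of(slow_tempi))),
    fast = list(beat_amp_uv = pick(fast_tempi, "beat_amp_uv"),
                selectivity = pick(fast_tempi, "z_beat"),
                nonbeat_amp_uv = pick(fast_tempi, "nonbeat_amp_uv"),
                endo_uv = mean(endo_of(fast_tempi)))
  ), class = "entrainment_indices")
}

#' Full per-condition SSEP analysis chain
#'
#' Convenience wrapper running high-pass filtering, epoching and trial
#' averaging, the amplitude spectrum, neighbor-bin noise subtraction,
#' channel averaging, and profile readout for one recording/condition.
#'
#' @param x Channels-by-samples EEG matrix (microvolts).
#' @param rate_hz Sampling rate.
#' @param onsets_s Stimulus onsets in seconds.
#' @param tempo A `tempo_spec`.
#' @param rhythm Rhythm label.
#' @param exclude_trials Logical flags of probe trials to drop, or NULL.
#' @param exclude_channels Channel indices to drop from the average.
#' @param highpass Apply the 0.1 Hz high-pass stage (default TRUE; can be
#'   skipped for drift-free synthetic data).
#' @param window_s Epoch window, default `c(1, 33)`.
#' @return An `ssep_profile`.
#' @export
analyze_condition <- function(x, rate_hz, onsets_s, tempo,
                              rhythm = NA_character_,
                              exclude_trials = NULL, exclude_channels = NULL,
                              highpass = TRUE, window_s = c(1, 33)) {
  if (highpass) x <- highpass_filter(x, rate_hz)
  avg <- epoch_and_average(x, rate_hz, onsets_s, window_s = window_s,
                           exclude_trials = exclude_trials)
  spec <- amplitude_spectrum(avg, rate_hz)
  spec <- subtract_noise(spec)
  spec <- channel_average(spec, exclude_channels = exclude_channels)
  extract_profile(spec, tempo, rhythm = rhythm)
}
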