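# Synthetic EEG and tapper generators with known ground truth.

#' Specification of a synthetic EEG recording
#'
#' Defaults emulate the recording setup of the study being modeled: 64
#' scalp channels sampled at 1024 Hz, 10 analyzable trials per condition,
#' and SSEPs of the order of 0.1-0.2 microvolts embedded in 1/f-plus-white
#' background noise.  Smaller channel counts/rates can be requested for
#' desk-scale simulation; all pipeline stages are rate-agnostic.
#'
#' @param planted Named numeric vector or data frame (`freq_hz`, `amp_uv`)
#'   of sinusoidal components to plant, phase-locked to each stimulus
#'   onset.  Amplitudes in microvolts; all >= 0.
#' @param n_channels Number of channels (default 64).
#' @param rate_hz Sampling rate (default 1024); must exceed twice the
#'   highest planted frequency.
#' @param n_trials Number of trials (default 10).
#' @param noise_white_sd White-noise SD per channel in microvolts
#'   (default 1).
#' @param noise_pink_sd 1/f-noise SD per channel in microvolts (default 1).
#' @param pink_exponent Spectral exponent of the 1/f noise (power spectral
#'   density proportional to 1/f^exponent; default 1).
#' @param phase_jitter_sd SD (radians) of trial-to-trial phase jitter of
#'   the planted components; 0 (default) = perfectly phase-locked.
#' @param seed Integer seed.
#' @return A list of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(planted, n_channels = 64L, rate_hz = 1024,
                         n_trials = 10L, noise_white_sd = 1,
                         noise_pink_sd = 1, pink_exponent = 1,
                         phase_jitter_sd = 0, seed = 1L) {
  if (is.data.frame(planted)) {
    stopifnot(all(c("freq_hz", "amp_uv") %in% names(planted)))
    freq <- planted$freq_hz; amp <- planted$amp_uv
  } else {
    freq <- as.numeric(names(planted)); amp <- unname(planted)
  }
  stopifnot(all(amp >= 0), all(freq > 0), n_channels >= 1L, n_trials >= 1L)
  if (any(freq >= rate_hz / 2))
    stop("planted frequency at or above the Nyquist frequency")
  structure(
    list(freq_hz = freq, amp_uv = amp, n_channels = as.integer(n_channels),
         rate_hz = rate_hz, n_trials = as.integer(n_trials),
         noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
         pink_exponent = pink_exponent, phase_jitter_sd = phase_jitter_sd,
         seed = as.integer(seed)),
    class = "eeg_sim_spec"
  )
}

# 1/f noise by spectral shaping of white noise: amplitude scaled by
# f^(-exponent/2), DC removed, rescaled to the requested SD.
pink_noise <- function(n, rate_hz, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  # mirror-symmetric scaling keeps the inverse transform real
  k <- seq_len(n) - 1L
  fsym <- pmin(k, n - k) * rate_hz / n
  scale <- c(0, fsym[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Simulate a multichannel EEG recording with planted SSEPs
#'
#' Each trial adds, on every channel, sinusoids at the planted frequencies
#' whose phases are fixed relative to the trial's stimulus onset (so
#' trial averaging preserves them), on top of fresh 1/f + white noise
#' spanning the whole recording.
#'
#' @param spec An `eeg_sim_spec`.
#' @param onsets_s Stimulus onset times in seconds; defaults to
#'   `spec$n_trials` onsets 35 s apart starting at 1 s.
#' @param stim_duration_s Duration of the planted activity after each
#'   onset (default 33.5 s, covering the +1..+33 s epoch).
#' @return List with `recording` (channels x samples, microvolts),
#'   `rate_hz`, `onsets_s`, `events` (data frame `onset_s`, `trial_type`),
#'   `spec`.
#' @export
simulate_eeg <- function(spec, onsets_s = NULL, stim_duration_s = 33.5) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  if (is.null(onsets_s))
    onsets_s <- 1 + (seq_len(spec$n_trials) - 1L) * 35
  n_total <- ceiling((max(onsets_s) + stim_duration_s + 0.5) * spec$rate_hz)
  with_seed(spec$seed, {
    rec <- matrix(0, spec$n_channels, n_total)
    for (ch in seq_len(spec$n_channels)) {
      noise <- spec$noise_white_sd * stats::rnorm(n_total)
      if (spec$noise_pink_sd > 0)
        noise <- noise + spec$noise_pink_sd *
          pink_noise(n_total, spec$rate_hz, spec$pink_exponent)
      rec[ch, ] <- noise
    }
    phases <- stats::runif(length(spec$freq_hz), 0, 2 * pi)
    n_stim <- round(stim_duration_s * spec$rate_hz)
    for (on in onsets_s) {
      i0 <- round(on * spec$rate_hz) + 1L
      idx <- i0:(i0 + n_stim - 1L)
      t_rel <- (idx - i0) / spec$rate_hz
      burst <- numeric(n_stim)
      for (k in seq_along(spec$freq_hz)) {
        ph <- phases[k]
        if (spec$phase_jitter_sd > 0)
          ph <- ph + stats::rnorm(1, 0, spec$phase_jitter_sd)
        burst <- burst + spec$amp_uv[k] *
          sin(2 * pi * spec$freq_hz[k] * t_rel + ph)
      }
      rec[, idx] <- sweep(rec[, idx, drop = FALSE], 2L, burst, `+`)
    }
    list(recording = rec, rate_hz = spec$rate_hz, onsets_s = onsets_s,
         events = data.frame(onset_s = onsets_s, trial_type = "stim"),
         spec = spec)
  })
}

#' Specification of a simulated tapper
#'
#' @param mode "beat" (isochronous beat tapping) or "tempo" (tapping with a
#'   tempo-changing pacing sequence).
#' @param delta_ms Mean tap lag in ms (negative = anticipation; default
#'   -36, a typical negative mean asynchrony).
#' @param sigma_motor_ms SD of Gaussian motor noise in ms (default 20).
#' @param alpha Prediction weight in \[0, 1\] (tempo mode): 1 = fully
#'   predicts the upcoming interval, 0 = copies the previous one.
#' @param miss_rate Probability of omitting each tap (default 0).
#' @param unit Tapping unit in beat mode ("beat", "subdivision" or "bar").
#' @param seed Integer seed.
#' @return A list of class `tapper_spec`.
#' @export
tapper_spec <- function(mode = c("beat", "tempo"), delta_ms = -36,
                        sigma_motor_ms = 20, alpha = 1, miss_rate = 0,
                        unit = c("beat", "subdivision", "bar"), seed = 1L) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  stopifnot(sigma_motor_ms >= 0, alpha >= 0, alpha <= 1,
            miss_rate >= 0, miss_rate < 1)
  structure(
    list(mode = mode, delta_ms = delta_ms, sigma_motor_ms = sigma_motor_ms,
         alpha = alpha, miss_rate = miss_rate, unit = unit,
         seed = as.integer(seed)),
    class = "tapper_spec"
  )
}

#' Simulate a beat tapper
#'
#' Taps at the chosen unit's target grid with a constant lag `delta_ms`
#' plus Gaussian motor noise; taps are then deleted independently at
#' `miss_rate`.  Output must be strictly increasing: motor noise so large
#' that tap order cannot be maintained raises an error.
#'
#' @param spec A `tapper_spec` with `mode = "beat"`.
#' @param beat_times_ms Theoretical beat onsets (ms).
#' @param tempo A `tempo_spec` (needed to build subdivision/bar grids).
#' @return Numeric vector of tap times in ms.
#' @export
simulate_beat_tapper <- function(spec, beat_times_ms, tempo) {
  stopifnot(inherits(spec, "tapper_spec"), spec$mode == "beat",
            inherits(tempo, "tempo_spec"), length(beat_times_ms) >= 1L)
  targets <- unit_grid(beat_times_ms, spec$unit, tempo)
  with_seed(spec$seed, {
    taps <- targets + spec$delta_ms +
      stats::rnorm(length(targets), 0, spec$sigma_motor_ms)
    if (spec$miss_rate > 0)
      taps <- taps[stats::runif(length(taps)) >= spec$miss_rate]
    if (any(diff(taps) <= 0))
      stop("motor noise too large to maintain tap ordering at this period")
    taps
  })
}

#' Simulate a tempo tapper
#'
#' Generates inter-tap intervals as a convex mixture of the current and the
#' previous pacing interval, `ITI_n = alpha * IOI_n + (1 - alpha) *
#' IOI_(n-1) + noise`: `alpha = 1` is a perfect predictor of the ongoing
#' tempo change, `alpha = 0` a pure tracker reproducing the interval just
#' heard.  The first tap falls at the first onset plus `delta_ms`.
#'
#' @param spec A `tapper_spec` with `mode = "tempo"`.
#' @param pacing A `pacing_sequence`.
#' @return Numeric vector of tap times in ms.
#' @export
simulate_tempo_tapper <- function(spec, pacing) {
  stopifnot(inherits(spec, "tapper_spec"), spec$mode == "tempo",
            inherits(pacing, "pacing_sequence"))
  iois <- pacing$iois_ms
  with_seed(spec$seed, {
    ioi_prev <- c(iois[1], iois[-length(iois)])
    itis <- spec$alpha * iois + (1 - spec$alpha) * ioi_prev +
      stats::rnorm(length(iois), 0, spec$sigma_motor_ms)
    taps <- pacing$onsets_ms[1] + spec$delta_ms + cumsum(c(0, itis))
    if (spec$miss_rate > 0) {
      keep <- stats::runif(length(taps)) >= spec$miss_rate
      keep[1] <- TRUE
      taps <- taps[keep]
    }
    taps
  })
}
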