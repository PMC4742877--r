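# Stimulus rendering and amplitude-envelope analysis.

#' Render a rhythm pattern to an audio waveform
#'
#' Each tone slot is filled with a 1000 Hz pure tone lasting the full event
#' duration, shaped with 10 ms linear rise and fall ramps; silence slots are
#' zeros.
#'
#' @param pattern A `rhythm_pattern`.
#' @param tempo A `tempo_spec`.
#' @param n_cycles Number of cycles to render (>= 1).
#' @param rate_hz Audio sampling rate (>= 4000; default 44100).
#' @param tone_hz Carrier frequency of the tones (default 1000).
#' @param ramp_ms Rise/fall ramp duration (default 10).
#'
#' @return An object of class `audio_wave`: list with `samples`, `rate_hz`,
#'   `duration_s`, `tempo`, `pattern`.
#' @export
render_audio <- function(pattern, tempo, n_cycles = 1L, rate_hz = 44100,
                         tone_hz = 1000, ramp_ms = 10) {
  stopifnot(inherits(pattern, "rhythm_pattern"), inherits(tempo, "tempo_spec"),
            n_cycles >= 1, rate_hz >= 4000)
  if (tempo$event_ms < 2 * ramp_ms)
    stop("event duration shorter than the rise+fall ramps")
  ns_event <- round(tempo$event_ms / 1000 * rate_hz)
  ns_ramp <- round(ramp_ms / 1000 * rate_hz)
  t_ev <- (seq_len(ns_event) - 1L) / rate_hz
  carrier <- sin(2 * pi * tone_hz * t_ev)
  ramp <- pmin(1, pmin((seq_len(ns_event) - 1L) / ns_ramp,
                       (ns_event - seq_len(ns_event)) / ns_ramp))
  tone <- carrier * ramp
  silence <- numeric(ns_event)
  cycle <- unlist(lapply(pattern$slots, function(s) if (s) tone else silence),
                  use.names = FALSE)
  samples <- rep(cycle, n_cycles)
  structure(
    list(samples = samples, rate_hz = rate_hz,
         duration_s = length(samples) / rate_hz,
         tempo = tempo, pattern = pattern),
    class = "audio_wave"
  )
}

#' Analytic-signal magnitude (Hilbert envelope)
#'
#' Computes the magnitude of the analytic signal via the frequency-domain
#' construction: zero the negative frequencies, double the positive ones,
#' and inverse-transform.  For a constant-amplitude tone the envelope equals
#' the tone amplitude away from the signal edges.
#'
#' @param x An `audio_wave`, or a numeric vector (then `rate_hz` is needed).
#' @param rate_hz Sampling rate when `x` is a bare vector.
#' @return An object of class `audio_envelope`: list with non-negative
#'   `samples`, `rate_hz`, `duration_s`.
#' @export
extract_envelope <- function(x, rate_hz = NULL) {
  if (inherits(x, "audio_wave")) {
    rate_hz <- x$rate_hz
    x <- x$samples
  }
  if (length(x) == 0L) stop("empty input")
  if (!all(is.finite(x))) stop("waveform must be finite")
  if (is.null(rate_hz)) stop("rate_hz required for a bare numeric vector")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else if (n > 1L) {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  structure(
    list(samples = env, rate_hz = rate_hz, duration_s = n / rate_hz),
    class = "audio_envelope"
  )
}

#' Amplitude spectrum of the stimulus envelope
#'
#' Single-sided amplitude spectrum of an envelope (see
#' [amplitude_spectrum()] for the amplitude convention).
#'
#' @param envelope An `audio_envelope`.
#' @return An `amplitude_spectrum` object (single channel).
#' @export
envelope_spectrum <- function(envelope) {
  stopifnot(inherits(envelope, "audio_envelope"))
  amplitude_spectrum(envelope$samples, envelope$rate_hz)
}

#' Count envelope components at cycle-frequency harmonics
#'
#' Renders a rhythm over an integer number of cycles, extracts the Hilbert
#' envelope and its amplitude spectrum, and counts the distinct
#' non-negligible components at harmonics of the cycle frequency from the
#' whole-cycle frequency (k = 1) up to and including the unitary event rate
#' (k = 12).  A harmonic is counted when its amplitude exceeds
#' `threshold_frac` of the strongest harmonic in that range.  Because the
#' rendered signal holds an integer number of cycles, harmonics fall exactly
#' on spectrum bins and off-harmonic bins carry only numerical leakage.
#'
#' @param pattern A `rhythm_pattern`.
#' @param tempo A `tempo_spec`.
#' @param n_cycles Integer number of cycles to analyze (default 5).
#' @param rate_hz Rendering rate; default 22050 (the cycle duration must map
#'   to a whole number of samples, which holds for all four tempi at this
#'   rate).
#' @param threshold_frac Fraction of the maximum harmonic amplitude below
#'   which a component is considered negligible (default 0.01).
#'
#' @return List with `n_components`, `harmonic_hz`, `harmonic_amp`,
#'   `max_offharmonic_amp` (largest amplitude at any non-harmonic bin below
#'   the event rate).
#' @export
count_envelope_components <- function(pattern, tempo, n_cycles = 5L,
                                      rate_hz = 22050,
                                      threshold_frac = 0.01) {
  wave <- render_audio(pattern, tempo, n_cycles = n_cycles, rate_hz = rate_hz)
  env <- extract_envelope(wave)
  spec <- envelope_spectrum(env)
  # harmonic k of the cycle frequency sits at bin index k * n_cycles
  harm_idx <- 1L + (1:12) * n_cycles
  harmonic_amp <- spec$amp[harm_idx]
  harmonic_hz <- spec$freq_hz[harm_idx]
  below_event <- 2L:max(harm_idx)
  off_idx <- below_event[(below_event - 1L) %% n_cycles != 0L]
  list(
    n_components = sum(harmonic_amp > threshold_frac * max(harmonic_amp)),
    harmonic_hz = harmonic_hz,
    harmonic_amp = harmonic_amp,
    max_offharmonic_amp = if (length(off_idx)) max(spec$amp[off_idx]) else NA_real_
  )
}
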