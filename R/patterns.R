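# Rhythm patterns and tempo arithmetic.
#
# Both stimuli are cycles of 12 isochronous slots (tone or silence) with a
# perceived beat every 4 slots, i.e. beats at slots 0, 4 and 8 (3 beats per
# cycle).  The unsyncopated rhythm places a tone on every beat; the
# syncopated rhythm leaves two of the three beats silent, each immediately
# preceded by an off-beat tone, so that a beat percept requires endogenous
# inference.

#' Default tone slots of the two rhythm patterns
#'
#' Fixed repository constants (0-based slot indices within the 12-slot
#' cycle).  Both patterns carry 6 tones; they were chosen, among all
#' arrangements satisfying the structural constraints below, to have
#' non-vanishing envelope energy at all 12 harmonics of the cycle frequency:
#'
#' * `unsyncopated`: tones at slots 0, 1, 2, 4, 5, 8 -- a tone on all three
#'   beat positions (0, 4, 8).
#' * `syncopated`: tones at slots 0, 3, 7, 9, 10, 11 -- only 1 of 3 beats
#'   (slot 0) carries a tone; the silent beats 4 and 8 are each immediately
#'   preceded by a tone (slots 3 and 7).
#'
#' @format A named list of two integer vectors.
#' @export
default_pattern_slots <- list(
  unsyncopated = c(0L, 1L, 2L, 4L, 5L, 8L),
  syncopated   = c(0L, 3L, 7L, 9L, 10L, 11L)
)

#' Construct a 12-slot rhythm pattern
#'
#' @param kind `"unsyncopated"` or `"syncopated"`.
#' @param tone_slots Optional integer vector of 0-based slot indices carrying
#'   a tone, overriding the package default for `kind`.  The override must
#'   still satisfy the structural invariants of `kind`.
#'
#' @return An object of class `rhythm_pattern`: a list with `slots` (logical
#'   length-12 vector, `TRUE` = tone), `kind`, and `beat_positions`
#'   (`c(0, 4, 8)`).
#' @export
#' @examples
#' p <- make_pattern("syncopated")
#' which(p$slots) - 1L   # 0-based tone slots
make_pattern <- function(kind = c("unsyncopated", "syncopated"),
                         tone_slots = NULL) {
  kind <- match.arg(kind)
  if (is.null(tone_slots)) tone_slots <- default_pattern_slots[[kind]]
  tone_slots <- as.integer(tone_slots)
  if (anyNA(tone_slots) || any(tone_slots < 0L | tone_slots > 11L))
    stop("tone_slots must be 0-based slot indices in 0..11")
  slots <- rep(FALSE, 12L)
  slots[tone_slots + 1L] <- TRUE
  pat <- structure(
    list(slots = slots, kind = kind, beat_positions = c(0L, 4L, 8L)),
    class = "rhythm_pattern"
  )
  validate_pattern(pat)
  pat
}

validate_pattern <- function(pat) {
  stopifnot(length(pat$slots) == 12L, is.logical(pat$slots))
  beats <- pat$beat_positions + 1L
  if (pat$kind == "unsyncopated") {
    if (!all(pat$slots[beats]))
      stop("unsyncopated pattern must carry a tone on all three beats")
  } else {
    silent_beats <- pat$beat_positions[!pat$slots[beats]]
    if (length(silent_beats) == 0L)
      stop("syncopated pattern must have at least one silent beat")
    # at least one off-beat tone immediately preceding a silent beat
    pre <- (silent_beats - 1L) %% 12L
    pre <- setdiff(pre, pat$beat_positions)
    if (!any(pat$slots[pre + 1L]))
      stop("syncopated pattern needs an off-beat tone right before a silent beat")
  }
  invisible(pat)
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  marks <- ifelse(x$slots, "x", ".")
  marks[x$beat_positions + 1L] <- toupper(marks[x$beat_positions + 1L])
  marks[marks == "."] <- "o"
  cat(sprintf("<rhythm_pattern: %s>  %s  (X/x = tone, O/o = silence, caps = beat)\n",
              x$kind, paste(marks, collapse = " ")))
  invisible(x)
}

#' Tempo specification for the rhythm stimuli
#'
#' The four presentation tempi use unitary event durations of 400, 200, 100
#' and 66 ms.  One beat spans 4 events and one cycle spans 12 events, so
#' e.g. the fastest tempo has a 264 ms beat period (~3.8 Hz beat) and a
#' 792 ms cycle.
#'
#' Note: a slowest-tempo cycle is 12 x 400 = 4800 ms under this arithmetic;
#' a cycle duration of 9600 ms is sometimes quoted for that tempo elsewhere,
#' which is inconsistent with 12 events of 400 ms and is not used here.
#'
#' @param tempo Tempo index 1..4 (slow to fast), or alternatively the event
#'   duration itself via `event_ms`.
#' @param event_ms Unitary event duration in ms (400, 200, 100 or 66);
#'   overrides `tempo` when given.
#'
#' @return An object of class `tempo_spec`: list with `tempo`, `event_ms`,
#'   `beat_ms`, `cycle_ms`, `event_hz`, `beat_hz`, `cycle_hz`.
#' @export
#' @examples
#' tempo_spec(4)$cycle_ms   # 792
tempo_spec <- function(tempo = NULL, event_ms = NULL) {
  durations <- c(400, 200, 100, 66)
  if (is.null(event_ms)) {
    if (is.null(tempo) || !tempo %in% 1:4)
      stop("tempo must be 1, 2, 3 or 4 (or give event_ms)")
    event_ms <- durations[tempo]
  } else {
    if (!event_ms %in% durations)
      stop("event_ms must be one of 400, 200, 100, 66")
    tempo <- match(event_ms, durations)
  }
  beat_ms <- 4 * event_ms
  cycle_ms <- 12 * event_ms
  structure(
    list(tempo = tempo, event_ms = event_ms, beat_ms = beat_ms,
         cycle_ms = cycle_ms, event_hz = 1000 / event_ms,
         beat_hz = 1000 / beat_ms, cycle_hz = 1000 / cycle_ms),
    class = "tempo_spec"
  )
}

#' @export
print.tempo_spec <- function(x, ...) {
  cat(sprintf("<tempo_spec %d: event %g ms, beat %g ms (%.3g Hz), cycle %g ms>\n",
              x$tempo, x$event_ms, x$beat_ms, x$beat_hz, x$cycle_ms))
  invisible(x)
}

#' Frequencies at which SSEPs are expected
#'
#' The amplitude envelope of a rhythm cycled at a given tempo contains
#' energy at harmonics of the cycle frequency.  Twelve of these, from the
#' whole-cycle frequency (k = 1) up to the unitary event rate (k = 12), are
#' the frequencies at which steady-state evoked potentials are read out of
#' the EEG spectrum.  The 3rd harmonic is the beat frequency (3 beats per
#' cycle).
#'
#' @param tempo A `tempo_spec` object.
#' @return Numeric vector of 12 frequencies in Hz, ordered k = 1..12.
#' @export
#' @examples
#' expected_frequencies(tempo_spec(2))[12]  # 5 Hz event rate at tempo 2
expected_frequencies <- function(tempo) {
  stopifnot(inherits(tempo, "tempo_spec"))
  (1:12) * tempo$cycle_hz
}

#' Beat onset times for a rendered stimulus
#'
#' @param tempo A `tempo_spec`.
#' @param n_cycles Number of rhythm cycles.
#' @param t0_ms Time of the first slot onset (ms).
#' @return Numeric vector of beat onset times in ms (3 per cycle).
#' @export
beat_times <- function(tempo, n_cycles, t0_ms = 0) {
  stopifnot(inherits(tempo, "tempo_spec"), n_cycles >= 1)
  t0_ms + seq(0, by = tempo$beat_ms, length.out = 3L * n_cycles)
}
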