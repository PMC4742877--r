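# Circular-statistics scoring of beat-tapping trials.
#
# Taps are mapped onto a unit circle spanning one period of the
# participant's tapping unit (subdivision, beat, or bar), with the target
# onset at phase 0.  Synchronization accuracy is the signed asynchrony
# derived from the mean resultant direction (negative = taps lead the
# target, the usual negative mean asynchrony); precision is 1 minus the
# mean resultant length (circular variance, 0 = perfectly consistent
# phase, 1 = uniform).

#' Infer the tapping unit from inter-tap intervals
#'
#' Participants sometimes tap the rhythm's subdivision (one event) or the
#' bar (one 12-event cycle) instead of the instructed beat (4 events).  The
#' unit is inferred as the candidate period closest to the median inter-tap
#' interval.  The root-mean-square error of the intervals against the
#' theoretical *beat* period is reported alongside: it stays large when the
#' participant did not tap the beat, whatever unit they chose.
#'
#' @param taps_ms Strictly increasing tap times in ms (>= 4 taps).
#' @param tempo A `tempo_spec`.
#' @return List with `unit` ("subdivision"/"beat"/"bar"), `period_ms` of
#'   the chosen unit, `rmse_ms` of inter-tap intervals vs the beat period,
#'   and `median_iti_ms`.
#' @export
infer_unit <- function(taps_ms, tempo) {
  stopifnot(inherits(tempo, "tempo_spec"))
  if (length(taps_ms) < 4L) stop("at least 4 taps required to infer a unit")
  if (any(diff(taps_ms) <= 0)) stop("tap times must be strictly increasing")
  iti <- diff(taps_ms)
  candidates <- c(subdivision = tempo$event_ms,
                  beat = tempo$beat_ms,
                  bar = tempo$cycle_ms)
  med <- stats::median(iti)
  unit <- names(candidates)[which.min(abs(med - candidates))]
  list(unit = unit,
       period_ms = unname(candidates[unit]),
       rmse_ms = sqrt(mean((iti - tempo$beat_ms)^2)),
       median_iti_ms = med)
}

#' Target-onset grid for a tapping unit
#'
#' Builds the grid of target onsets for the chosen unit, anchored to the
#' stimulus beat times: the beat grid itself, its 4-fold refinement
#' (subdivision = one event), or every 3rd beat (bar = 12 events = 3
#' beats).
#'
#' @param beat_times_ms Theoretical beat onsets of the trial (ms).
#' @param unit "subdivision", "beat" or "bar".
#' @param tempo A `tempo_spec`.
#' @return Numeric vector of target onsets in ms.
#' @export
unit_grid <- function(beat_times_ms, unit = c("beat", "subdivision", "bar"),
                      tempo) {
  unit <- match.arg(unit)
  stopifnot(inherits(tempo, "tempo_spec"), length(beat_times_ms) >= 1L)
  switch(unit,
    beat = beat_times_ms,
    subdivision = as.vector(outer(0:3 * tempo$event_ms, beat_times_ms, `+`)),
    bar = beat_times_ms[seq(1L, length(beat_times_ms), by = 3L)]
  )
}

#' Map tap times to circular phases
#'
#' Each tap is referred to its nearest target onset; the signed offset,
#' divided by the unit period and scaled to radians, is wrapped to
#' [0, 2*pi) with the target at 0.  A tap a quarter period late has phase
#' pi/2; a quarter period early, 3*pi/2.
#'
#' @param taps_ms Tap times (ms), non-empty.
#' @param targets_ms Target onset grid (ms).
#' @param period_ms Unit period (> 0).
#' @return Numeric vector of phases in [0, 2*pi).
#' @export
taps_to_phases <- function(taps_ms, targets_ms, period_ms) {
  if (length(taps_ms) == 0L) stop("empty tap list")
  stopifnot(period_ms > 0, length(targets_ms) >= 1L)
  offsets <- vapply(taps_ms, function(tp) {
    tp - targets_ms[which.min(abs(tp - targets_ms))]
  }, numeric(1))
  (offsets / period_ms * 2 * pi) %% (2 * pi)
}

#' Circular summary of tap phases
#'
#' Mean resultant vector of the unit phasors `exp(i * phase)`.  The
#' resultant length R (0..1) measures phase concentration; circular
#' variance is 1 - R.  The mean direction, wrapped to (-pi, pi], converts
#' to a signed asynchrony in ms (positive = taps lag the target).
#'
#' @param phases Phases in radians (any real values; used modulo 2*pi).
#' @param period_ms Period of the circular scale in ms.
#' @return An object of class `circular_summary`: list with `n`, `R`,
#'   `circ_variance`, `mean_direction` (radians in (-pi, pi]),
#'   `asynchrony_ms`.
#' @export
circular_summary <- function(phases, period_ms) {
  if (length(phases) == 0L) stop("no phases")
  stopifnot(period_ms > 0)
  v <- mean(exp(1i * phases))
  R <- Mod(v)
  dir <- if (R > 0) wrap_pi(Arg(v)) else NA_real_
  structure(
    list(n = length(phases), R = R, circ_variance = 1 - R,
         mean_direction = dir,
         asynchrony_ms = if (is.na(dir)) NA_real_ else dir / (2 * pi) * period_ms),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary: n=%d, R=%.3f, circ var=%.3f, asynchrony=%+.1f ms>\n",
    x$n, x$R, x$circ_variance, x$asynchrony_ms))
  invisible(x)
}

#' Score one beat-tapping trial
#'
#' Chains tapping-unit inference, target-grid construction, phase mapping,
#' and the circular summary for a single trial.
#'
#' @param taps_ms Tap times (ms).
#' @param tempo A `tempo_spec`.
#' @param beat_times_ms Theoretical beat onsets of the trial; defaults to
#'   `n_cycles` cycles from time 0.
#' @param n_cycles Used only when `beat_times_ms` is NULL.
#' @return Data frame with one row: `unit`, `period_ms`, `rmse_ms`, `n_taps`,
#'   `R`, `circ_variance`, `asynchrony_ms`.
#' @export
score_tap_trial <- function(taps_ms, tempo, beat_times_ms = NULL,
                            n_cycles = 40L) {
  if (is.null(beat_times_ms)) beat_times_ms <- beat_times(tempo, n_cycles)
  u <- infer_unit(taps_ms, tempo)
  grid <- unit_grid(beat_times_ms, u$unit, tempo)
  ph <- taps_to_phases(taps_ms, grid, u$period_ms)
  cs <- circular_summary(ph, u$period_ms)
  data.frame(unit = u$unit, period_ms = u$period_ms, rmse_ms = u$rmse_ms,
             n_taps = length(taps_ms), R = cs$R,
             circ_variance = cs$circ_variance,
             asynchrony_ms = cs$asynchrony_ms)
}

#' Participant-level exclusion rule for beat tapping
#'
#' A participant who tapped at the theoretical beat unit in fewer than
#' `min_beat_conditions` of their conditions did not follow the instructed
#' strategy in the majority of conditions and is excluded from the
#' beat-tapping analyses.
#'
#' @param units Character vector of inferred units, one per condition
#'   (normally 8), or a data frame with a `unit` column.
#' @param min_beat_conditions Minimum number of beat-unit conditions needed
#'   to keep the participant (default 4 of 8; 0 keeps everyone).
#' @return List with `keep` (logical), `n_beat`, `n_conditions`, `units`.
#' @export
apply_exclusion <- function(units, min_beat_conditions = 4L) {
  if (is.data.frame(units)) units <- units$unit
  n_beat <- sum(units == "beat")
  list(keep = n_beat >= min_beat_conditions,
       n_beat = n_beat, n_conditions = length(units), units = units)
}
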