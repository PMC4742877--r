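# End-to-end orchestration: cohort -> SSEP metrics -> tapping metrics ->
# prediction metrics -> measure table -> brain-behavior regressions.

#' Per-participant SSEP measures from a synthetic cohort
#'
#' Runs the full SSEP chain ([analyze_condition()]) on every EEG condition
#' of every participant and aggregates with [aggregate_indices()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param highpass Apply the 0.1 Hz high-pass stage (default TRUE).
#' @return List with `conditions` (tidy per-condition data frame) and
#'   `participants` (one row each: `mean_beat_amp_uv`, `mean_selectivity`,
#'   `mean_nonbeat_amp_uv`, `endo_mean_uv`, `endo_slow_uv`, `endo_fast_uv`,
#'   `nonbeat_slow_uv`, `nonbeat_fast_uv`).
#' @export
cohort_ssep_measures <- function(cohort, highpass = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cond_rows <- list()
  part_rows <- list()
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    rows <- lapply(p$eeg, function(e) {
      tempo <- tempo_spec(e$tempo)
      prof <- analyze_condition(e$recording, e$rate_hz, e$onsets_s, tempo,
                                rhythm = e$rhythm, highpass = highpass)
      data.frame(participant = i, rhythm = e$rhythm, tempo = e$tempo,
                 beat_amp_uv = prof$amp_uv[prof$beat_index],
                 z_beat = selectivity_zscore(prof),
                 nonbeat_amp_uv = mean(prof$amp_uv[-prof$beat_index]))
    })
    conds <- do.call(rbind, rows)
    agg <- aggregate_indices(conds)
    cond_rows[[i]] <- conds
    part_rows[[i]] <- data.frame(
      participant = i,
      mean_beat_amp_uv = agg$mean_beat_amp_uv,
      mean_selectivity = agg$mean_selectivity,
      mean_nonbeat_amp_uv = agg$mean_nonbeat_amp_uv,
      endo_mean_uv = agg$endo_mean_uv,
      endo_slow_uv = agg$slow$endo_uv, endo_fast_uv = agg$fast$endo_uv,
      nonbeat_slow_uv = agg$slow$nonbeat_amp_uv,
      nonbeat_fast_uv = agg$fast$nonbeat_amp_uv)
  }
  list(conditions = do.call(rbind, cond_rows),
       participants = do.call(rbind, part_rows))
}

#' Per-participant beat-tapping measures from a synthetic cohort
#'
#' Scores every tapping trial with [score_tap_trial()] and applies the
#' beat-unit exclusion rule.
#'
#' @param cohort A `synthetic_cohort`.
#' @param min_beat_conditions Exclusion threshold (default 4 of 8).
#' @return List with `trials` (tidy per-trial data frame) and
#'   `participants` (rows: `mean_asynchrony_ms`, `mean_circ_variance`,
#'   `n_beat_conditions`, `keep`).
#' @export
cohort_tapping_measures <- function(cohort, min_beat_conditions = 4L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  trial_rows <- list()
  part_rows <- list()
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    rows <- lapply(p$tap_trials, function(tt) {
      tempo <- tempo_spec(tt$tempo)
      sc <- score_tap_trial(tt$taps_ms, tempo, beat_times_ms = tt$beat_times_ms)
      cbind(data.frame(participant = i, rhythm = tt$rhythm, tempo = tt$tempo),
            sc)
    })
    trials <- do.call(rbind, rows)
    excl <- apply_exclusion(trials$unit, min_beat_conditions)
    beat_rows <- trials[trials$unit == "beat", , drop = FALSE]
    part_rows[[i]] <- data.frame(
      participant = i,
      mean_asynchrony_ms = if (excl$keep) mean(beat_rows$asynchrony_ms) else NA_real_,
      mean_circ_variance = if (excl$keep) mean(beat_rows$circ_variance) else NA_real_,
      n_beat_conditions = excl$n_beat,
      keep = excl$keep)
    trial_rows[[i]] <- trials
  }
  list(trials = do.call(rbind, trial_rows),
       participants = do.call(rbind, part_rows))
}

#' Per-participant temporal-prediction measures from a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with one row per participant: `prediction_index`,
#'   `n_valid_trials`, `pacing_async_ms`, `pacing_async_sd_ms`.
#' @export
cohort_prediction_measures <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(seq_along(cohort$participants), function(i) {
    p <- cohort$participants[[i]]
    trials <- do.call(rbind, lapply(p$pacing_trials, function(tr)
      score_pacing_trial(tr$taps_ms, tr$pacing)))
    s <- summarize_task3(trials)
    data.frame(participant = i, prediction_index = s$mean_index,
               n_valid_trials = s$n_valid,
               pacing_async_ms = s$mean_asynchrony_ms,
               pacing_async_sd_ms = s$sd_asynchrony_ms)
  })
  do.call(rbind, rows)
}

#' Run the whole study pipeline on a synthetic cohort
#'
#' Executes stimuli-aware SSEP extraction, beat-tapping scoring with
#' exclusion, prediction-index computation, assembles the per-participant
#' measure table, and fits the three brain-behavior regressions
#' (synchronization accuracy, synchronization precision, and temporal
#' prediction, each on the SSEP beat measure, the endogenous index, and
#' years of musical training) plus the slow/fast-tempo and non-beat
#' follow-up analyses.  Participants failing the beat-unit exclusion enter
#' the measure table with missing tapping measures and are removed
#' listwise from the regressions that need them.
#'
#' @param cohort A `synthetic_cohort` (or a `cohort_spec`, which is then
#'   simulated first).
#' @param ssep_measure Which beat-SSEP measure feeds the regressions:
#'   `"selectivity"` (mean beat z-score; default) or `"amplitude"` (mean
#'   beat amplitude in microvolts).
#' @param out_dir Optional directory; when given, tidy CSVs of all stage
#'   outputs are written there.
#' @return A list of class `study_results`: `measures` (per-participant
#'   table), `regressions` (list `accuracy`, `precision`, `prediction`),
#'   `followups` (list with `prediction_slow_fast`, `nonbeat_slow_fast`,
#'   `nonbeat_accuracy_r`, `training_prediction_r`), `ssep`, `tapping`,
#'   `prediction`, `excluded` (participant ids).
#' @export
run_study <- function(cohort, ssep_measure = c("selectivity", "amplitude"),
                      out_dir = NULL) {
  ssep_measure <- match.arg(ssep_measure)
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))

  ssep <- cohort_ssep_measures(cohort)
  tapping <- cohort_tapping_measures(cohort)
  prediction <- cohort_prediction_measures(cohort)

  measures <- Reduce(function(a, b) merge(a, b, by = "participant"),
                     list(ssep$participants,
                          tapping$participants[, c("participant",
                                                   "mean_asynchrony_ms",
                                                   "mean_circ_variance",
                                                   "keep")],
                          prediction))
  measures$training_years <- cohort$ground_truth$training_years
  measures$beat_ssep <- if (ssep_measure == "selectivity")
    measures$mean_selectivity else measures$mean_beat_amp_uv

  preds <- c("beat_ssep", "endo_mean_uv", "training_years")
  regressions <- list(
    accuracy = multiple_regression(measures, "mean_asynchrony_ms", preds),
    precision = multiple_regression(measures, "mean_circ_variance", preds),
    prediction = multiple_regression(measures, "prediction_index", preds)
  )
  followups <- list(
    prediction_slow_fast = multiple_regression(
      measures, "prediction_index", c("endo_slow_uv", "endo_fast_uv")),
    nonbeat_slow_fast = multiple_regression(
      measures, "prediction_index", c("nonbeat_slow_uv", "nonbeat_fast_uv")),
    nonbeat_accuracy_r = pearson_correlation(
      standardize(measures$mean_nonbeat_amp_uv), measures$mean_asynchrony_ms),
    training_prediction_r = pearson_correlation(
      measures$training_years, measures$prediction_index)
  )

  res <- structure(
    list(measures = measures, regressions = regressions,
         followups = followups, ssep = ssep, tapping = tapping,
         prediction = prediction,
         excluded = measures$participant[!measures$keep]),
    class = "study_results"
  )
  if (!is.null(out_dir)) write_study_results(res, out_dir)
  res
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results: %d participants (%d excluded from tapping)>\n",
              nrow(x$measures), length(x$excluded)))
  for (nm in names(x$regressions)) {
    cat(sprintf("-- %s --\n", nm))
    print(x$regressions[[nm]])
  }
  invisible(x)
}

#' Write tidy CSVs of all study outputs
#'
#' @param results A `study_results` object.
#' @param out_dir Output directory (created if missing).
#' @export
write_study_results <- function(results, out_dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(results$measures, "measures.csv")
  w(results$ssep$conditions, "ssep_conditions.csv")
  w(results$tapping$trials, "tapping_trials.csv")
  w(results$prediction, "prediction_participants.csv")
  reg_rows <- do.call(rbind, lapply(names(results$regressions), function(nm) {
    r <- results$regressions[[nm]]
    cbind(data.frame(model = nm, r_squared = r$r_squared,
                     adj_r_squared = r$adj_r_squared, f = r$f_stat,
                     df1 = r$df[1], df2 = r$df[2], p = r$p_value, n = r$n),
          r$coefficients)
  }))
  w(reg_rows, "regressions.csv")
  invisible(out_dir)
}
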