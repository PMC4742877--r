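# Prediction-tracking index from tapping with tempo-changing sequences.
#
# The lag-0 cross-correlation between inter-tap intervals (ITIs) and the
# pacing inter-onset intervals (IOIs) is high when the tapper anticipates
# the ongoing tempo change; the lag-1 cross-correlation (ITI against the
# previous IOI) is high when the tapper merely copies the interval just
# heard.  Their ratio per trial is > 1 for predominantly predictive
# tapping and < 1 for tracking.

#' Align taps to pacing onsets
#'
#' Each tap is matched to its nearest pacing onset, accepted when it falls
#' within half the local IOI of that onset; at most one tap (the nearest)
#' is kept per onset.  ITIs between taps matched to *adjacent* onsets are
#' paired with the IOI spanning those onsets; intervals broken by a missed
#' tap are dropped (pairwise deletion, no interpolation).
#'
#' @param taps_ms Tap times in ms (>= 3).
#' @param onsets_ms Pacing onsets in ms (>= 3).
#' @return An object of class `aligned_series`: list with `pairs` (data
#'   frame: `onset_index`, `iti_ms`, `ioi_ms`, `ioi_prev_ms`),
#'   `asynchronies_ms` (per matched tap), `n_matched`.
#' @export
align_taps <- function(taps_ms, onsets_ms) {
  if (length(taps_ms) < 3L) stop("at least 3 taps required")
  if (length(onsets_ms) < 3L) stop("at least 3 onsets required")
  taps_ms <- sort(taps_ms)
  n_on <- length(onsets_ms)
  iois <- diff(onsets_ms)

  # nearest onset per tap, tolerance = half the IOI on the side the tap falls
  cand <- findInterval(taps_ms, onsets_ms)  # onset index at or before tap
  match_of <- rep(NA_integer_, length(taps_ms))
  offset <- rep(NA_real_, length(taps_ms))
  for (i in seq_along(taps_ms)) {
    j <- cand[i]
    jj <- if (j < 1L) 1L else if (j >= n_on) n_on else {
      if (taps_ms[i] - onsets_ms[j] <= onsets_ms[j + 1L] - taps_ms[i]) j else j + 1L
    }
    d <- taps_ms[i] - onsets_ms[jj]
    local_ioi <- if (d >= 0) {
      if (jj < n_on) iois[jj] else iois[n_on - 1L]
    } else {
      if (jj > 1L) iois[jj - 1L] else iois[1L]
    }
    if (abs(d) <= local_ioi / 2) {
      match_of[i] <- jj
      offset[i] <- d
    }
  }
  keep <- !is.na(match_of)
  # one tap per onset: keep the nearest
  if (any(keep)) {
    ord <- order(abs(offset[keep]))
    idx <- which(keep)[ord]
    seen <- logical(n_on)
    for (i in idx) {
      if (seen[match_of[i]]) keep[i] <- FALSE else seen[match_of[i]] <- TRUE
    }
  }
  m_tap <- which(keep)
  if (length(m_tap) < 2L) stop("fewer than 2 taps matched to onsets")
  m_on <- match_of[m_tap]
  o <- order(m_on)
  m_tap <- m_tap[o]; m_on <- m_on[o]

  adj <- which(diff(m_on) == 1L)  # consecutive matched taps on adjacent onsets
  pairs <- data.frame(
    onset_index = m_on[adj + 1L],
    iti_ms = taps_ms[m_tap[adj + 1L]] - taps_ms[m_tap[adj]],
    ioi_ms = iois[m_on[adj]],
    ioi_prev_ms = ifelse(m_on[adj] > 1L, iois[pmax(m_on[adj] - 1L, 1L)], NA_real_)
  )
  structure(
    list(pairs = pairs, asynchronies_ms = offset[m_tap],
         n_matched = length(m_tap)),
    class = "aligned_series"
  )
}

#' Lagged ITI-IOI cross-correlation
#'
#' Pearson correlation between the inter-tap intervals and the pacing IOIs
#' at lag 0 (same interval) or lag -1 (previous interval).
#'
#' @param aligned An `aligned_series`.
#' @param lag 0 or -1.
#' @return Correlation coefficient in [-1, 1].
#' @export
lag_crosscorr <- function(aligned, lag = 0) {
  stopifnot(inherits(aligned, "aligned_series"), lag %in% c(0, -1))
  p <- aligned$pairs
  x <- p$iti_ms
  y <- if (lag == 0) p$ioi_ms else p$ioi_prev_ms
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("fewer than 3 overlapping pairs at this lag")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance in one of the interval series")
  stats::cor(x[ok], y[ok])
}

#' Prediction-tracking index of one trial
#'
#' Ratio of the lag-0 to the lag-1 cross-correlation.  When the lag-1
#' (tracking) correlation is at or below `min_r1` the ratio is no longer
#' meaningful as a prediction measure and the trial is flagged invalid
#' (NA) instead of producing an explosive ratio.
#'
#' @param r_lag0,r_lag1 The two cross-correlations.
#' @param min_r1 Validity floor for `r_lag1` (default 0.05).
#' @return The index (> 1 = predominantly predicting, < 1 = tracking), or
#'   NA when invalid.
#' @export
prediction_index <- function(r_lag0, r_lag1, min_r1 = 0.05) {
  if (is.na(r_lag0) || is.na(r_lag1) || r_lag1 <= min_r1) return(NA_real_)
  r_lag0 / r_lag1
}

#' Score one pacing trial
#'
#' @param taps_ms Tap times in ms.
#' @param pacing A `pacing_sequence` (or numeric vector of onsets in ms).
#' @param min_r1 Validity floor passed to [prediction_index()].
#' @return One-row data frame: `r_lag0`, `r_lag1`, `index`, `valid`,
#'   `mean_async_ms`, `sd_async_ms`, `n_pairs`, `n_matched`.
#' @export
score_pacing_trial <- function(taps_ms, pacing, min_r1 = 0.05) {
  onsets <- if (inherits(pacing, "pacing_sequence")) pacing$onsets_ms else pacing
  al <- align_taps(taps_ms, onsets)
  r0 <- lag_crosscorr(al, 0)
  r1 <- lag_crosscorr(al, -1)
  idx <- prediction_index(r0, r1, min_r1 = min_r1)
  data.frame(r_lag0 = r0, r_lag1 = r1, index = idx, valid = !is.na(idx),
             mean_async_ms = mean(al$asynchronies_ms),
             sd_async_ms = stats::sd(al$asynchronies_ms),
             n_pairs = nrow(al$pairs), n_matched = al$n_matched)
}

#' Summarize the tempo-changing tapping task
#'
#' Averages the prediction index over valid trials and pools the tap
#' asynchronies across all trials (weighted by the number of matched taps,
#' with the pooled SD combining within- and between-trial variance).
#'
#' @param trials Data frame of per-trial results as returned by
#'   [score_pacing_trial()] (rows stacked).
#' @return List of class `prediction_result`: `mean_index`, `n_valid`,
#'   `n_trials`, `mean_asynchrony_ms`, `sd_asynchrony_ms`, `trials`.
#' @export
summarize_task3 <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("index", "valid", "mean_async_ms", "sd_async_ms",
                  "n_matched") %in% names(trials)))
  valid <- trials$valid & !is.na(trials$index)
  if (!any(valid)) stop("no valid trials")
  w <- trials$n_matched
  mu <- sum(w * trials$mean_async_ms) / sum(w)
  # pooled variance: within-trial + between-trial-mean components
  ss <- sum((w - 1) * trials$sd_async_ms^2 + w * (trials$mean_async_ms - mu)^2)
  structure(
    list(mean_index = mean(trials$index[valid]),
         n_valid = sum(valid), n_trials = nrow(trials),
         mean_asynchrony_ms = mu,
         sd_asynchrony_ms = sqrt(ss / (sum(w) - 1)),
         trials = trials),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result: mean index %.3f (%d/%d valid trials), asynchrony %+.1f +/- %.1f ms>\n",
    x$mean_index, x$n_valid, x$n_trials,
    x$mean_asynchrony_ms, x$sd_asynchrony_ms))
  invisible(x)
}
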