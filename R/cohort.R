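# Full synthetic study cohorts with planted brain-behavior structure.

#' Default planted correlation matrix for a synthetic cohort
#'
#' Correlations among the six per-participant latent traits:
#' `amp` (beat SSEP amplitude), `endo` (endogenous-entrainment index),
#' `async` (tap asynchrony level; also drives the pacing-task lag),
#' `alpha` (prediction weight in the tempo task), `train` (years of
#' musical training), `motor` (motor-noise level).  The defaults plant the
#' qualitative structure under study -- beat SSEP with tapping asynchrony
#' (0.7), endogenous index with prediction weight (0.8), training with
#' prediction weight (0.4) and with lower motor noise (-0.6) -- and form a
#' positive semi-definite matrix.
#'
#' @return A 6 x 6 correlation matrix.
#' @export
default_cohort_correlations <- function() {
  nm <- c("amp", "endo", "async", "alpha", "train", "motor")
  S <- diag(6)
  dimnames(S) <- list(nm, nm)
  S["amp", "async"] <- S["async", "amp"] <- 0.7
  S["endo", "alpha"] <- S["alpha", "endo"] <- 0.8
  S["train", "alpha"] <- S["alpha", "train"] <- 0.4
  S["train", "motor"] <- S["motor", "train"] <- -0.6
  S
}

#' Specification of a synthetic cohort
#'
#' Group-level means and SDs default to the orders of magnitude of the
#' modeled study: beat SSEP amplitudes of 0.21/0.21/0.12/0.13 (unsyncopated)
#' and 0.09/0.08/0.09/0.12 microvolts (syncopated) across the four tempi,
#' non-beat amplitudes around 0.03-0.05 microvolts, tapping asynchronies of
#' tens to hundreds of ms (negative mean asynchrony), prediction weights
#' yielding indices near 1.06, and 12.4 +/- 6.8 years of musical training.
#'
#' @param n_participants Number of participants (default 18).
#' @param correlations 6 x 6 latent correlation matrix (see
#'   [default_cohort_correlations()]); must be positive semi-definite.
#' @param eeg List of EEG simulation settings: `n_channels`, `rate_hz`,
#'   `n_trials`, `noise_white_sd`, `noise_pink_sd`.  The default desk-scale
#'   profile (8 channels, 128 Hz, 4 trials) keeps whole-cohort simulation
#'   tractable; the pipeline is agnostic to these sizes.
#' @param n_pacing_trials Number of tempo-changing tapping trials
#'   (default 12: the six arrangements twice).
#' @param n_offunit Number of participants simulated as tapping off the
#'   beat unit (subdivision) in 7 of 8 conditions, exercising the
#'   exclusion rule (default 2).
#' @param endo_sd Between-participant SD of the endogenous index
#'   (microvolts, default 0.05).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 18L,
                        correlations = default_cohort_correlations(),
                        eeg = list(n_channels = 8L, rate_hz = 128,
                                   n_trials = 4L, noise_white_sd = 1,
                                   noise_pink_sd = 1),
                        n_pacing_trials = 12L,
                        n_offunit = 2L,
                        endo_sd = 0.05,
                        seed = 1L) {
  stopifnot(n_participants >= 1L, is.matrix(correlations),
            nrow(correlations) == 6L, ncol(correlations) == 6L)
  if (is.null(colnames(correlations))) {
    nm <- c("amp", "endo", "async", "alpha", "train", "motor")
    dimnames(correlations) <- list(nm, nm)
  }
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("planted correlation matrix is not positive semi-definite")
  structure(
    list(n_participants = as.integer(n_participants),
         correlations = correlations, eeg = eeg,
         n_pacing_trials = as.integer(n_pacing_trials),
         n_offunit = as.integer(n_offunit), endo_sd = endo_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# group-level parameter table (rows = tempo 1..4)
.cohort_group_params <- function() {
  list(
    unsync_beat_mu = c(0.21, 0.21, 0.12, 0.13),
    unsync_beat_sd = c(0.11, 0.11, 0.05, 0.08),
    endo_mu = c(-0.12, -0.13, -0.03, -0.01),  # syncopated minus unsyncopated
    nonbeat_mu = list(unsyncopated = c(0.03, 0.03, 0.03, 0.03),
                      syncopated   = c(0.04, 0.05, 0.04, 0.03)),
    async_mu = list(unsyncopated = c(-264.7, -156.8, -20.75, -14.54),
                    syncopated   = c(-100.1, -1.4, -34.8, -20.0)),
    async_sd = list(unsyncopated = c(162.9, 131.3, 71.17, 50.97),
                    syncopated   = c(194.6, 179.8, 102.6, 39.7)),
    train_mu = 12.44, train_sd = 6.79,
    delta3_mu = -36.04, delta3_sd = 15.40
  )
}

#' Simulate a full synthetic study cohort
#'
#' Draws per-participant latent traits from the planted correlation
#' structure, then generates for each participant: 8 EEG condition
#' recordings (2 rhythms x 4 tempi, with the participant's beat and
#' non-beat SSEP amplitudes planted at the 12 envelope frequencies), 8
#' beat-tapping trials, and `n_pacing_trials` tempo-changing tapping
#' trials, plus years of musical training.  A ground-truth table of all
#' planted parameters is returned for recovery testing.
#'
#' @param spec A `cohort_spec`.
#' @return A list of class `synthetic_cohort` with `ground_truth` (data
#'   frame), `participants` (list; each has `eeg` -- a list of 8 condition
#'   simulations --, `tap_trials`, `pacing_trials`), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gp <- .cohort_group_params()
  n <- spec$n_participants
  if (n < 2L) stop("a cohort needs at least 2 participants")

  # the correlation structure is planted as ground truth: for cohorts large
  # enough to support it, the latent draw is rescaled so its sample
  # correlation matrix equals the specification exactly (otherwise the
  # sampling noise of the latents themselves, ~1/sqrt(n), would dominate
  # what recovery tests measure)
  z <- with_seed(spec$seed, {
    MASS::mvrnorm(n, mu = rep(0, 6), Sigma = spec$correlations,
                  empirical = n > 6L)
  })
  colnames(z) <- colnames(spec$correlations)

  offunit <- rep(FALSE, n)
  if (spec$n_offunit > 0L)
    offunit[seq.int(n, by = -1L, length.out = min(spec$n_offunit, n))] <- TRUE

  # prediction weights centered so the resulting indices land near the
  # observed 1.06 +/- 0.02 distribution
  alpha <- pmin(1, pmax(0.05, 0.65 + 0.055 * z[, "alpha"]))
  train <- pmax(0, gp$train_mu + gp$train_sd * z[, "train"])
  sigma_motor <- pmin(60, pmax(12, 35 * exp(0.3 * z[, "motor"])))
  delta3 <- gp$delta3_mu + gp$delta3_sd * z[, "async"]

  conditions <- expand.grid(rhythm = c("unsyncopated", "syncopated"),
                            tempo = 1:4, stringsAsFactors = FALSE)

  participants <- vector("list", n)
  gt_rows <- vector("list", n)
  for (i in seq_len(n)) {
    unsync_beat <- pmax(0.02, gp$unsync_beat_mu + gp$unsync_beat_sd * z[i, "amp"])
    endo <- gp$endo_mu + spec$endo_sd * z[i, "endo"]
    sync_beat <- pmax(0.01, unsync_beat + endo)

    eeg_list <- vector("list", nrow(conditions))
    tap_rows <- vector("list", nrow(conditions))
    for (ci in seq_len(nrow(conditions))) {
      rhythm <- conditions$rhythm[ci]
      tp <- conditions$tempo[ci]
      tempo <- tempo_spec(tp)
      beat_amp <- if (rhythm == "unsyncopated") unsync_beat[tp] else sync_beat[tp]
      nb <- gp$nonbeat_mu[[rhythm]][tp]
      amps <- rep(nb, 12)
      amps[3] <- beat_amp
      es <- eeg_sim_spec(
        planted = data.frame(freq_hz = expected_frequencies(tempo),
                             amp_uv = amps),
        n_channels = spec$eeg$n_channels, rate_hz = spec$eeg$rate_hz,
        n_trials = spec$eeg$n_trials,
        noise_white_sd = spec$eeg$noise_white_sd,
        noise_pink_sd = spec$eeg$noise_pink_sd,
        seed = spec$seed + 7919L * i + 101L * ci)
      eeg_list[[ci]] <- c(simulate_eeg(es),
                          list(rhythm = rhythm, tempo = tp))

      # one beat-tapping trial per condition (the tapped 11th trial)
      n_beats <- floor(33000 / tempo$beat_ms)
      bt <- beat_times(tempo, n_cycles = ceiling(n_beats / 3))[seq_len(n_beats)]
      delta2 <- gp$async_mu[[rhythm]][tp] +
        gp$async_sd[[rhythm]][tp] * 0.8 * z[i, "async"]
      # keep the planted lag inside half a unit period
      delta2 <- max(min(delta2, tempo$beat_ms / 2 - 10), -tempo$beat_ms / 2 + 10)
      unit_i <- if (offunit[i] && ci <= 7L) "subdivision" else "beat"
      unit_period <- switch(unit_i, subdivision = tempo$event_ms,
                            beat = tempo$beat_ms, bar = tempo$cycle_ms)
      delta2 <- max(min(delta2, unit_period / 2 - 5), -unit_period / 2 + 5)
      ts <- tapper_spec(mode = "beat", delta_ms = delta2,
                        sigma_motor_ms = min(sigma_motor[i], unit_period / 8),
                        unit = unit_i,
                        seed = spec$seed + 104729L * i + 13L * ci)
      taps <- simulate_beat_tapper(ts, bt, tempo)
      tap_rows[[ci]] <- list(rhythm = rhythm, tempo = tp, taps_ms = taps,
                             beat_times_ms = bt, delta_ms = delta2)
    }

    pacing_trials <- vector("list", spec$n_pacing_trials)
    for (tr in seq_len(spec$n_pacing_trials)) {
      arr <- ((tr - 1L) %% 6L) + 1L
      # the pacing sequences are fixed study materials: identical for
      # every participant (seed independent of i)
      pac <- generate_pacing_sequence(arr, seed = spec$seed + 31L * tr)
      # interval noise for the tempo task is calibrated so the pooled
      # asynchrony SD lands near the observed ~40 ms (noise accumulates
      # across the trial because no error correction is modeled, so this
      # is much smaller than the beat-tapping motor noise)
      sigma_tempo <- min(15, max(3, 6.5 * exp(0.3 * z[i, "motor"])))
      ts <- tapper_spec(mode = "tempo", delta_ms = delta3[i],
                        sigma_motor_ms = sigma_tempo,
                        alpha = alpha[i],
                        seed = spec$seed + 15485863L + 977L * i + tr)
      pacing_trials[[tr]] <- list(pacing = pac,
                                  taps_ms = simulate_tempo_tapper(ts, pac))
    }

    participants[[i]] <- list(eeg = eeg_list, tap_trials = tap_rows,
                              pacing_trials = pacing_trials)
    gt_rows[[i]] <- data.frame(
      participant = i,
      z_amp = z[i, "amp"], z_endo = z[i, "endo"], z_async = z[i, "async"],
      z_alpha = z[i, "alpha"], z_train = z[i, "train"], z_motor = z[i, "motor"],
      mean_unsync_beat_uv = mean(unsync_beat),
      mean_endo_uv = mean(sync_beat - unsync_beat),
      alpha = alpha[i], delta3_ms = delta3[i],
      sigma_motor_ms = sigma_motor[i],
      training_years = train[i], offunit = offunit[i])
  }

  structure(
    list(ground_truth = do.call(rbind, gt_rows),
         participants = participants,
         conditions = conditions,
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d participants, %d EEG conditions, %d pacing trials each>\n",
    x$spec$n_participants, nrow(x$conditions), x$spec$n_pacing_trials))
  invisible(x)
}
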