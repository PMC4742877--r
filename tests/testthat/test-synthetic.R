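# Synthetic EEG, tapper and cohort generators: ground-truth recovery.

test_that("noise-free planted sinusoid is recovered exactly by the spectral chain", {
  spec <- eeg_sim_spec(planted = c("2.5" = 0.2), n_channels = 2, rate_hz = 128,
                       n_trials = 3, noise_white_sd = 0, noise_pink_sd = 0,
                       seed = 5)
  sim <- simulate_eeg(spec)
  prof <- analyze_condition(sim$recording, sim$rate_hz, sim$onsets_s,
                            tempo_spec(3), highpass = FALSE)
  expect_equal(prof$amp_uv[prof$beat_index], 0.2, tolerance = 1e-6 / 0.2)
  # the 11 non-planted harmonics stay at zero
  expect_lt(max(abs(prof$amp_uv[-prof$beat_index])), 1e-10)
})

test_that("EEG simulation is seed-reproducible and validates frequencies", {
  spec <- eeg_sim_spec(planted = c("2.5" = 0.1), n_channels = 2, rate_hz = 64,
                       n_trials = 2, seed = 9)
  a <- simulate_eeg(spec)
  b <- simulate_eeg(spec)
  expect_identical(a$recording, b$recording)
  spec2 <- eeg_sim_spec(planted = c("2.5" = 0.1), n_channels = 2, rate_hz = 64,
                        n_trials = 2, seed = 10)
  expect_false(identical(a$recording, simulate_eeg(spec2)$recording))
  expect_error(eeg_sim_spec(planted = c("40" = 0.1), rate_hz = 64), "Nyquist")
  expect_error(eeg_sim_spec(planted = c("2.5" = -0.1), rate_hz = 64))
})

test_that("doubling the planted amplitude doubles the recovered amplitude", {
  rec_amp <- function(A, seed) {
    spec <- eeg_sim_spec(planted = stats::setNames(A, "2.5"), n_channels = 4,
                         rate_hz = 64, n_trials = 10, seed = seed)
    sim <- simulate_eeg(spec)
    prof <- analyze_condition(sim$recording, sim$rate_hz, sim$onsets_s,
                              tempo_spec(3), highpass = FALSE)
    prof$amp_uv[prof$beat_index]
  }
  a1 <- mean(sapply(1:6, function(s) rec_amp(0.2, s)))
  a2 <- mean(sapply(1:6, function(s) rec_amp(0.4, s)))
  expect_equal(a2 / a1, 2, tolerance = 0.15)
})

test_that("beat tapper plants lag, unit and miss rate as specified", {
  t3 <- tempo_spec(3)
  bt <- beat_times(t3, n_cycles = 14)
  # deterministic lag: every asynchrony is exactly delta
  s0 <- tapper_spec("beat", delta_ms = -50, sigma_motor_ms = 0, seed = 2)
  taps <- simulate_beat_tapper(s0, bt, t3)
  sc <- score_tap_trial(taps, t3, beat_times_ms = bt)
  expect_equal(sc$R, 1)
  expect_equal(sc$circ_variance, 0)
  expect_equal(sc$asynchrony_ms, -50)
  # subdivision tapper: median ITI = event duration, unit inferred back
  ssub <- tapper_spec("beat", delta_ms = 0, sigma_motor_ms = 0,
                      unit = "subdivision", seed = 2)
  tsub <- simulate_beat_tapper(ssub, bt, t3)
  u <- infer_unit(tsub, t3)
  expect_equal(u$median_iti_ms, 100)
  expect_equal(u$unit, "subdivision")
  # miss rate thins taps roughly binomially
  sm <- tapper_spec("beat", delta_ms = 0, sigma_motor_ms = 0,
                    miss_rate = 0.5, seed = 4)
  bt_many <- beat_times(t3, n_cycles = 40)  # 120 targets
  n_kept <- length(simulate_beat_tapper(sm, bt_many, t3))
  expect_gt(n_kept, qbinom(0.0005, 120, 0.5))
  expect_lt(n_kept, qbinom(0.9995, 120, 0.5))
  # unsortable output is an error, not silent reordering
  sbad <- tapper_spec("beat", delta_ms = 0, sigma_motor_ms = 400, seed = 6)
  expect_error(simulate_beat_tapper(sbad, bt, t3), "ordering")
})

test_that("tempo tapper realizes the prediction weight alpha", {
  pac <- generate_pacing_sequence(4, seed = 17)
  s1 <- tapper_spec("tempo", delta_ms = 0, sigma_motor_ms = 0, alpha = 1,
                    seed = 3)
  r1 <- score_pacing_trial(simulate_tempo_tapper(s1, pac), pac)
  expect_equal(r1$r_lag0, 1, tolerance = 1e-10)
  expect_gt(r1$index, 1)
  s0 <- tapper_spec("tempo", delta_ms = 0, sigma_motor_ms = 0, alpha = 0,
                    seed = 3)
  r0 <- score_pacing_trial(simulate_tempo_tapper(s0, pac), pac)
  expect_gt(r0$r_lag1, 0.99)
  expect_lt(r0$index, 1)
  # alpha = 0.5 sits between the two interval streams: index near 1
  s5 <- tapper_spec("tempo", delta_ms = 0, sigma_motor_ms = 0, alpha = 0.5,
                    seed = 3)
  r5 <- score_pacing_trial(simulate_tempo_tapper(s5, pac), pac)
  expect_equal(r5$index, 1, tolerance = 0.05)
})

test_that("cohort generation validates its spec and is reproducible", {
  bad <- diag(6)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- 0.9
  bad[1, 3] <- bad[3, 1] <- -0.9   # impossible triangle
  expect_error(cohort_spec(n_participants = 10, correlations = bad),
               "positive semi-definite")
  small <- cohort_spec(n_participants = 3, n_offunit = 1,
                       eeg = list(n_channels = 1, rate_hz = 64, n_trials = 1,
                                  noise_white_sd = 1, noise_pink_sd = 1),
                       n_pacing_trials = 2, seed = 6)
  a <- simulate_cohort(small)
  b <- simulate_cohort(small)
  expect_equal(a$ground_truth, b$ground_truth)
  expect_identical(a$participants[[1]]$eeg[[1]]$recording,
                   b$participants[[1]]$eeg[[1]]$recording)
  expect_equal(nrow(a$ground_truth), 3L)
  expect_length(a$participants[[2]]$eeg, 8L)
  expect_length(a$participants[[2]]$pacing_trials, 2L)
  expect_true(a$ground_truth$offunit[3])
  expect_error(simulate_cohort(cohort_spec(n_participants = 1)),
               "at least 2")
})
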