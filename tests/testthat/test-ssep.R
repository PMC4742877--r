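# Filtering, epoching, spectra, noise subtraction, profiles and indices.

test_that("high-pass filter removes drift and preserves band content", {
  rate <- 256
  n <- rate * 120
  # constant (DC) input is annihilated away from the filter edges
  y <- highpass_filter(rep(1, n), rate)
  expect_lt(max(abs(y[(30 * rate):(90 * rate)])), 1e-4)
  # 10 Hz sinusoid amplitude preserved within 1%
  x <- sin(2 * pi * 10 * (0:(n - 1)) / rate)
  y10 <- highpass_filter(x, rate)
  expect_equal(max(abs(y10[(30 * rate):(90 * rate)])), 1, tolerance = 0.01)
  expect_error(highpass_filter(numeric(0), rate))
  expect_error(highpass_filter(x, rate, cutoff_hz = 200))
})

test_that("epoch averaging recovers the trial-locked component", {
  rate <- 64
  # identical epochs: average equals any one epoch
  epoch <- sin(2 * pi * 2 * (0:(rate - 1)) / rate)
  x <- rep(epoch, 5)
  onsets <- (0:4) * 1
  avg <- epoch_and_average(x, rate, onsets, window_s = c(0, 1))
  expect_equal(as.numeric(avg), epoch)
  expect_equal(attr(avg, "n_trials"), 5L)
  # zero-mean noise shrinks ~1/n: planted sinusoid + noise, 100 trials
  n_tr <- 100
  set.seed(21)
  noise <- matrix(rnorm(n_tr * rate), n_tr, rate)
  x2 <- as.vector(t(sweep(noise, 2, epoch, `+`)))
  on2 <- (seq_len(n_tr) - 1)
  avg2 <- epoch_and_average(x2, rate, on2, window_s = c(0, 1))
  mse <- mean((as.numeric(avg2) - epoch)^2)
  expect_lt(mse, 3 / n_tr)  # MSE of the mean of n unit-variance draws ~ 1/n
  # flagged probe trials are excluded before averaging
  x3 <- c(epoch, epoch * 100, epoch)
  avg3 <- epoch_and_average(x3, rate, 0:2, window_s = c(0, 1),
                            exclude_trials = c(FALSE, TRUE, FALSE))
  expect_equal(as.numeric(avg3), epoch)
  expect_error(epoch_and_average(x, rate, onsets = 4.5, window_s = c(0, 1)),
               "bounds")
  expect_error(epoch_and_average(x, rate, onsets = 0:4, window_s = c(0, 1),
                                 exclude_trials = rep(TRUE, 5)))
})

test_that("amplitude spectrum uses the single-sided sinusoid convention", {
  rate <- 1024
  # the standard 32-s epoch gives 0.03125 Hz bins
  sp32 <- amplitude_spectrum(numeric(32 * rate), rate_hz = rate)
  expect_equal(sp32$bin_hz, 0.03125)
  expect_true(all(sp32$amp == 0))
  # integer-period sinusoid of amplitude A yields exactly A at its bin
  n <- 8 * 64
  x <- 0.37 * sin(2 * pi * 2.5 * (0:(n - 1)) / 64 + 0.4)
  sp <- amplitude_spectrum(x, rate_hz = 64)
  i <- which.min(abs(sp$freq_hz - 2.5))
  expect_equal(sp$amp[1, i], 0.37, tolerance = 1e-12)
  expect_lt(max(sp$amp[1, -i]), 1e-12)
  expect_error(amplitude_spectrum(c(1, Inf), rate_hz = 64))
})

test_that("neighbor-bin subtraction uses the 0.09-0.15 Hz stencil", {
  rate <- 64
  n <- 32 * rate  # 0.03125 Hz bins
  sp <- amplitude_spectrum(numeric(n), rate_hz = rate)
  # offsets of 3 and 4 bins = 0.094 and 0.125 Hz; 1, 2 and 5 excluded
  corr <- subtract_noise(sp)
  expect_identical(corr$noise_offsets_bins, c(3L, 4L))
  # flat spectrum -> 0 at every interior bin
  spf <- sp; spf$amp[] <- 0.42
  cf <- subtract_noise(spf)
  interior <- cf$amp[1, !is.na(cf$amp[1, ])]
  expect_true(all(abs(interior) < 1e-12))
  # isolated peak A on zero background: peak unchanged, stencil bins go -A/4
  spk <- sp; j <- 201L; spk$amp[1, j] <- 0.8
  ck <- subtract_noise(spk)
  expect_equal(ck$amp[1, j], 0.8)
  expect_equal(ck$amp[1, j + 3L], -0.2)
  expect_equal(ck$amp[1, j + 4L], -0.2)
  expect_equal(ck$amp[1, j + 1L], 0)   # adjacent bins keep a clean zero
  # peak A + background c at the peak, background c at neighbors -> A
  spb <- sp; spb$amp[] <- 0.05; spb$amp[1, j] <- 0.05 + 0.3
  cb <- subtract_noise(spb)
  expect_equal(cb$amp[1, j], 0.3)
  expect_error(subtract_noise(ck))  # already corrected
})

test_that("channel averaging is an unweighted mean with exclusions", {
  rate <- 64; n <- 32 * rate
  x <- rbind(rep(1, n), rep(3, n))
  sp <- amplitude_spectrum(x, rate_hz = rate)
  one <- channel_average(amplitude_spectrum(x[1, , drop = FALSE], rate))
  expect_equal(one$amp, amplitude_spectrum(x[1, , drop = FALSE], rate)$amp)
  avg <- channel_average(sp)
  expect_equal(avg$amp[1, 1], (1 + 3) / 2)
  only2 <- channel_average(sp, exclude_channels = 1L)
  expect_equal(only2$amp[1, 1], 3)
  expect_error(channel_average(sp, exclude_channels = 1:2))
})

test_that("profile readout picks the bins nearest the 12 expected frequencies", {
  t3 <- tempo_spec(3)
  rate <- 64; n <- 32 * rate
  freqs <- expected_frequencies(t3)
  x <- numeric(n)
  tt <- (0:(n - 1)) / rate
  amps <- c(rep(0.03, 2), 0.21, rep(0.03, 9))  # beat amplitude 0.21 uV
  for (k in 1:12) x <- x + amps[k] * sin(2 * pi * freqs[k] * tt)
  sp <- channel_average(subtract_noise(amplitude_spectrum(x, rate_hz = rate)))
  prof <- extract_profile(sp, t3, rhythm = "unsyncopated")
  expect_equal(prof$amp_uv[prof$beat_index], 0.21, tolerance = 0.02)
  expect_equal(prof$freq_hz, freqs)
  # zeros in, zeros out
  sp0 <- channel_average(subtract_noise(amplitude_spectrum(numeric(n), rate)))
  expect_true(all(extract_profile(sp0, t3)$amp_uv == 0))
  # spectrum too short for the tempo's harmonics
  spshort <- amplitude_spectrum(numeric(32 * 8), rate_hz = 8)
  expect_error(extract_profile(channel_average(subtract_noise(spshort)),
                               tempo_spec(3)),  # event rate 10 Hz > Nyquist 4 Hz
               "range")
})

test_that("selectivity z-score matches direct arithmetic and is scale-free", {
  amps <- c(0.03, 0.03, 0.2, rep(0.03, 9))
  # oracle: population-SD z-score computed in place
  mu <- mean(amps); sig <- sqrt(mean((amps - mu)^2))
  expect_equal(selectivity_zscore(amps), (0.2 - mu) / sig)
  expect_equal(selectivity_zscore(amps), 3.3166, tolerance = 1e-4)
  # beat amplitude equal to the mean -> 0
  a0 <- c(0.1, 0.2, 0.15, 0.1, 0.2, 0.15, 0.1, 0.2, 0.15, 0.1, 0.2, 0.15)
  expect_equal(selectivity_zscore(a0), (0.15 - mean(a0)) / sqrt(mean((a0 - mean(a0))^2)))
  expect_error(selectivity_zscore(rep(0.1, 12)), "undefined")
  # invariance under positive scaling and constant shifts
  set.seed(4)
  for (i in 1:20) {
    a <- runif(12, 0, 0.3)
    z <- selectivity_zscore(a)
    expect_equal(selectivity_zscore(3.7 * a), z)
    expect_equal(selectivity_zscore(a + 0.5), z)
    expect_equal(selectivity_zscore(2 * a + 1), z)
  }
})

test_that("endogenous index is the syncopated-minus-unsyncopated beat amplitude", {
  mk <- function(beat, tempo, rhythm) {
    structure(list(amp_uv = c(0.03, 0.03, beat, rep(0.03, 9)),
                   freq_hz = expected_frequencies(tempo),
                   beat_index = 3L, tempo = tempo, rhythm = rhythm),
              class = "ssep_profile")
  }
  t3 <- tempo_spec(3); t4 <- tempo_spec(4)
  # group-mean amplitudes at the 2.5 Hz tempo: 0.09 - 0.12 = -0.03
  expect_equal(endogenous_index(mk(0.09, t3, "syncopated"),
                                mk(0.12, t3, "unsyncopated")), -0.03)
  # and at the fastest tempo: 0.12 - 0.13 = -0.01
  expect_equal(endogenous_index(mk(0.12, t4, "syncopated"),
                                mk(0.13, t4, "unsyncopated")), -0.01)
  expect_equal(endogenous_index(mk(0.1, t3, "syncopated"),
                                mk(0.1, t3, "unsyncopated")), 0)
  expect_error(endogenous_index(mk(0.1, t3, "syncopated"),
                                mk(0.1, t4, "unsyncopated")), "tempo")
})

test_that("condition aggregation forms the slow/fast and mean indices", {
  grid <- expand.grid(rhythm = c("unsyncopated", "syncopated"), tempo = 1:4,
                      stringsAsFactors = FALSE)
  # identical values -> aggregates equal that value
  cst <- transform(grid, beat_amp_uv = 0.21, z_beat = 2, nonbeat_amp_uv = 0.03)
  agg <- aggregate_indices(cst)
  expect_equal(agg$mean_beat_amp_uv, 0.21)
  expect_equal(agg$mean_selectivity, 2)
  expect_equal(agg$slow$beat_amp_uv, 0.21)
  expect_equal(agg$mean_nonbeat_amp_uv, 0.03)
  expect_equal(agg$endo_mean_uv, 0)
  # slow aggregate of the two slow-tempo unsyncopated beat amplitudes
  tbl <- transform(grid, z_beat = 1, nonbeat_amp_uv = 0.03)
  tbl$beat_amp_uv <- ifelse(tbl$rhythm == "unsyncopated",
                            c(0.21, 0.21, 0.12, 0.13)[tbl$tempo],
                            c(0.09, 0.08, 0.09, 0.12)[tbl$tempo])
  agg2 <- aggregate_indices(tbl)
  expect_equal(agg2$slow$endo_uv, mean(c(0.09 - 0.21, 0.08 - 0.21)))
  expect_equal(agg2$fast$endo_uv, mean(c(0.09 - 0.12, 0.12 - 0.13)))
  expect_equal(unname(agg2$endo_by_tempo["1"]), -0.12)
  expect_error(aggregate_indices(tbl[-1, ]), "missing")
  expect_silent(aggregate_indices(tbl[tbl$tempo %in% 1:2, ],
                                  require_complete = FALSE))
})
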