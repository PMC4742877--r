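# Rhythm patterns, tempo arithmetic, audio rendering, envelopes, pacing.

test_that("default patterns satisfy their structural invariants", {
  pu <- make_pattern("unsyncopated")
  ps <- make_pattern("syncopated")
  for (p in list(pu, ps)) {
    expect_length(p$slots, 12L)
    expect_identical(p$beat_positions, c(0L, 4L, 8L))
  }
  # a tone on every beat
  expect_true(all(pu$slots[pu$beat_positions + 1L]))
  # at least one silent beat, preceded by an off-beat tone
  silent <- ps$beat_positions[!ps$slots[ps$beat_positions + 1L]]
  expect_gte(length(silent), 1L)
  pre <- setdiff((silent - 1L) %% 12L, ps$beat_positions)
  expect_true(any(ps$slots[pre + 1L]))
  expect_error(make_pattern("swung"))
  # overrides are validated against the same invariants
  expect_error(make_pattern("unsyncopated", tone_slots = c(0, 4)),
               "all three beats")
  expect_error(make_pattern("syncopated", tone_slots = c(0, 4, 8, 1)),
               "silent beat")
})

test_that("tempo arithmetic reproduces the stimulus constants", {
  t4 <- tempo_spec(4)
  expect_equal(t4$event_ms, 66)
  expect_equal(t4$cycle_ms, 792)
  expect_equal(t4$beat_ms, 264)
  expect_equal(t4$beat_hz, 1000 / 264)      # ~3.79, prints as 3.8
  expect_equal(tempo_spec(1)$beat_ms, 1600)  # 0.625 Hz beat
  expect_equal(tempo_spec(2)$beat_hz, 1.25)
  expect_equal(tempo_spec(3)$beat_hz, 2.5)
  expect_equal(tempo_spec(event_ms = 200)$tempo, 2L)
  expect_error(tempo_spec(5))
  expect_error(tempo_spec(event_ms = 150))
})

test_that("expected frequencies are the 12 cycle harmonics", {
  f2 <- expected_frequencies(tempo_spec(2))
  expect_length(f2, 12L)
  expect_equal(f2[12], 5)            # unitary event rate at tempo 2
  expect_equal(f2[3], tempo_spec(2)$beat_hz)
  expect_equal(expected_frequencies(tempo_spec(3))[3], 2.5)
  expect_equal(expected_frequencies(tempo_spec(4))[3], 1000 / 264)
  for (tp in 1:4) {
    ts <- tempo_spec(tp)
    expect_equal(expected_frequencies(ts)[3], 1 / (4 * ts$event_ms / 1000))
  }
})

test_that("rendering fills tone slots and leaves silence empty", {
  t2 <- tempo_spec(2)
  rate <- 8000
  # single tone in slot 5 (0-based 4 = a beat): nonzero support in that slot only
  p1 <- make_pattern("unsyncopated",
                     tone_slots = c(0, 4, 8))
  w <- render_audio(p1, t2, n_cycles = 1, rate_hz = rate)
  ns_event <- round(t2$event_ms / 1000 * rate)
  on <- which(abs(w$samples) > 0)
  slots_hit <- sort(unique((on - 1) %/% ns_event))
  expect_identical(slots_hit, c(0, 4, 8))
  # duration of one cycle at tempo 4 = 792 ms (within one sample per event)
  w4 <- render_audio(make_pattern("unsyncopated"), tempo_spec(4),
                     n_cycles = 1, rate_hz = 44100)
  expect_equal(w4$duration_s * 1000, 792, tolerance = 1e-3)
  expect_error(render_audio(p1, t2, n_cycles = 0))
  expect_error(render_audio(p1, t2, rate_hz = 1000))
})

test_that("Hilbert envelope matches the closed form for a pure tone", {
  rate <- 10000
  x <- 0.7 * sin(2 * pi * 1000 * (0:(rate - 1)) / rate)
  env <- extract_envelope(x, rate_hz = rate)
  expect_true(all(env$samples >= 0))
  interior <- env$samples[2000:8000]
  expect_lt(max(abs(interior - 0.7)), 1e-3)
  expect_equal(extract_envelope(numeric(16), rate_hz = 100)$samples,
               numeric(16))
  expect_error(extract_envelope(numeric(0), rate_hz = 100))
  expect_error(extract_envelope(c(1, NA, 2), rate_hz = 100))
})

test_that("envelope of a rendered tempo-2 stimulus is cycle-periodic", {
  t2 <- tempo_spec(2)
  rate <- 8000
  w <- render_audio(make_pattern("syncopated"), t2, n_cycles = 3,
                    rate_hz = rate)
  env <- extract_envelope(w)$samples
  cyc <- round(t2$cycle_ms / 1000 * rate)   # 2400 ms
  # compare the middle cycle against the one after it (edges excluded)
  expect_lt(max(abs(env[(cyc + 1):(2 * cyc)] - env[1:cyc])), 1e-6)
})

test_that("envelope spectra carry energy only at cycle harmonics", {
  for (kind in c("unsyncopated", "syncopated")) {
    cc <- count_envelope_components(make_pattern(kind), tempo_spec(2),
                                    n_cycles = 4, rate_hz = 11025)
    expect_equal(cc$n_components, 12L)
    expect_lt(cc$max_offharmonic_amp, 1e-10 * max(cc$harmonic_amp))
  }
})

test_that("pacing sequences respect the IOI and step-size constraints", {
  for (arr in 1:6) {
    p <- generate_pacing_sequence(arr, seed = 7 + arr)
    expect_gte(min(p$iois_ms), 400)
    expect_lte(max(p$iois_ms), 600)
    steps <- abs(diff(p$iois_ms))
    expect_gte(min(steps), 11)
    expect_lte(max(steps), 64)
    expect_equal(p$duration_s, 40, tolerance = 0.025)
    expect_equal(p$onsets_ms, cumsum(c(0, p$iois_ms)))
  }
})

test_that("pacing sequences are reproducible and seed-sensitive", {
  a <- generate_pacing_sequence(3, seed = 11)
  b <- generate_pacing_sequence(3, seed = 11)
  c <- generate_pacing_sequence(3, seed = 12)
  expect_identical(a$iois_ms, b$iois_ms)
  expect_false(identical(a$iois_ms, c$iois_ms))
  expect_error(generate_pacing_sequence(7, seed = 1))
  expect_error(generate_pacing_sequence(1, seed = 1,
                                        phase_switch_points = c(10, 50)))
})
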