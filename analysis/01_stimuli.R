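#!/usr/bin/env Rscript
# Stimulus construction: the two 12-event rhythms, the four tempi, the
# envelope frequencies at which SSEPs are expected, and the harmonic
# content of the rendered envelopes.

suppressPackageStartupMessages(library(beatentrain))
dir.create("results", showWarnings = FALSE)

tempi <- lapply(1:4, tempo_spec)
cat("Tempo grid (event / beat / cycle durations):\n")
for (ts in tempi)
  cat(sprintf("  tempo %d: event %3g ms, beat %4g ms (%.3g Hz), cycle %4g ms\n",
              ts$tempo, ts$event_ms, ts$beat_ms, ts$beat_hz, ts$cycle_ms))

freq_tbl <- do.call(rbind, lapply(tempi, function(ts) {
  data.frame(tempo = ts$tempo, harmonic = 1:12,
             freq_hz = expected_frequencies(ts),
             is_beat = (1:12) == 3)
}))
write.csv(freq_tbl, "results/expected_frequencies.csv", row.names = FALSE)
cat("\nExpected SSEP frequencies written to results/expected_frequencies.csv\n")

cat("\nDefault patterns:\n")
print(make_pattern("unsyncopated"))
print(make_pattern("syncopated"))

harm_tbl <- do.call(rbind, lapply(c("unsyncopated", "syncopated"), function(kind) {
  do.call(rbind, lapply(tempi, function(ts) {
    cc <- count_envelope_components(make_pattern(kind), ts,
                                    n_cycles = 4, rate_hz = 22050)
    data.frame(rhythm = kind, tempo = ts$tempo, harmonic = 1:12,
               freq_hz = cc$harmonic_hz, amplitude = cc$harmonic_amp,
               n_components = cc$n_components,
               max_offharmonic = cc$max_offharmonic_amp)
  }))
}))
write.csv(harm_tbl, "results/envelope_harmonics.csv", row.names = FALSE)

cat("\nEnvelope harmonic content (components at cycle harmonics k = 1..12):\n")
agg <- unique(harm_tbl[, c("rhythm", "tempo", "n_components", "max_offharmonic")])
print(agg, row.names = FALSE)
cat("Every rhythm x tempo carries all 12 components; off-harmonic energy is\n")
cat("numerical leakage only (see max_offharmonic).\n")

# pacing sequences for the temporal-prediction task
pac_tbl <- do.call(rbind, lapply(1:6, function(arr) {
  p <- generate_pacing_sequence(arr, seed = 100 + arr)
  data.frame(arrangement = arr, n_onsets = length(p$onsets_ms),
             duration_s = p$duration_s,
             ioi_min = min(p$iois_ms), ioi_max = max(p$iois_ms),
             step_min = min(abs(diff(p$iois_ms))),
             step_max = max(abs(diff(p$iois_ms))))
}))
write.csv(pac_tbl, "results/pacing_arrangements.csv", row.names = FALSE)
cat("\nPacing arrangements (40-s sinusoidal tempo changes, IOI 400-600 ms):\n")
print(pac_tbl, row.names = FALSE)
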