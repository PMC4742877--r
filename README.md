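# beatentrain

Analysis pipeline linking **covert neural entrainment** to auditory
rhythms with **overt sensorimotor synchronization** behavior, for
auditory-neuroscience researchers working with EEG frequency tagging and
paced finger tapping.

When listeners hear a rhythmic pattern, the EEG spectrum shows
steady-state evoked potentials (SSEPs) at the frequencies of the
stimulus amplitude envelope. With an *unsyncopated* rhythm (a tone on
every beat), beat-frequency activity can be driven exogenously; with a
*syncopated* rhythm (most beats silent), it must be generated
endogenously. This package implements the complete computational chain
needed to relate those neural measures to tapping behavior:

* **Stimuli** — 12-event tone/silence cycles (beats every 4 events) at
  four tempi (event durations 400/200/100/66 ms; beat rates 0.6–3.8 Hz);
  Hilbert amplitude envelopes and their spectra, which carry exactly 12
  frequency components from the cycle frequency up to the event rate;
  40-s tempo-changing pacing sequences with sinusoidally modulated
  inter-onset intervals (400–600 ms, steps 11–64 ms).
* **SSEP extraction** — 0.1 Hz zero-phase high-pass, epoching (+1 to
  +33 s) and trial averaging, single-sided amplitude spectra (0.031 Hz
  bins), neighbor-bin noise subtraction (offsets ±0.09–0.15 Hz, adjacent
  bins excluded), channel averaging, and readout at the 12 expected
  frequencies.
* **Entrainment indices** — beat selectivity `z = (x − μ)/σ` over the 12
  SSEP amplitudes, and the endogenous-entrainment index
  `A_beat(syncopated) − A_beat(unsyncopated)`.
* **Tapping metrics** — circular statistics on tap phases: signed
  asynchrony from the mean resultant direction (accuracy) and circular
  variance `1 − R` (precision), with tapping-unit inference
  (subdivision/beat/bar) and a beat-unit exclusion rule.
* **Temporal prediction** — per-trial ratio of lag-0 to lag-1
  cross-correlations between inter-tap and pacing inter-onset intervals
  (> 1 = predicting tempo changes, < 1 = tracking them).
* **Brain–behavior statistics** — OLS regressions with standardized
  betas, partial correlations and adjusted R², relating synchronization
  accuracy, precision and prediction to the neural indices and musical
  training.
* **Synthetic ground truth** — generators for EEG with planted SSEPs in
  1/f + white noise, beat/tempo tappers with known lag, motor noise and
  prediction weight, and whole cohorts with a planted latent correlation
  structure, so every stage has a parameter-recovery test.

## Worked example

```r
library(beatentrain)

# Stimulus frame: tempo 3 = 100 ms events, 2.5 Hz beat
tempo <- tempo_spec(3)
expected_frequencies(tempo)[3]
#> [1] 2.5

# Synthetic EEG: 0.2 uV beat SSEP + 0.03 uV at the other 11 envelope
# frequencies, in 1/f + white noise; 8 channels, 10 trials
amps <- rep(0.03, 12); amps[3] <- 0.2
spec <- eeg_sim_spec(planted = data.frame(freq_hz = expected_frequencies(tempo),
                                          amp_uv = amps),
                     n_channels = 8, rate_hz = 128, n_trials = 10, seed = 1)
sim <- simulate_eeg(spec)

# Full SSEP chain: filter, epoch-average, spectrum, noise subtraction,
# channel average, profile readout
prof <- analyze_condition(sim$recording, sim$rate_hz, sim$onsets_s, tempo)
round(prof$amp_uv, 3)
#>  [1] 0.010 0.020 0.180 0.008 0.013 0.012 0.016 0.014 0.020 0.020 0.025 0.018
selectivity_zscore(prof)
#> [1] 3.300026
```

The planted 0.2 µV beat SSEP is recovered as 0.180 µV (noise subtraction
slightly attenuates low-SNR amplitudes; see the methods vignette) and
stands out from the other envelope frequencies with a selectivity z-score
of 3.3.

```r
# Beat tapping: anticipatory tapper, -40 ms lag, 20 ms motor noise
bt <- beat_times(tempo, n_cycles = 14)
taps <- simulate_beat_tapper(tapper_spec("beat", delta_ms = -40,
                                         sigma_motor_ms = 20, seed = 1),
                             bt, tempo)
score_tap_trial(taps, tempo, beat_times_ms = bt)
#>   unit period_ms  rmse_ms n_taps         R circ_variance asynchrony_ms
#> 1 beat       400 23.98925     42 0.9644856    0.03551444      -38.3168

# Temporal prediction: a predictor (alpha = 0.9) on a tempo-changing sequence
pac <- generate_pacing_sequence(1, seed = 1)
taps3 <- simulate_tempo_tapper(tapper_spec("tempo", delta_ms = -36,
                                           sigma_motor_ms = 10, alpha = 0.9,
                                           seed = 1), pac)
score_pacing_trial(taps3, pac)[, 1:5]
#>      r_lag0    r_lag1    index valid mean_async_ms
#> 1 0.9904245 0.8656986 1.144076  TRUE      7.449575
```

The tapping trial is scored at the beat unit with a recovered asynchrony
of −38 ms (planted −40) and circular variance 0.036; the predictive
tempo tapper yields a prediction-tracking index of 1.14 (> 1:
predominantly predicting).

The numbered scripts under `analysis/` run the stages as a narrative —
stimuli and envelope spectra (`01`), SSEP recovery (`02`), tapping
metrics (`03`), the prediction index (`04`), and a full 18-participant
synthetic cohort with the three brain–behavior regressions (`05`) — each
writing tidy CSVs under `results/`:

```sh
Rscript analysis/01_stimuli.R
# ...
Rscript analysis/05_cohort_regression.R 42   # optional seed
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models and
their assumptions, the tunable parameters with defaults and units, what
the synthetic generators do and do not emulate, numerical choices, and
known limitations.
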