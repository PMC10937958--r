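# lfpstate

Multi-structure LFP brain-state analysis for pharmacological experiments.

## The problem

Psychotomimetic drug challenges (for example NMDA-antagonist models of
psychosis in hemi-parkinsonian rodents) change brain activity in ways that
are hard to read from raw local field potentials: aberrant high-frequency
oscillations (HFOs, ~130–160 Hz) appear across many structures in
parallel, become abnormally phase-locked between regions, lower the
temporal complexity of the signal, and shift the global spectral state.
Antipsychotic compounds partially reverse these signatures. `lfpstate`
implements the full analysis chain a systems-neurophysiology lab needs to
quantify such effects from multichannel recordings and open-field video
tracking, plus a synthetic-data generator with ground-truth ledgers so
every stage can be validated on data where the right answer is known.

## What it computes

- **Bipolar derivation** of electrode pairs within a structure
  (volume-conduction rejection) and sample-accurate condition epochs.
- **Spectrograms** from 50%-overlapping 8-s Hanning windows (0.5 Hz grid,
  0–300 Hz) and **fractal/rhythmic separation** by irregular resampling:
  the arrhythmic 1/f component is estimated as the median over resampling
  factors h ∈ {1.10, …, 1.90} of √(S_h(f)·S_{1/h}(f)), and rhythmic power
  is reported as dB_fractal = 10·log₁₀(total/fractal).
- **Parametric peak detection** per 60-s block with the model
  y(f) = A·exp(−((f−B)/C)²) + D·f + E, accepting peaks only when
  R² > 0.2, 2 < A < 100 dB, B in band (HFO 115–170 Hz, gamma 30–70 Hz),
  1 < C < 20 Hz, −1 < D < 1, −10 < E < 10. Summaries: detection rate,
  band power over a 20 Hz band centered on the session peak frequency
  (median of B), and peak frequency.
- **Phase coupling**: zero-phase band-pass ± analytic signal, phase
  differences gated to blocks with detections in both structures,
  one sample per cycle, summarized by a von Mises fit (κ from Fisher's
  piecewise ML inverse; σ² = 1/κ) and Δκ matrices between conditions.
- **Permutation entropy** (order 6, consecutive samples, 30,000-sample
  sliding windows) per channel and condition, normalized by ln 720.
- **Brain-state similarity**: concatenated per-structure dB_fractal
  spectra (1–300 Hz) correlated between treatments, with rank-sum and
  Kruskal–Wallis group tests on animal-level coefficients.
- **Locomotion**: centroid speed from pose tracks (25 fps), bouts with
  speed ≥ 2 cm/s for ≥ 0.5 s, bout statistics, cumulative turning.
- **Hierarchical permutation tests** honoring animal/session nesting.

## Worked example

Simulate one session (baseline, then a drug epoch carrying 6 dB HFOs at
145 Hz shared by three structures with known phase lags), run detection
and coupling:

```r
library(lfpstate)

ep <- data.frame(label = c("baseline", "vehicle"),
                 start_s = c(0, 120), end_s = c(120, 240))
cfg <- synthetic_session_config(
  duration_s = 240, condition_epochs = ep,
  oscillations = list(list(
    condition = "vehicle", band = "HFO", center_f = 145, bandwidth = 10,
    amplitude_db = 6,
    episode_schedule = data.frame(start_s = 120, end_s = 240),
    phase_lag_map = c(mPFC = 0, OFC = pi/8, vStr = pi/4), kappa = 8)),
  seed = 42)
sess  <- generate_session(cfg)
bset  <- bipolar_derive(sess$recording, sess$channel_map)
blocks <- block_spectra(bset, block_s = 60)
fits   <- fit_blocks(blocks, band_definition("HFO"))
print(summarize_band(fits, blocks), digits = 3)
#>   structure hemisphere condition n_blocks detection_rate band_power peak_frequency
#> 1      mPFC   lesioned  baseline        2              0    -0.0268             NA
#> 2      mPFC   lesioned   vehicle        2            100     3.4458            146
#> 3       OFC   lesioned  baseline        2              0     0.0484             NA
#> 4       OFC   lesioned   vehicle        2            100     3.6031            145
#> 5      vStr   lesioned  baseline        2              0     0.1508             NA
#> 6      vStr   lesioned   vehicle        2            100     3.5455            145

print(structure_pair_coupling(bset, fits, "vehicle"), digits = 3)
#>        pair structure_a structure_b     n     mu  rbar kappa
#> 1  mPFC-OFC        mPFC         OFC 17143 -0.410 0.489  1.12
#> 2 mPFC-vStr        mPFC        vStr 17143 -0.902 0.485  1.11
#> 3  OFC-vStr         OFC        vStr 17143 -0.516 0.492  1.13
```

Reading the output: the baseline epoch produces no HFO detections (0%
rate, band power ≈ 0 dB, "peak absent"); the drug epoch is detected in
every block with band power ≈ 3.5 dB_fractal — the mean of the Gaussian
peak over its 20 Hz band, consistent with the injected 6 dB peak height —
and a peak frequency at the injected 145 Hz. The coupling table recovers
the injected lags: mPFC−OFC has circular mean ≈ −π/8 (−0.39), and
mPFC−vStr sits near −π/4 (−0.79) within the per-episode phase offset the
generator draws at κ = 8 (SD ≈ 0.35 rad; this run uses a single long
episode). The measured κ is diluted below the configured value by in-band
background noise, as expected at realistic SNR, while its ordering across
conditions tracks the generator's.

The full demonstration experiment — 3 animals × 2 sessions × 3 conditions
through every stage (detection, Δκ, entropy, state similarity, behavior,
nested statistics) — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "out/")
res$summaries      # detection rate / band power / peak frequency
res$coupling_change  # Δκ (treatment − vehicle) per structure pair
```

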