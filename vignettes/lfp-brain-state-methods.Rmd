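---
title: "Methods: multi-structure LFP brain-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-structure LFP brain-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`lfpstate` characterizes pharmacologically induced brain states from
multichannel local field potential (LFP) recordings: which oscillations are
present, how strong and how fast they are, how tightly brain structures are
phase-coupled, how temporally ordered the signal is, and how similar the
global spectral state of one treatment is to another. Because real
multi-structure recordings of this kind are rarely shared, the package pairs
every analysis stage with a synthetic-data generator whose ground truth is
recorded in a ledger, so the whole pipeline can be validated end to end on
data where the right answer is known.

This vignette explains the models, the tunable parameters with their
defaults, what the generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

# Data model

A recording is a channels x time matrix of voltages (micro-V) at a sampling
rate of 2 kHz (the rate the pipeline assumes downstream; `downsample()`
brings faster acquisitions to it with a brick-wall Fourier anti-alias
filter). A channel map assigns every channel to a brain structure (the
default vocabulary is the 11-structure set amyg, dStr, OC, OFC, PC, mPFC,
M1, S1, thal, vHipp, vStr) and a hemisphere (`lesioned` / `intact` for
unilateral-lesion designs). Condition epochs are half-open `[start, end)`
intervals in seconds from recording start; slicing is sample-accurate
(`floor(start * fs) + 1` through `floor(end * fs)`).

All derived spectra are computed on bipolar derivations: differences of two
electrodes within the same structure (`bipolar_derive()`). Differencing
removes voltage common to both electrodes, which is the standard guard
against volume conduction from distant strong sources. The default pairing
sorts channels by id within a structure and pairs consecutively (1-2, 3-4,
...), so each electrode enters one pair; an all-pairs mode exists for
electrode-level coupling analyses. Which electrodes to pair is a genuinely
open choice in this kind of analysis; consecutive pairing is deterministic
and independent of electrode spacing, which is why it is the default.

The container serializes to plain text (CSV samples written with 17
significant digits plus a JSON metadata sidecar), which round-trips doubles
bitwise and stays portable across languages.

# Spectral analysis

## Spectrogram

`compute_spectrogram()` uses 50%-overlapping 8-s Hanning windows. Each
window is demeaned and scaled as a one-sided power spectral density
(micro-V^2/Hz). An 8-s window natively yields 0.125 Hz bins; the package
averages four native bins per output bin to produce the declared 0.5 Hz
grid, keeping the window length and the output resolution decoupled. The
grid starts at 0.5 Hz: demeaned windows make the DC bin degenerate, so it
is not reported.

## Separating rhythmic from arrhythmic components

LFP spectra are dominated by an arrhythmic 1/f^alpha background. To make
genuinely rhythmic activity visible, `irasa_decompose()` estimates the
fractal (arrhythmic) component by irregular resampling: resampling a time
series by a factor h leaves a power-law spectrum invariant apart from a
frequency dilation, while any narrowband peak is displaced. The fractal
estimate at frequency f is

    fractal(f) = median over h of sqrt( S_h(f) * S_1/h(f) )

with h in {1.10, 1.15, ..., 1.90} paired with reciprocals, and the rhythmic
residue is reported in dB relative to the fractal component:

    dB_fractal(f) = 10 log10( total(f) / fractal(f) ).

Two numerical routes are implemented. The default (`method = "rescale"`)
uses the exact dilation identity of resampling for stationary segments:
S_h(f) = h S(h f) and S_1/h(f) = S(f/h)/h, so the h factors cancel inside
the geometric mean and the whole estimate reduces to evaluating one Welch
spectrum at rescaled frequencies. The second route
(`method = "resample"`) materializes Fourier-resampled series and computes
their Welch spectra; it exists as a cross-check and the two agree on test
signals. The rescale route was chosen as default because it is an order of
magnitude faster at identical accuracy (residue bias about -0.03 dB on
pure-fractal input), which is what makes block-wise decomposition across
hundreds of blocks practical.

Decomposition operates per analysis segment (by default the 60-s detection
block) with Welch averaging across the segment's 8-s windows *before* the
dB ratio is formed. Averaging first matters: the log of a single-window
periodogram carries a chi-square bias of about -2.5 dB which would
contaminate the residue if ratios were taken per window.

# Oscillation detection

Rhythmic peaks are quantified with a five-parameter model fitted to the
structure-averaged dB_fractal spectrum of each 60-s block:

    y(f) = A exp( -((f - B)/C)^2 ) + D f + E

A is the peak height (dB), B the peak frequency (Hz), C the width (Hz),
and D, E a linear background. Two bands are defined: HFO (B in 115-170 Hz,
fitted over 100-185 Hz) and gamma (B in 30-70 Hz, fitted over 20-85 Hz);
the fit range pads the B range by about 15 Hz so the linear background is
identifiable. Fitting uses bounded Levenberg-Marquardt least squares with
a deterministic 3 x 3 multi-start grid over B (band quartiles) and C in
{3, 8, 15} Hz; ties break toward the lowest residual, then the lowest B,
so a given spectrum always returns the same fit.

A block is a positive detection only when all conditions hold with strict
inequalities: R^2 > 0.2, 2 < A < 100 dB, B inside the band, 1 < C < 20 Hz,
-1 < D < 1, -10 < E < 10. Summaries report per structure and condition:
the detection rate (% of blocks), band power (mean dB_fractal over a 20 Hz
band centered on the session peak frequency — the median of B over the
session's detected blocks, computed per structure), and the peak frequency
(median detected B within the condition). A structure with no detections
reports its peak frequency as missing ("peak absent"), not as zero.

The 60-s block is the package's temporal unit of detection; it balances
spectral signal-to-noise against temporal resolution and is configurable
(`block_s`).

# Phase coupling

Psychotomimetic-state HFOs appear in several structures at once and share
a common frequency, so their phase relations are informative about
inter-structure coupling. `extract_band_phase()` band-passes the bipolar
trace with a zero-phase 4th-order Butterworth filter over the session peak
frequency ± 10 Hz (the same 20 Hz band used for band power) and takes the
analytic-signal phase. Phase differences between structures are restricted
to blocks where the detector fired in *both* structures (oscillations
detected in parallel), pooled within condition, and decimated to one
sample per oscillation cycle before estimation — the maximum-likelihood
theory for concentration assumes independent draws, and per-cycle sampling
removes most serial dependence.

The pooled circular sample is summarized by a von Mises (circular normal)
fit: mean direction mu and concentration kappa, with kappa obtained from
the resultant length by Fisher's piecewise approximation to the
maximum-likelihood inverse (three regimes at R < 0.53, 0.53-0.85, >= 0.85)
and capped at 500 (R = 1 is otherwise a pole). The reporting convention
sigma^2 = 1/kappa links kappa to a circular variance. Samples smaller than
10 are reported undefined rather than estimated. Treatment effects are
expressed as Delta kappa = kappa_condition - kappa_reference per structure
pair; cells undefined in either condition propagate as missing.

# Signal complexity

`permutation_entropy_series()` estimates temporal complexity as the
Shannon entropy of ordinal patterns: each window of 6 consecutive samples
(no delay) is reduced to its rank permutation, identified by a Lehmer
code with stable tie-breaking (earlier occurrence ranks first — ties have
measure zero in continuous signals but integer test fixtures need
determinism). At 2 kHz a 6-sample pattern spans 3 ms, shorter than an HFO
period, so the measure reflects sub-oscillation temporal structure.
Entropy is computed in sliding windows of 30,000 samples (15 s) with a
1-s default hop inside each condition epoch and averaged into one value
per channel and condition. Values are reported normalized by ln(6!) = ln
720 (range 0-1) with raw nats alongside, since either unit is defensible.
A strong narrowband oscillation *lowers* permutation entropy relative to
arrhythmic noise — the ordering the drug-challenge interpretation relies
on — and this is verified on generator output in the test suite.

# Global brain states

A brain state is summarized as the concatenation of per-structure
time-averaged dB_fractal spectra over 1-300 Hz (599 bins per structure at
0.5 Hz) in a declared structure order; with six structures this is the
canonical 3,594-bin state vector. Spectra are averaged across a
structure's electrode pairs before concatenation (a per-electrode mode
would multiply vector length without adding desk-scale information).
States are compared by Pearson correlation; per animal, each treatment
state is correlated against that animal's baseline and vehicle states,
and group summaries report medians with quartiles. Between-treatment
comparisons use Wilcoxon rank-sum tests on the animal-level coefficients
(suppressed below 3 animals per group), and pairwise
reference-vs-treatment similarity distributions are compared with a
Kruskal-Wallis omnibus test.

# Behavior

Pose tracks (25 fps, cm coordinates, multiple body parts) reduce to a
centroid by averaging available parts per frame; frames with no tracked
part are linearly interpolated and flagged. Speed is centroid displacement
times frame rate. Locomotion bouts are maximal runs with speed >= 2 cm/s
lasting >= 0.5 s; 0.5 s at 25 fps is 12.5 frames, rounded up to 13 (the
conservative reading). A 5-frame median filter suppresses tracking jitter
before thresholding (raw mode available). Summaries report bout rate per
minute, mean bout speed/duration/distance, and within-bout locomotion per
second; with no bouts the means are reported missing, not zero.
Cumulative turning sums wrapped frame-to-frame changes of the heading
(direction of centroid displacement), excluding frames slower than 1 cm/s
where heading is undefined; positive is counterclockwise, i.e.
ipsiversive for a right-hemisphere lesion.

# Statistics

Condition comparisons honor the animal/session hierarchy with a
permutation test: the exchangeable unit is the (animal, session,
condition) cell mean, condition labels are permuted within animal, the
statistic is the difference of animal-level condition means, and
p = (1 + #{|T*| >= |T|}) / (1 + n_perm). This is a distribution-free
analogue of a nested ANOVA that needs no variance-component estimation;
designs with no animal observed under both conditions are rejected with
an explanatory error rather than silently unnested. A rank-based mode
makes the p-value invariant to monotone transforms. Wilcoxon rank-sum and
Kruskal-Wallis tests (base R implementations behind the package's
interfaces) cover the animal-level group comparisons, and
Benjamini-Hochberg adjustment is available for significance maps across
the 11 structures (both raw and adjusted maps are emitted, since
per-structure testing without correction is also common practice).

# The synthetic-data generator

`generate_session()` realizes a configured session:

* **Arrhythmic background** — independent per channel, synthesized by
  spectral shaping of white Gaussian noise (|H(f)| proportional to
  f^(-alpha/2)); default alpha = 2 and variance 2,500 micro-V^2 (50
  micro-V RMS), typical of rodent LFP.
* **Oscillation episodes** — a common complex narrowband carrier per band
  (Gaussian spectral envelope; bandwidth = FWHM of the power spectrum,
  default 10 Hz at 145 Hz center for HFOs) drives all target structures,
  so simultaneous episodes share one frequency. Channel j of structure s
  is rotated by lag_s + j * delta, with delta = pi/2 by default — a
  within-structure spatial phase gradient without which bipolar
  differencing would cancel the oscillation entirely.
* **Phase concentration** — the first structure in the lag map is the
  phase reference; every other structure draws a per-episode von Mises
  offset with the configured kappa (plus a small low-pass phase drift
  when kappa is finite). Pairs involving the reference therefore carry
  exactly the configured concentration; non-reference pairs compound two
  draws and are less concentrated, with ordering preserved.
* **Amplitude calibration** — `amplitude_db` is defined in the same units
  the pipeline reports: the dB_fractal peak height at band center. The
  generator calibrates empirically (one iteration) against the Welch
  spectrum of the bipolar-derived background, so injected amplitude and
  measured peak height agree within about 1 dB.
* **Episode schedules** — explicit lists, or a Poisson process with given
  rate and duration (default 30-s episodes; the literature gives no
  quantitative episode durations, so this is a configurable convention).
* **Pose tracks** — resting centroid between scheduled bouts, scheduled
  speed during them, optional constant-sign turning, zero-mean body-part
  offsets plus Gaussian jitter; with zero noise the schedule is exactly
  recoverable.

What the generator does *not* emulate: biophysical neural-mass dynamics,
nonstationary drift, movement artifacts, volume-conducted cross-structure
leakage, electrode impedance drift, or realistic spatial correlation of
the background. Passing tests therefore demonstrate that the analysis
recovers known spectral/phase/entropy/behavioral structure under the
stated statistical assumptions — not that it is robust to every artifact
of real recordings.

# Numerical choices and degenerate inputs

* Welch windows are demeaned; the one-sided density halves the Nyquist
  bin correctly; variance checks against white noise hold within 5%.
* The peak fit's R^2 is computed on the fitted range against the
  mean-only model; optimizer failure on all starts returns an explicit
  non-detection with missing parameters rather than an error.
* kappa estimation caps at 500; identical phases give R = 1, the cap, by
  construction. Uniform samples give kappa below 0.05 at n = 5,000.
* All-constant entropy windows return 0 with a warning; windows shorter
  than 5 * m! samples warn that the estimate is coarse.
* Epochs shorter than one entropy window or one detection block are
  reported missing, never silently padded.
* Degenerate similarity analyses (identical vectors, zero variance)
  suppress tests instead of fabricating p-values.
* Every stochastic function takes a seed; the pipeline derives per-stage
  seeds from the master seed by fixed offsets, and reruns are bitwise
  identical.

# Problem sizes

The demonstration experiment (`pipeline_config()` defaults) uses 3
animals x 2 sessions x 3 conditions (baseline / vehicle / treatment),
three structures with two electrodes each, 120-s condition epochs and
60-s detection blocks — sizes chosen so a full end-to-end run with every
stage completes in about a minute on a laptop while leaving each stage
enough data to estimate its quantities stably. Validation analyses in the
test suite use the same scales (60-s blocks, 5,000-sample circular
estimates, 30,000-sample entropy windows, 200 permutation-null designs).

# Known limitations

* The gamma band label (30-90 Hz in descriptive use) is wider than the
  detector's B range (30-70 Hz); the detector follows the stricter
  bound, the label follows common usage.
* kappa is estimated on pooled per-cycle samples per structure pair;
  per-electrode-pair estimation before averaging is available but not the
  default.
* The hierarchical permutation test replaces a nested ANOVA / GLMM with
  Dunnett adjustment; it controls size under exchangeability within
  animal but does not produce simultaneous confidence intervals.
* Non-reference structure pairs in the generator compound two von Mises
  draws, so their realized concentration is below the configured kappa
  (documented, ordering preserved).
* IRASA's dilation identity assumes within-segment stationarity; strongly
  nonstationary segments should be decomposed at shorter block lengths.
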