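---
title: "Adaptive wavelet reconstruction and cepstral screening of multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive wavelet reconstruction and cepstral screening of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aleewr)
```

## The screening problem

`aleewr` implements a complete screening pipeline for resting-state
multichannel EEG: given recordings from two groups (healthy controls and
patients with schizophrenia), it produces epoch-level class predictions and
cross-validated performance estimates. The pipeline has six stages, each
exposed as ordinary functions and orchestrated by `run_pipeline()`:

1. **Artefact removal** — FastICA decomposes the channels into maximally
   independent sources; kurtosis-outlier sources (blink-like transients)
   are removed and the signal reconstructed.
2. **Segmentation and gain normalisation** — recordings are cut into
   non-overlapping 20 s epochs and every channel is z-scored
   (population SD) so amplifier gain and offset cannot leak into the
   features.
3. **Adaptive wavelet reconstruction** — each channel is decomposed with an
   empirical wavelet transform (EWT) whose band boundaries are data-driven;
   sub-band modes are scored by log energy, and only modes passing a
   relative threshold are summed back into the "reconstructed" channel.
4. **Cepstral Hjorth features** — the real cepstrum of each reconstructed
   channel is summarised by three Hjorth descriptors (activity, mobility,
   complexity), giving 3 × 19 = 57 features per epoch.
5. **ANOVA feature ranking** — each feature's one-way ANOVA F statistic
   against the class label ranks the features; the top *k* (default 10) are
   kept.
6. **KNN classification under repeated stratified 10-fold CV** — fine
   (k = 1), weighted (k = 100, squared-inverse votes) and cubic
   (Minkowski order 3) nearest-neighbour variants.

## Models and conventions

### ICA model and FastICA

Observed channels are modelled as an instantaneous linear mixture
`y = A z` of independent non-Gaussian sources `z`; the unmixing matrix `W`
(with `z = W y`) is estimated by the fixed-point FastICA iteration with the
log-cosh contrast and symmetric decorrelation, after centring and PCA
whitening. Convergence is declared when the largest rotation-row direction
change falls below `tol` (default 1e-6, at most 500 iterations);
non-convergence returns a usable model flagged `converged = FALSE` with a
warning, because on real EEG the near-Gaussian background subspace often
rotates freely while the artefact directions are long settled.

Artefact flagging is deliberately simple and fully configurable, since no
universally agreed rejection criterion exists: a source is flagged when its
excess kurtosis is a robust outlier (median/MAD z-score above
`kurtosis_z = 3`) *and* exceeds an absolute floor (`min_kurtosis = 1`).
Blink-like transients concentrate energy in brief bumps and have excess
kurtosis in the tens; near-Gaussian cortical background stays below about
0.3, so the floor exists purely to stop sampling noise in the kurtosis of
genuinely Gaussian sources from tripping the outlier rule when few
components are available. The rule never flags every component, and the
whole cleanup stage can be disabled (`ica = list(enabled = FALSE)`).

Cleanup runs once per recording before segmentation by default
(`scope = "recording"`): artefact statistics are estimated far better on
fifteen minutes of signal than on a 20 s epoch. A per-epoch scope is
available. For long recordings the whitener and rotation are estimated on a
temporal subsample (`est_every = 3` in the pipeline default, i.e. every
third sample); with tens of thousands of samples per channel this leaves
the estimate essentially unchanged — the direct, every-sample fit remains
the function default.

### Empirical wavelet transform

Band boundaries are placed at the midpoints between successive local maxima
of the magnitude spectrum. Peak detection runs on the open band (0, fs/2)
after a short centred moving average (default 5 bins; 1 disables it) whose
purpose is to suppress noise-induced micro-maxima; candidates below 1e-8 of
the spectral peak are discarded as floating-point artefacts of otherwise
exactly-zero spectra. The `n_peaks` largest maxima are kept (default 5,
configurable 1–16; ties keep the lower frequency). One maximum yields a
single all-pass band.

The filter bank is the Meyer-type construction: the scaling function rolls
off across `[(1-γ)φ₁, (1+γ)φ₁]` as `cos(π/2·β(·))`, each wavelet rises and
falls across the analogous transitions at its two boundaries, and the last
wavelet stays at 1 up to Nyquist. The transition polynomial is
`β(x) = x⁴(35 − 84x + 70x² − 20x³)`, the lowest-order polynomial satisfying
`β(x) + β(1−x) = 1` with flat ends, which makes squared responses sum to
one at every frequency (partition of unity) provided the single
transition-width parameter γ obeys the no-overlap bound
`γ < minᵢ (φᵢ₊₁ − φᵢ)/(φᵢ₊₁ + φᵢ)`. `gamma = "auto"` (the default) takes
0.9 of that bound, with the Nyquist edge included so the top transition
stays in band; an explicit γ violating the bound is an error.

**Reconstruction convention.** Applying each response once gives modes whose
*twice-filtered* sum reproduces the input. Because the mode-selection stage
reconstructs by plain summation of selected modes, decomposition here
multiplies the spectrum by the *squared* response: the partition of unity
then makes `Σ modes = input` exact (relative L2 error at machine precision,
property-tested over 100 seeds). Responses are applied on the two-sided
conjugate-symmetric grid so every mode is real.

### Log-energy mode selection

Each mode is scored by `LE = log(Σ x²)` (sums floored at 1e-300 so silent
modes score finitely). Scores are min-max normalised to [0, 1] and a mode
is kept when its normalised score reaches the threshold (default 0.10,
"10% or higher"); the highest-energy mode is always kept, and all-equal
scores keep everything. The normalisation basis is a genuinely open design
choice: raw log energies of z-scored EEG can be negative, so a
raw-percentage reading is ill-defined. The min-max reading is the default;
`basis = "energy_share"` instead scores each mode by its share of total
(unlogged) energy. One subtlety follows from the min-max choice: the
weakest mode scores exactly 0 and is excluded at any positive threshold, so
the "threshold → 0 recovers the input" limit is exact only in the
energy-share basis — the suite tests it there. Selection is monotone in the
threshold and the selected-mode energy never exceeds the full
reconstruction's.

### Cepstral Hjorth features

The real cepstrum is `c = Re(IFFT(log |FFT(x)|))`, with the log-magnitude
floored at 1e-12 of the spectral peak (an absolute floor would break on
z-scored inputs). Gain enters only at quefrency zero, and circular time
shifts leave the cepstrum unchanged — two invariances the suite checks
directly. On the cepstral sequence the three Hjorth descriptors are

* activity `A = (1/N) Σ (cᵢ − μ)²` (population variance),
* mobility `M = sqrt(A(Δc) / A(c))`,
* complexity `C = M(Δc) / M(c)`,

with `Δ` the unit-spacing first difference (any constant quefrency step
cancels in the ratios). Mobility is implemented with the square root — the
standard Hjorth convention, and the only reading under which complexity is
the mobility *ratio* with a sinusoid scoring ≈ 1; the literal no-radical
variant is available via `sqrt = FALSE`. Features are computed on the
full-band reconstructed channel, not on rhythm sub-bands, and are named
`A<ch>`, `M<ch>`, `C<ch>` channel-major (`AFp1, MFp1, CFp1, …`), 57
features for the 19-channel 10-20 montage. Activity's population (1/N)
normalisation is followed as printed; with 5000 coefficients the
distinction from 1/(N−1) is far below every tolerance used here.

### Feature ranking and classification

The per-feature weight is the one-way ANOVA F statistic,
`F = (SSR/(k−1)) / (SSE/(n−k))` from the between/within partition
`SST = SSR + SSE`; a perfectly separating feature (SSE = 0, SSR > 0) gets
an `Inf` sentinel and ranks first, identical-mean features get 0, and ties
keep the lower column index. p-values are deliberately not computed —
nothing downstream consumes them.

**Selection scope.** Ranking features once on the full table and then
cross-validating leaks selection information. The harness therefore
re-ranks inside each training fold by default (`scope = "fold"`); the
global mode (`scope = "global"`) reproduces the rank-first workflow for
comparison. Similarly, epoch-level CV (epochs of one subject may appear in
both train and test folds) is the default protocol because it matches the
way such screening results are usually reported; `subject_cv = TRUE` gives
the leakage-free grouped alternative in which every subject's epochs stay
on one side of each split.

KNN distance ties are broken by training index; uniform vote ties take the
tied-class neighbour with the smallest training index; a zero-distance
neighbour under squared-inverse weighting decides outright. `k` larger
than the training set is clipped with a warning. The cubic variant's
neighbour count is not standardised anywhere; it defaults to 10 and is
configurable. Folds are stratified (class-wise sizes differ by at most
one) and re-shuffled each repeat from one seed, so a report is
reproducible from its logged configuration alone.

## The synthetic generator

`synth_config()` defaults describe the study geometry the pipeline is
designed for: 2 × 14 subjects, 19 channels (10-20 labels) at 250 Hz, 36
twenty-second epochs per subject — 504 epochs per class. (A fifteen-minute
recording holds 45 such epochs; published per-subject counts in this
setting are nearer 36, so the generator parameterises epochs-per-subject
rather than fixing recording length.)

Each channel is the sum of:

* a **resonant AR(2) oscillation** — pole frequency 10 Hz for controls;
  the disease class shifts it by `2·class_effect` Hz, broadens the
  bandwidth (pole radius 0.995 − 0.01·`class_effect`) and adds a harmonic
  ripple (relative amplitude 0.3·`class_effect` at the double frequency).
  At `class_effect = 0` the classes are exchangeable by construction. The
  oscillation is multiplied by a slow (~1 s) positive envelope because
  resting alpha waxes and wanes in bursts; this also makes the channel
  processes super-Gaussian, which is precisely the non-Gaussianity the ICA
  source model assumes — without it the Gaussian background subspace is
  unidentifiable and FastICA cannot converge;
* **1/f background noise** (spectral exponent `noise_slope`, default 1),
  at 0.7 of the oscillation's scale;
* **blink artefacts** — a shared source of smooth 0.4 s bumps at Poisson
  rate `artifact_rate` (default 4/min), projected onto the seven frontal
  channels with a fixed topography and amplitude 8, i.e. large and sparse;
* per-channel random gains in [0.5, 2], which exist solely to exercise
  gain normalisation.

Ground truth (blink source and times, topography, gains, class parameters)
rides along with every recording, so artefact removal can be validated
against what was actually injected.

**What passing tests do and do not show.** The generator produces
EEG-like second-order structure, burstiness, artefacts and a controllable
class effect; it does not simulate volume conduction (channels are
independent apart from the blink), microstates, non-stationary drift, or
any physiological disease signature. Tests against it demonstrate that the
pipeline's machinery is correct and that a spectral-envelope class
difference of the injected kind is detected; they say nothing about
clinical performance on real recordings.

## Numerical choices, degenerate inputs

* constant channels fail gain normalisation with the channel named;
  all-zero channels pass through the wavelet stage unchanged with a
  warning; all-zero signals are degenerate for spectra and cepstra.
* EDF output quantises to the format's 16 bits over each channel's
  observed range; one-second records, so integer sampling rates and
  whole-second durations.
* Delimited recordings are samples-per-row with a channel-name header;
  non-numeric or non-finite cells are parse errors.
* seeds: every stochastic stage (ICA initialisation, fold shuffling,
  generation) takes an explicit integer seed and restores the caller's RNG
  state; per-subject seeds derive deterministically from the master seed.

## Problem sizes used by the automated suites

Unit and property tests run on reduced geometries (2–19 channels, 0.5–20 s
windows, 3–6 subjects) chosen so the whole suite completes in minutes; the
acceptance tests additionally run the full-size synthetic study
(2 × 504 epochs, fine KNN, 10-fold × 5 repeats) at `class_effect` 2 and 0,
and the acceptance script reports a mid-sized study (2 × 96 epochs) plus
all machine-precision invariants. Cross-validated accuracy at a given
`class_effect` is a property of the generator *and* the geometry: smaller
studies give fewer neighbours and lower accuracy, which is why the script's
mid-size accuracy sits below the full-size figure.

## Known limitations

* The log-energy threshold is static; adapting it to signal-to-noise
  conditions is out of scope here.
* Instantaneous frequency/amplitude extraction from the wavelet stage is
  not implemented — no downstream stage consumes it.
* No montage re-referencing, filtering, resampling or annotation handling;
  inputs are assumed artefact-clean apart from what ICA removes.
* The EDF reader supports plain EDF with a common sampling rate, not EDF+
  annotations or per-signal rates.
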