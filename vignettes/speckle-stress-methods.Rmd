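---
title: "Methods: speckle activity coefficients and hypoxic-stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle activity coefficients and hypoxic-stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic generators do and
do not emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The sensing problem

Apples stored under dynamic controlled atmosphere are held near their low
oxygen limit. Below the anaerobic compensation point, respiration turns
fermentative and the fruit accumulates damage, so storage systems need an
early, non-destructive hypoxic-stress signal. Two established signals are
the transient rise of minimum chlorophyll fluorescence F₀ and the change in
CO₂ respiration rate. The third signal implemented here is dynamic laser
speckle: coherent light scattered by biologically active tissue produces a
time-varying interference pattern whose fluctuation rate tracks internal
activity, and whose dynamics change when the tissue's physiology changes.

## 2. Speckle activity coefficients

### 2.1 Decorrelation curve and relaxation time

For a video stack of `n` frames, the curve `CORR(t)` is the Pearson
correlation between the flattened pixel vectors of two frames a lag `t`
apart, averaged over all frame pairs at that lag (the all-pairs estimator;
a first-frame-reference mode is available as a config flag, but the
averaged form has lower variance). Pearson correlation and all standard
deviations use sample (n−1) normalization throughout; this convention is
pinned by a hand-computed tLASCA example in the tests. A frame with zero
pixel variance makes the correlation undefined and raises an error naming
the frame.

The curve is summarized by the stretched-exponential
(Kohlrausch–Williams–Watts) decay

$$\mathrm{CORR}(t) = e^{-(t/\tau)^{\beta}},$$

with relaxation time τ (seconds) and stretch exponent β ∈ (0, 2]. One
deliberate deviation from the source description: the decay model is
sometimes printed with a positive exponent, `exp(+(t/τ)^β)`, which grows
without bound and cannot describe a curve that falls from 1; the standard
decaying KWW form is implemented instead. Downstream work uses τ* = ln τ,
which symmetrizes the heavy right tail of τ across fruit.

**Fitting protocol.** Bounded nonlinear least squares over all positive
lags; the lag-0 point is excluded because the model passes through 1
exactly and would otherwise pin the fit. Bounds: τ ∈ [lag_min/100,
100·lag_max], β ∈ [0.05, 2]. Two starts are tried: the heuristic (τ₀ = the
first lag where the curve crosses e⁻¹, β₀ = 1) and a linearized start from
regressing `log(-log CORR)` on `log t`, which is exact on model-generated
data. Each start is run through L-BFGS-B and polished with `nlminb` at
near-machine tolerances; the lower SSE wins. The `converged` flag does not
parrot optimizer return codes — both optimizers routinely flag
machine-precision optima as "abnormal" — but accepts a solution whose
numerical gradient has vanished (or whose residual is ~0). A curve whose
correlations all stay above `1 − tol_decay` (default `tol_decay = 1e-3`)
has no measurable decay and raises an error; `analyze_stack()` converts
that error into a partial record with the message in `fit_error`, because a
static clip still has well-defined tLASCA and IM (both 0).

The default maximum lag is half the clip length (900 frames of a 1800-frame
clip): long lags are averaged over few pairs and would otherwise enter the
residual with equal weight but much higher variance. This default is a
package choice, not a protocol statement, and is configurable.

### 2.2 tLASCA

Temporal laser speckle contrast: per pixel, the temporal standard deviation
of intensity across all frames divided by the temporal mean, then averaged
over pixels. Pixels with zero temporal mean (dark corners in real
acquisitions) have an undefined ratio; the default policy excludes them and
reports the count, a strict mode raises.

### 2.3 Inertia moment

The time-history speckle pattern (THSP) has one row per pixel and one
column per frame. Ordered pairs of time-consecutive quantized values
accumulate into a gray-level co-occurrence matrix, normalized by its total;
the inertia (contrast) moment is Σ GLCM[i,j]·(i−j)². The source prints the
weight as "(i,j)²"; the standard contrast weight (i−j)² is the only reading
under which static speckle (all mass on the diagonal) gives IM = 0, which
is how the coefficient is interpreted, so that is what is implemented.
Because the weight depends only on i−j, the scalar reduces to the mean
squared jump of quantized values between consecutive frames; the test suite
checks this fast route against a literal dictionary-of-pairs oracle.

Quantization defaults to the native `2^bit_depth` levels (no re-binning of
8-bit data); equal-width down-binning over the bit-depth range or the
observed data range is available. The data-range mode makes IM invariant to
positive intensity rescaling. The GLCM is accumulated asymmetric; a
symmetric option exists for convention compatibility (it cannot change the
moment — the weight is symmetric). All pixels contribute; some legacy
implementations sample a pixel subset, which is noted as a source of
numerical differences, not implemented.

## 3. The speckle simulator and its oracle

The simulator provides ground truth the real instrument cannot: a complex
circular-Gaussian field with *known* temporal correlation
`g₁(Δt) = exp(−(Δt/τ_field)^β_field)`. Construction: white complex
innovations per frame → spatial low-pass in the Fourier domain with cutoff
`1/(2·grain_px)` cycles/px → temporal mixing through the Cholesky factor of
the `n×n` lag covariance (with `1e-10` diagonal jitter; this caps practical
clip length around 2000 frames, enough for 60 s at 30 fps) → intensity
`|E|²` → scaling so the 99.9th percentile maps to `0.9·(2^bit_depth − 1)`
(avoids saturation clipping, which would bias correlations) → optional
additive Gaussian camera noise → rounding. Everything is reproducible
bit-for-bit from the seed, with the caller's RNG state restored.

For circular-Gaussian fields the Siegert relation gives the intensity
correlation `g₂ − 1 = |g₁|²`, so the Pearson curve the estimators see
decays as `exp(−2(Δt/τ_field)^β)` — a stretched exponential with the same β
and effective relaxation time `τ_field·2^(−1/β)`. This closed form
(`analytic_intensity_correlation()`, including a variance-ratio attenuation
factor under camera noise that assumes fully developed exponential
intensity statistics) is the acceptance surface: recovery of τ within 10%
and β within 0.15 across τ_field ∈ {0.2, 0.5, 2} s × β ∈ {0.7, 1} is
checked over 20 seeds per setting.

The simulator is phenomenological: it does not model tissue optics, pigment
absorption, or wavelength-dependent penetration. The RED/IR channel
contrast in real data can only be emulated by choosing different τ/noise
settings per channel.

## 4. Experiment-level synthesis

`simulate_experiment()` works at the coefficient level (simulating raw
video for every epoch of a 6.5 h protocol would be wasteful; the video path
is covered by the speckle simulator). Its defaults are the stated protocol:
2 h ambient preconditioning, 3.5 h zero-oxygen, 1 h restored atmosphere,
epochs every 8 min, 15 apples. Signals respond with a mean onset delay of
2.1 h after oxygen removal — exponential-jittered per apple with σ = 10 min
so detection-latency tests have spread (reported method latencies differ by
less than one 8-min epoch) — rising over ~2 epochs (logistic) to a plateau.
After restoration, τ* and CF relax back (midpoint 0.25 h after
restoration), respiration stays elevated through the final hour. The
"transition" phase tag covers the first 0.25 h of the final hour,
representing the 8–10 min atmosphere ramp; phase durations for it are not
separately specified by the protocol, so this is a package convention.

Numerical choices, fixed once and not revisited:

- **Effect sizes 6σ** per signal (in units of that signal's noise σ): a
  clear but not caricatured step, comfortably above the 3σ labeling
  threshold, within the "≥5σ" regime the truth-recovery property assumes.
- **Noise**: AR(1) with coefficient 0.3 (epochs 8 min apart are mildly
  autocorrelated), marginal σ per signal: 0.05 for both τ* channels, 5 for
  CF (baseline ~300 instrument units), 0.3 for respiration (baseline ~10).
- **τ*_RED between-apple baseline spread 3× that of τ*_IR** — the red
  channel is the less repeatable one (pigment-dependent), and this is what
  makes τ*_IR the better predictor in the classifier comparison.
- **chlorophyll_low_fraction = 0.2**: one in five apples shows no CF
  response at all (low-chlorophyll skin); their CF effect size is 0. This
  reproduces the situation where fluorescence-based sensing fails and
  speckle must carry the detection.
- **Phenotypes**: mass ~ N(163.92, 12.87²) g, firmness ~ N(41.15, 3.32²) N,
  SSC ~ N(12.67, 0.92²) % (reported sample moments); volume from mass at
  0.8 g/cm³ apple density with 5% noise; area from the sphere-equivalent
  model A = 4π(3V/4π)^(2/3).

The truth table marks epochs between onset and the recovery midpoint as
stressed, provided any effect size is positive — a world with all effects
zero contains no stress. The generator emulates signal *shapes* (levels,
steps, relaxation, noise); it does not emulate instrument drift, epoch
misalignment between devices, spatial CF heterogeneity, or fruit-to-fruit
covariance of responses, so a green truth-recovery test establishes the
labeling logic, not field performance.

## 5. Expert labeling

"Considerable change" is not quantitatively defined by the reference
procedure, so the package adopts a robust z-score: an epoch's signal flags
when it departs from the baseline (preconditioning-phase) median by more
than `k = 3` MAD-scaled σ in the signal's stress direction (increase for
τ*, CF and respiration). `k` is exposed; raising it can only shrink the
flagged set (tested as a monotonicity property). Zero baseline dispersion
falls back to a 10% relative threshold with a message. The epoch is labeled
hypoxic stress when ≥ 2 of the 3 signals flag. The τ role defaults to
τ*_IR (the stable channel); this is a package choice — the reference
procedure names "relaxation time" without a channel. Labeling is strictly
per apple and therefore invariant to apple order.

The labeler uses the respiration *level* (that is what an expert inspects),
while the classifier consumes its first derivative (central differences,
one-sided at the ends, h in hours) — both are computed, matching the
reference data preparation.

## 6. Classifier

"20-fold cross-validation with 70%/30%" describes repeated random
subsampling, not k-fold partitioning: 20 independent seeded 70/30 splits,
stratified by class (the reference is silent on stratification; without it,
small tables can draw single-class training sets — which are resampled with
a logged retry and a 10-attempt cap). Splits are drawn at the observation
level to match the published framing; a `group_by_apple` mode exists
because observation-level splitting leaks within-apple autocorrelation into
test scores. That leak is noted, not silently fixed: reported test metrics
under the default mode are optimistic relative to a new-fruit deployment.

No gradient-boosting library ships in the supported toolchain, so
`src/gbdt.cpp` implements a small deterministic GBDT: logistic loss,
leaf-wise growth to at most 6 leaves, exact greedy splits on presorted
features, 500 rounds, learning rate 0.05, `min_data_in_leaf = 20`,
hessian floor 1e-3, no L2 penalty — the fixed regime of the reference
models, with remaining knobs at common defaults. Ties in leaf selection
break to the lowest node index and presorting is stable, so fits are
bit-reproducible. Gain importance accumulates each chosen split's gain per
feature and is normalized to sum to 1; reported gain is the mean of
normalized per-split gains across the 20 splits (whether the reference
averaged across splits or refit once is unstated; averaging is adopted).
The backend name is recorded in every report so a substituted
implementation would be visible.

Metrics use the stress class as positive, decision threshold 0.5.
Zero-denominator ratios report 0 with a warning flag rather than NaN. The
F1 harmonic-mean identity is asserted per split before averaging.

The twelve variants pair each base signal (τ*_IR, τ*_RED, CF,
Δrespiration) with no extras (1–4), mass (5–8), or mass+firmness+SSC
(9–12). `run_variant_suite()` shares split assignments across variants
(same seed ⇒ same partitions), which is what makes the τ*_IR-vs-CF
comparison in acceptance criterion 7 a paired test.

## 7. Numerical conventions and degenerate inputs

- Floating comparisons in tests use absolute tolerance 1e-9 unless a looser
  tolerance is stated by the property being tested.
- Time is in hours for epoch tables, seconds for τ and lags; CSV output is
  UTF-8, comma-separated, `.` decimal, with `#` comment headers carrying
  configuration; floats serialize at 12 significant digits.
- Degenerate inputs have defined behavior throughout: static stacks (fit
  error, tLASCA = IM = 0), zero-variance frames (error with frame index),
  zero-mean pixels (policy), duplicate timestamps (error), single-class
  training splits (logged resample), all-zero confusion counts (error).
- The TIFF codec implements exactly the baseline subset it writes
  (uncompressed grayscale, 8/16-bit, little-endian, strip-organized) plus
  tolerant reading of either byte order; it was cross-validated against an
  independent TIFF implementation during development. Acquisition metadata
  travels as JSON in the first page's ImageDescription.

## 8. Known limitations

- The synthetic world is phenomenological; green tests establish estimator
  and pipeline correctness, not biological performance. Published
  performance numbers for the real protocol are computed on undeposited
  data and are out of scope as reproduction targets.
- Observation-level splits (the default, matching the published protocol)
  overstate generalization to unseen fruit; use `group_by_apple = TRUE`
  for a fruit-level estimate.
- The stretched-exponential fit assumes a monotone decay to ~0 within the
  fitted window; clips much shorter than τ yield weakly identified (τ, β)
  pairs — visible as inflated `rmse` spread across seeds, not guarded
  against beyond the bounds.
- tLASCA and IM are exposure-time sensitive in real acquisitions; the
  package computes them as defined and leaves acquisition optimization out
  of scope.
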