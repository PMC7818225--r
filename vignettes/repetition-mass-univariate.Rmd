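---
title: "Mass-univariate scalp-time analysis of ERP repetition effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate scalp-time analysis of ERP repetition effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`erpmass` implements a statistical-parametric-mapping analysis of how
event-related potentials (ERPs) change when an object is shown repeatedly.
The pipeline runs in six stages.

**Preprocessing.** Epoched EEG (61 scalp + 4 EOG channels, 500 Hz, epochs
-100 to 550 ms) is band-pass filtered 1--30 Hz, re-referenced to the common
average of the scalp channels, baseline-corrected to the 100 ms
pre-stimulus window, and cleaned by rejecting every trial on which any EEG
or EOG channel exceeds ±75 µV. Retained trials are averaged into 24
condition means per subject: 6 presentation indices × 4 experimental
blocks.

**Scalp-time volumes.** Each mean ERP is flattened to a 32 × 32 pixel
scalp map per time point over the 50--500 ms analysis window (226 frames at
500 Hz) and the stacked 3-D image is smoothed with a Gaussian kernel of
FWHM [16 mm, 16 mm, 16 ms]. All statistics are computed per voxel of this
space × time volume; pixels outside the electrode hull are NA and excluded
everywhere.

**First-level GLM.** The 24 condition means per voxel are modelled with a
24 × 8 design: four block indicators plus, per block, a mean-centred
parametric modulator encoding the hypothesized repetition trajectory
g(r) over presentations r = 1..6. Three models are fitted that share the
indicator columns and differ only in g: exponential
g(r) = exp(-(r-1)/tau), linear (decreasing), and a categorical "change
detection" first-presentation indicator. Centring within block makes each
modulator orthogonal to its block indicator, so the modulator beta
measures the repetition modulation and the indicator absorbs the block
mean. With a decaying positive component, suppression yields a positive
beta and enhancement a negative one.

**Group inference.** The four block betas are averaged per subject
(summary statistic) and tested voxelwise with a one-sample test across
subjects: F = t², df = (1, S−1). The reported (F, equivalent-Z) pairs of
the analysis this package reimplements are mutually consistent with
exactly this test at S = 17 — all nine pairs are reproduced by
`fToZ(F, c(1, 16))` to |ΔZ| < 1e-5 — which fixes the default degrees of
freedom.

**Random-field-theory FWE correction.** The voxel-level family-wise error
threshold is the F value at which the expected Euler characteristic (EC)
of the excursion set equals α = 0.05. Because df1 = 1, the F(1, v) field
is the square of a t field and its excursion set is the disjoint union of
the two symmetric t excursion sets; the EC densities are therefore exactly
twice the t-field densities, which is how `expectedEC()` computes them.
Smoothness is estimated from the standardized group residuals as
fwhm = sqrt(4 ln 2 / mean(∂residual²)) per axis, and the masked search
region is summarized as a cuboid with the same in-plane area and frame
count (edge and face resels included). Suprathreshold voxels are grouped
by 26-connectivity; up to three local maxima at least 8 mm or 8 ms apart
are reported per cluster, ordered by cluster size.

**Model comparison.** Per voxel and subject the Bayesian information
criterion approximates the log model evidence,
LME ≈ −(n/2) ln(RSS/n) − (k/2) ln n with n = 24 and k = 8. Because k is
identical across the three models, evidence differences reduce to
(n/2) ln(RSS ratio) — stated here explicitly to avoid misreading the
penalty terms. Per-pair differences are summed over subjects (the log
group Bayes factor) and summarized (median, mean, SD, % positive,
one-sample Kolmogorov–Smirnov D against the fixed standard normal,
Wilcoxon signed-rank Z with tie correction and no continuity correction)
both within a conjunction mask of voxels significant under the models and
over the whole volume. |ΔLME| > 5 is labelled very strong evidence.

# The synthetic generator

No recorded EEG ships with the package; every stage is exercised by a
generator that emulates the study design: 17 subjects, 4 blocks × 60
objects × 6 presentations at a 570 ms stimulus onset asynchrony, with a
posterior P1 (~+5 µV at 100 ms) and P2 (~+4 µV at 220 ms) base waveform.
Ground-truth repetition effects are planar-Gaussian spatial weights
(default FWHM 40 mm) around a centre channel, confined to a time window
with 10 ms raised-cosine ramps, with amplitude sign·A·g(r); the defaults
place four effects in the windows and scalp regions the analysis is built
to resolve (occipital 86--140 ms, occipitotemporal 320--340 ms,
temporoparietal 322--360 ms, frontotemporal 400--446 ms), all exponential
with tau = 1. Noise is Gaussian, spatially correlated as
exp(−arc distance / 50 mm) on an 85 mm sphere, spectrally shaped to
1--30 Hz, with 12 µV per-sample SD per single trial; subject amplitudes
are drawn once per subject from Normal(A, subjectSd²) truncated at zero.

What the generator does *not* emulate: ocular and muscle artifact
morphology (artifacts are injected as synthetic transients only to test
the ±75 µV rule), trial-to-trial latency jitter, non-stationary noise,
volume-conduction-accurate topographies, or overlap of adjacent-trial
ERPs at the short SOA. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative model, not validity
on any particular recorded dataset.

## Calibration of the free effect sizes

The source analysis reports statistics but not effect sizes in µV, so the
default amplitudes are free parameters. Two stated conditions constrain
them: group peak F values of the order seen in the reimplemented results
(~30--60), and voxelwise model recovery — the group ΔLME must favour the
generative exponential model over the linear and change-detection
alternatives in ≥95% of effect voxels. These pull in opposite directions:
the centred exponential (tau = 1) and change-detection regressors share
98.3% of their variance, so separating them needs a high fixed-effects
SNR, while the group F is governed by the ratio of amplitude to
between-subject SD. The defaults were therefore calibrated jointly — once,
before the acceptance tests were frozen — to amplitudes of 6.5--8 µV with
subjectSd = 2.8 µV (ratio ≈ 2.3--2.9). This favours the recovery
condition; resulting group peak F values run well above the ~30--60
anchor (the acceptance script reports the realized peak per run), a
deliberate trade-off documented here rather than revisited.

# Numerical choices

* **Filter.** "24 dB/octave" is realized as a 4th-order Butterworth
  section per band edge. Zero phase (to avoid latency shifts in the
  86--140 ms window) is implemented by applying the squared magnitude
  response in the frequency domain with 1 s odd-reflective padding —
  identical in magnitude to forward–backward filtering and exactly linear
  phase. Epochs are filtered (the synthetic data are generated epoched);
  the padding default is a config field.
* **Rejection ordering.** Whether the ±75 µV rule applies before or after
  filtering/baseline is ambiguous in such pipelines; the default applies
  it to the filtered, baseline-corrected values, the alternative is a
  config flag, and the choice is echoed in the output metadata.
* **Projection scale.** FWHM is specified in mm but the original pixel
  pitch is unknowable, so the grid fixes 4.25 mm/pixel (32 pixels ≈ a
  flattened 85 mm head). An azimuthal-equidistant projection at true
  85 mm scale would put the outer electrode ring outside that grid, so
  the projection preserves arc distances up to one global scale chosen so
  the 90° circle lands at 60 mm (`rimMm`); every electrode then falls
  inside the grid with margin for the interpolation hull.
* **Interpolation.** Delaunay-triangulation barycentric-linear
  interpolation (implemented in the package: Bowyer–Watson with
  ties-inside circumcircle handling, since the exactly cocircular outer
  ring otherwise degenerates). It is exact for affine fields and local;
  out-of-hull pixels are NA rather than extrapolated, because
  extrapolated voxels would be untestable.
* **Masked smoothing.** Separable Gaussian, σ = FWHM/√(8 ln 2) per axis
  in voxel units, kernel truncated at 4σ, with mask-weighted
  renormalization so in-mask outputs are convex combinations of in-mask
  inputs and the NA pattern is invariant.
* **Smoothness estimator.** First differences of unit-variance
  standardized residuals; for white noise this converges to
  √(2 ln 2) ≈ 1.18 voxels rather than 1 (the discrete-difference analogue
  of the continuous formula), and it overestimates large FWHM by a few
  percent — both conservative directions for the EC threshold, and the
  null simulations confirm the realized family-wise error rate stays at
  or below the nominal 0.05.
* **Resels.** The EC computation summarizes the masked region as an
  equivalent cuboid (same in-plane area, same frame count). The exact
  Lipschitz–Killing curvatures of the staircase mask are not computed;
  the approximation error is absorbed by the same conservatism.
* **Degenerate inputs.** Zero-variance voxels get F = ∞, are flagged and
  excluded from thresholding; zero-RSS voxels have undefined log evidence
  and are returned NA; with df2 = 2 the F-field EC density does not decay
  and no threshold attains α — `fweThreshold` reports this instead of
  looping.
* **Design decisions on open points.** The conjunction mask defaults to
  the intersection ("all") with the union available as `mode = "any"`
  (the two descriptions of the original mask conflict; the Methods-style
  intersection was chosen). The KS reference is the fixed standard normal
  with no parameter estimation. tau is an exposed parameter (default 1
  presentation) rather than an asserted ground truth.

# Problem sizes used by tests and the acceptance script

Multi-dataset runs use a scaled-down design: 2 objects per block instead
of 60, with the single-trial noise SD rescaled to 12·√(2/60) µV so that
the *condition-mean* noise (1.55 µV per channel and sample) equals the
full design's. This preserves every distributional property of the
subject-level statistics while cutting simulation cost thirtyfold. The
family-wise error simulations run on a reduced 16 × 16 × 64 grid with the
default smoothing expressed in voxel units. These sizes are the package's
chosen test conditions and are stated wherever results are reported.

# Limitations

Fixed-effects model comparison only (no random-effects exceedance
probabilities); voxel-level FWE only (no cluster-extent p-values); no
source reconstruction — inference stays at the scalp level; the RFT
threshold assumes a stationary, sufficiently smooth field, which the
default 16 mm/16 ms kernel is there to secure; and the generator's
simplifications listed above bound what a green test suite can claim
about recorded EEG.
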