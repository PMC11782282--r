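---
title: "Fixation saliency analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation saliency analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesal)
```

## The scientific problem

Cerebral/cortical visual impairment (CVI) produces visual deficits that
standard ophthalmic testing cannot characterize in young or
developmentally delayed children, because higher-order deficits (face
recognition, depth, figure–ground segregation, visual complexity) are
normally probed with neuropsychological instruments that require verbal
cooperation. Free-viewing eye tracking sidesteps that requirement: the
child only watches images on a monitor.

gazesal implements the quantitative core of this approach. Each stimulus
image is paired with feature-specific grayscale **saliency maps** — one
map per visual feature (red, luminance, faces, depth, background, ...),
each produced by an external generator and normalized to 0–255. Fixations
are detected from the raw gaze stream, and each fixation is assigned a
**fixation saliency value**: the intensity of the map pixel under the
fixation's center. High values on a feature's map mean the viewer's gaze
preferentially landed where that feature is present. Per-feature values
are averaged per image and then per participant, and participant means
are compared between groups.

## Viewing geometry

All angular thresholds require a pixel-to-degree model. `screen_geometry()`
stores the display resolution, physical size and viewing distance (60 cm
in the intended setup), and `px_to_deg()` converts with the exact per-axis
arctangent,

$$\theta_x = \arctan\!\left(\frac{(x - c_x)\,s_x}{d}\right),$$

where $s_x$ is cm per pixel and $d$ the viewing distance. The small-angle
linear form would be accurate to ~0.5% at 10°, but the exact form costs
nothing and inverts cleanly (`deg_to_px()` is the identity inverse to
1e-9 px, which the test suite asserts over off-screen points too). The
coordinate convention is the eye-tracker one: origin top-left, x
rightward, y downward, 0-based, pixel centers at integer coordinates.
Monitor physical size is configurable; the 53.1 × 29.9 cm default is a
generic 24-inch 16:9 panel.

## Event detection

The detector honors two definitions simultaneously:

* **saccades** — ballistic movements whose peak speed exceeds 30 deg/s
  *and* peak |acceleration| exceeds 8000 deg/s² over an amplitude greater
  than 0.1°;
* **fixations** — periods in which gaze stays within 0.1° of its centroid
  for at least 100 ms.

Composition order was a genuine design choice. We run the kinematic
saccade picker first and then carve fixations from the inter-saccade
segments with a greedy left-to-right dispersion rule (I-DT style). At the
sample level, a candidate saccadic sample is one where speed *or*
|acceleration| exceeds its threshold — a disjunction is necessary because
a smooth saccade's acceleration crosses zero exactly at peak velocity, so
demanding both per sample would split every saccade in half. The
event-level acceptance is conjunctive on the peaks, so every emitted
saccade satisfies all three stated criteria.

Other numerical choices:

* **Dispersion** is the maximum member-sample distance from the running
  centroid (a radius), not a bounding box: it is rotation invariant and
  matches the intuition of "stable within 0.1 degree". Whether the stated
  0.1° is a radius, diameter or box is ambiguous in common usage; radius
  is our convention and the parameter is configurable for sensitivity
  analysis.
* **Kinematics** are central differences of the degree-space position
  (one-sided at segment ends) on the denoised trace at 500 Hz, with no
  parametric smoothing — the simplest defensible estimator at this rate.
* **Denoising** replaces the vendor's unpublished "heuristic filter" with
  a documented 3-sample sliding median over valid samples: it removes
  one-sample spikes exactly and leaves monotone ramps untouched. It runs
  by default and can be disabled in the pipeline config.
* **Gaps**: samples with neither eye valid break differentiation windows
  and events; no event spans a gap longer than two nominal inter-sample
  intervals. Blink interpolation is out of scope.
* **Greedy tie-break**: the dispersion window always extends as far right
  as possible before closing, which makes detection deterministic.

Binocular streams are composited before detection: both eyes valid →
positions averaged; one valid → that eye used unchanged (monocular
recording from the fixating eye must be first-class in strabismus);
neither → invalid sample.

## Saliency maps

Raw generator output is smoothed with a separable Gaussian and min–max
normalized to integers 0–255 (round half away from zero), so every
non-constant map attains 0 and 255 exactly. Three details matter:

* The smoothing boundary is half-sample symmetric reflection, which
  conserves total map mass exactly (a Neumann boundary); the suite checks
  this to 1e-6 even for kernels wider than the map.
* The generator's Gaussian width is not standardized anywhere, so the
  default is scale-free: σ = 2% of map width, configurable and recorded
  in output metadata.
* A constant raw map normalizes to all zeros and is flagged `constant`;
  the scoring stage refuses it with an explicit error, because a constant
  map carries no feature signal and would manufacture identical values
  for every fixation.

**Differential maps** (paired opposite prompts, e.g. foreground vs
background) subtract the *raw* maps and then smooth-and-normalize the
signed difference over its full range — negatives are informative and are
not clipped. Normalizing each map first and then subtracting is a
coherent alternative; we chose raw-first subtraction and note that the
two differ when the two prompts have very different dynamic ranges.
Swapping the operands yields the 255-complement map, which the tests
assert.

Maps are consumed as 8-bit grayscale PNG via a manifest CSV; any program
that writes such a PNG from (image, prompt) satisfies the generator
contract, so specific segmentation or gaze-prediction models stay
external to the package.

## Scoring rules

* **Out-of-image rule**: a fixation is discarded when its centroid is
  more than 20% of the image dimension outside the image, per axis
  (`margin_frac = 0.20`). A radial reading of the same rule is plausible;
  per-axis is the most literal and the fraction is a parameter.
* **In-margin but off-image** fixations are scored at the nearest
  boundary pixel (clamping): the rule keeps these fixations but the map
  exists only over the image, and clamping is the assumption-minimal
  lookup. Each record carries an `off_image` flag so the choice is
  auditable.
* **Nearest-pixel lookup**, no interpolation: intensities are defined per
  pixel.
* **Trial assignment** of a fixation straddling a boundary is by temporal
  midpoint.
* **Aggregation**: per-image mean first, then the participant's overall
  mean as the unweighted mean of per-image means. This follows the stated
  analysis order and prevents long trials from dominating a participant's
  summary. Trials with no surviving fixation are excluded before
  averaging.

## Statistics

* `mann_whitney_u()` computes U with midranks. For $n_a + n_b \le 12$ the
  two-sided p is exact by full enumeration of the
  $\binom{n_a+n_b}{n_a}$ group labelings (ties need no correction — the
  enumeration sees them); otherwise a tie-corrected normal approximation
  with continuity correction. The suite proves the exact branch equals an
  independently written brute-force enumerator on every input with
  $n_a+n_b \le 10$, checks the approximation against the exact
  distribution at 20+20 (agreement better than 0.02), and calibrates the
  null rejection rate to [0.04, 0.06] at α = 0.05 over 2000 replicates.
* `spearman_rho()` is the product-moment correlation of midranks; p-values
  are exact by permutation for $n \le 8$, t-approximate otherwise.
* `covariate_regression()` is OLS with intercept (via `lm()`), with an
  explicit rank check that names collinear columns. The study plan's
  "multivariate regression" is read as multivariable OLS on the
  participant-level summary.
* `sample_size_two_means()` implements the closed form
  $n = 2(z_{1-\alpha/2} + z_{\beta})^2 \sigma^2 / \Delta^2$. With means
  48 and 43, SD 8, α = 0.05, power 0.80 this is 40.19 per group; the
  headline value uses nearest-integer rounding (40 per group, 80 total),
  which is the convention that matches the design figure — ceiling would
  give 41, and both are reported, along with an ARE-adjusted (3/π)
  Mann–Whitney size as an optional column. `mc_power_two_sample()`
  verifies the design empirically: 10,000 Monte-Carlo cohorts at 40 per
  group give ~79% power against the analytic Welch value of 78.8%.
* No multiple-testing correction is applied across features by default
  (the analysis plan specifies raw per-feature p-values); a
  Benjamini–Hochberg column is available via `adjust = TRUE`.

## Stimulus spectrum

`high_freq_energy_fraction()` supports the acuity-threshold rationale: if
essentially all stimulus energy lies above a viewer's grating-acuity
cutoff (e.g. 3 cpd), the viewer cannot resolve the content. The 2-D FFT
power spectrum is computed (optionally Hann-windowed; the default is the
plain transform), the DC bin is excluded, and per-axis cycles-per-degree
scales — exact trigonometric subtense, anisotropic pixels handled —
combine into a radial frequency. The suite checks Parseval's identity, a
single-line grating, a flat-spectrum bin-counting oracle, and monotonicity
in the threshold. Published percentages of this kind depend on the
specific stimulus set and are treated as context, not as a reproduction
target.

## The simulator and what passing tests mean

`simulate_recording()` is the validation harness: a simulated viewer
samples fixation targets with probability proportional to a weighted
mixture of map intensities (weights $w_f \ge 0$, $\sum w_f \le 1$, the
remainder uniform exploration), holds each target for a truncated-normal
duration (default mean 250 ms, SD 50 ms, floor 80 ms), and transitions
between targets along minimum-jerk trajectories whose peak speed
($1.875\,A/T$) and peak acceleration ($\approx 5.77\,A/T^2$) scale with
amplitude, so multi-degree saccades comfortably trip the 30 deg/s and
8000 deg/s² thresholds at the default 30 ms transition time. Gaussian
jitter is added independently per eye, so binocular compositing halves
its variance exactly as with a real tracker. The 80 ms duration floor is
deliberately below the 100 ms detection minimum so every simulated
session exercises the rejection path; ground-truth comparisons therefore
count the scripted fixations of duration ≥ 100 ms as the detectable set.

This design has closed-form consequences used as oracles:

* a weight-1 viewer's expected fixation saliency value on map $M$ is
  $\sum I^2 / \sum I$ over the map intensities, and in general
  $E[v] = w \sum I^2/\sum I + (1-w)\,\bar I$, strictly increasing in $w$
  for any non-constant map;
* fixation counts follow a renewal process with rate
  $T/(\mu_{\text{fix}} + T_{\text{sacc}})$.

An optional `min_target_sep_deg` enforces a minimum angular separation
between consecutive targets by rejection resampling. It exists because
two consecutive targets closer than the dispersion threshold are
*correctly* merged into one fixation by any dispersion-based detector;
recovery tests that require exact count matching enable it (1°), while
closed-form mean checks keep it at 0 because rejection biases the target
marginal slightly.

What the simulator does **not** emulate: nystagmus and smooth pursuit,
blinks beyond validity gaps, pupil dynamics, calibration drift, head
movement, and any statistical structure of real scanpaths beyond
map-weighted target selection (no inhibition of return, no saccadic
momentum). Passing the recovery suite therefore shows the pipeline is
correct *given* its event model, not that the event model captures every
oculomotor phenomenon of the clinical population — in particular, event
*timing* under nystagmus is known to be unreliable, and such recordings
need the subgroup analyses the stats module provides.

Cohort simulation derives per-participant seeds deterministically from a
master seed, so identical seeds reproduce recordings byte-for-byte
through the CSV writer.

## Problem sizes used in validation

The shipped tests run miniature versions of the full design: cohorts of
one to two participants per group, one to six trials of 1.5–8 s at
500 Hz, 800 × 800 px maps, 10,000 Monte-Carlo replicates for the power
verification and 2000 for null calibration. These sizes were chosen so
the whole suite completes in a few minutes while keeping every Monte-Carlo
margin (3 SE bands, ±3 percentage points on power) well clear of its
noise floor.

## Known limitations

* The greedy I-DT carve is $O(L^2)$ in the length of a stable segment;
  at 500 Hz with multi-minute uninterrupted stable gaze it is noticeably
  slower than the event-rate-typical case. Real recordings with normal
  saccade rates are unaffected.
* The out-of-range margin, dispersion measure and in-margin clamping are
  stated conventions for genuinely ambiguous rules; all three are
  parameters, and sensitivity analyses should vary them.
* `load_map_png()` down-converts >8-bit PNGs with a warning rather than
  preserving depth; the scoring scale is defined as 0–255.
* The sample-size formula is the normal-approximation means formula; for
  a rank-test analysis the ARE-adjusted column is the safer number.
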