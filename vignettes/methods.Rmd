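---
title: "Methods: camera-based blood pressure from the palm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera-based blood pressure from the palm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmbp)
```

`palmbp` estimates systolic and diastolic blood pressure (SBP/DBP) from the
pulse signal a webcam sees in the palm. This vignette explains the model,
the procedure, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices the implementation
makes where the design was genuinely open.

## The physiological signal model

Arterial pulse pressure is modelled as a harmonic series of the cardiac
fundamental: with angular frequency $\omega_H$, harmonic amplitudes
$(a_k, b_k)$, subject-to-lens distance $z$ and wave speed $c$,

$$p(z, t) = \sum_{k=0}^{N} \left[a_k \cos(\omega_H k t) + b_k \sin(\omega_H k t)\right] e^{-kz/c}.$$

The zeroth term is the baseline reflectance; the first harmonic dominates,
and higher harmonics are weak corrections (the classic simplification keeps
only $k \le 1$). `simulate_pulse_wave()` samples this model at a chosen
frame rate with optional Gaussian sensor noise. Blood-volume changes
modulate light absorption, so the camera's green channel — the one most
sensitive to hemoglobin — carries this waveform: systole (maximum volume,
maximum absorption) shows as a reflectance valley in raw intensity; after
sign alignment the package works with peaks above valleys.

## From frames to features

**ROI.** The palm quadrilateral runs through hand landmarks 1, 5, 17 and 0
(thumb base, index base, pinky base, wrist). Pixel membership uses the
even-odd rule on pixel centers in 0-based coordinates — deterministic and
orientation-independent. Landmarks arrive through a provider interface (a
JSON fixture reader ships with the package), so nothing depends on a camera
or a bundled detection model.

**Normalization.** Each channel's per-frame ROI mean is z-scored over the
whole 10 s capture, dividing by the population (n-denominator) standard
deviation — the same convention the ICA whitening step uses. A constant
channel maps to zeros. Normalization happens before ICA by default
(`prenormalize = TRUE`); the flag exists because the ordering is a
convention, not a necessity.

**ICA.** The channel matrix is centered, whitened by eigendecomposition of
the population covariance, and decomposed by deflationary FastICA.
Whitening drops directions whose eigenvalue is below `var_threshold`
(default `1e-6`, relative to the total variance): this rejects numerically
null directions — for instance, when only the green channel actually varies
— without discarding weak pulse signal. The contrast is log-cosh
($g = \tanh$), the robust standard choice; a cubic (kurtosis) alternative
is available. Components are estimated one at a time with Gram–Schmidt
decorrelation; each weight vector iterates until the inner product of
successive iterates exceeds $1 - \mathrm{tol}$ (default `1e-6`) or
`max_iter` (200) is reached, in which case the result is flagged
unconverged rather than raised as an error. Initial weights are seeded
standard normals, so everything is reproducible. The pulse component is the
one with the largest spectral-power fraction in the physiologic band
0.7–3 Hz (42–180 bpm), sign-aligned so mean peak exceeds mean valley. When
the mixing matrix is known (fully synthetic experiments),
`semiblind_unmix()` inverts it exactly instead.

**Peak/valley features.** Extrema are strict 3-point local maxima/minima;
runs of equal samples (plateaus, common in 8-bit data) count once at the
run's first sample. A refractory filter then removes, iteratively, the
earliest adjacent peak–trough pair closer than
`round(min_interval_s * fps)` samples (default 0.25 s — half of the
shortest credible cardiac half-period; at 120 bpm and 20 frames/s a beat
spans 10 samples and the filter gap is 5). Removing whole adjacent pairs
preserves peak/valley alternation by construction, so the retained extrema
always alternate and respect the interval. A measurement splits the first
10 s into ten consecutive 1 s windows, averages each window's retained
peaks (valleys) to one value, and averages the per-window values into
`Epeak` (`Evalley`); windows in which nothing survives are skipped and
reported via `windows_used`.

## The two calibration routes

Both routes regress device (cuff) readings on BMI and one pulse feature.

**Empirical formula + NM-PSO.** $BP = \alpha_0 + \alpha_1 x +
\mathrm{BMI}(1 + \alpha_2 x)$, with $x = E_{peak}$ for SBP and
$x = E_{valley}$ for DBP, fitted separately per BMI interval. The fitness is
the mean squared error over the interval's subjects — the minimal loss
consistent with reporting RMSE. Default intervals follow the Taiwanese
MOHW convention ($<18.5$, $18.5$–$24$, $24$–$27$, $\ge 27$ kg/m²),
half-open on the right and fully overridable. Intervals with fewer than
three subjects (three unknowns) raise an error naming the interval, and a
constant feature raises a non-identifiability error.

The optimizer is the hybrid Nelder–Mead / particle swarm: for dimension
$N$, $3N+1$ particles start uniformly in the search box; each iteration
sorts the swarm, applies one simplex step (reflection $\alpha=1$, expansion
$\gamma=2$, contraction $\beta=0.5$, shrink factor 0.5) to the best $N+1$,
then a global-best PSO update (inertia $w=0.5$, accelerations
$c_1=c_2=1.5$, fresh $U(0,1)$ draws per particle per dimension) to the
worst $2N$ only. Velocities are clamped to magnitude 120 and positions to
the box; the nominal box $[0, 120]$ is widened to $[-120, 120]$ for
coefficient fitting, since a one-signed box would forbid negative intercept
corrections (and a velocity floor of 0 would forbid leftward motion
entirely). Particles moved by the simplex get their velocity reset to zero
— the hybrid defines no velocity for simplex moves. Ties sort stably by
particle index; the run stops early when the swarm's fitness spread falls
below $10^{-10}$, otherwise after `n_iter` iterations (default 100). In the
simplex step the contraction test compares the reflection against the
*second-best* vertex, which makes contraction more frequent than in
textbook Nelder–Mead but preserves convergence (a failed contraction
shrinks toward the best vertex).

**Regression.** $BP = \gamma_0 + \gamma_1 \mathrm{BMI} + \gamma_2 E$,
solved by QR least squares — numerically stable and mathematically equal to
the normal equations $(X'X)^{-1}X'y$, which the tests verify explicitly.

Because both formulas absorb the scale of the features, coefficients are
only meaningful under the preprocessing that produced their calibration
features. `calibrate_cohort()` therefore embeds a fingerprint (a short hash
of the canonical JSON of the preprocessing configuration) and
`measure_bp()` refuses to predict under a different configuration.

## Validation metrics

`mae()`, `mape()`, `rmse()` follow their standard definitions;
`aami_check()` passes when MAE $\le 5$ mmHg and the signed-error sample SD
(n−1 denominator) $\le 8$ mmHg; `bhs_grade()` grades the cumulative
percentages of absolute errors within 5/10/15 mmHg (A: $\ge$ 60/85/95%,
B: 50/75/90%, C: 40/65/85%, else D — the published BHS protocol thresholds,
supplied as an overridable matrix since conventions differ in detail).
Confidence intervals use the normal approximation
$\bar{x} \pm 1.96\, s/\sqrt{n}$, consistent with standard device-validation
reporting.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws BMI and features uniformly, enforces
$E_{peak} > E_{valley}$ by swapping, and assigns device readings from the
empirical formula plus Gaussian device noise; it is a pure function of its
seed. `render_synthetic_frames()` writes the pulse into the green channel
inside a palm polygon (amplitude 5 intensity units on a baseline of 120,
clipped to 8-bit — a realistic webcam dynamic range) over a static seeded
background, and emits landmarks at the polygon's vertices.

`synthetic_subjects()` builds closed-loop study cohorts: resting subjects
with heart rates 63–90 bpm, a random systolic phase, and a second harmonic
of 5–22% of the fundamental. Those ranges are dictated by what the windowed
measurement procedure can process, not by convenience: a second harmonic
much above a quarter of the fundamental creates dicrotic secondary extrema
spaced inside the 0.25 s refractory interval (the filter then removes
entire windows), and a 60 bpm subject whose peak sits exactly on a 1 s
window boundary is invisible to in-window 3-point detection in every window
because the period is commensurate with the window. Device readings are
generated by applying true coefficients to the features extracted through
the *same* preprocessing path (the default true coefficients are chosen to
give normotensive pressures on the z-scored feature scale), so calibration
followed by measurement should close the loop exactly up to optimizer
residual — which is what the pipeline tests assert (RMSE $\le 1$ mmHg,
noiseless).

What passing these tests does **not** show about real data: the generator
has no motion artifacts, no lighting drift, no skin-tone or perfusion
variability, no camera compression noise, and its device readings follow
the fitted formula's own functional form. Synthetic closed-loop accuracy is
a consistency check of the implementation, not evidence of clinical
accuracy; the formula-generated cohorts likewise make the AAMI-bound tests
a statement about noise handling, not about human physiology.

## Numerical choices and problem sizes

* Noiseless closed-loop checks run the optimizer at `n_iter = 400` (the
  convex MSE bowl needs deep polishing to reach sub-mmHg residuals);
  everything else uses the default 100 iterations.
* Test and acceptance problem sizes: cohorts of 200 subjects (150/50
  train/holdout) over ten seeds for the validation-bound checks; 20–40
  subjects for closed-loop pipeline checks; 1500–4000 samples for ICA
  property checks. These sizes put sampling error well inside the asserted
  tolerances while keeping the whole suite near ten seconds.
* Degenerate inputs are errors with typed condition classes
  (`palmbp_no_beats`, `palmbp_degenerate_roi`, `palmbp_singular_design`,
  `palmbp_calibration_mismatch`, ...), so callers can distinguish them
  programmatically; a constant channel z-scores to zeros rather than NaN;
  empty frame lists yield empty traces.

## Known limitations

* The BMI-interval table does not extrapolate: a BMI outside every
  calibrated interval is an error by design.
* Heart rates at or above 120 bpm approach the refractory filter's limit
  (peak–trough spacing 0.25 s) and will lose beats.
* The ten-window procedure assumes consecutive, non-overlapping windows and
  at least 10 s of signal.
* FastICA convergence is not guaranteed; unconverged components are
  returned flagged rather than raised, and the band-power selection step is
  a heuristic, not an artifact classifier.
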