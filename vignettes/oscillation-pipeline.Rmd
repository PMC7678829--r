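---
title: "Quantifying transverse muscle oscillations from B-mode ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transverse muscle oscillations from B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonomuscle)
```

`sonomuscle` measures the transverse (deep–superficial) oscillations of
muscle tissue during gait from B-mode ultrasound, alongside the impact
content of the ground reaction force and the wavelet intensity of surface
EMG. This vignette documents the models behind each stage, the parameters
that matter, the synthetic data that the test suite runs on, and the
numerical and design choices that were genuinely open.

## The measurement problem

A probe strapped over the calf images the soleus at roughly 80 frames/s
over a 60 x 50 mm field of view. The superficial and deep aponeuroses of
the muscle appear as two bright, nearly horizontal bands. When the foot
strikes the ground, an impact transient travels into the limb and the
muscle oscillates transversely about its gross gait motion. Three signal
chains quantify this:

1. ultrasound → landmark tracking → displacement spectra;
2. vertical ground reaction force → impact input frequency;
3. EMG → time-resolved intensity (the muscle's activation state shapes how
   it damps impact energy).

## Active-shape-model segmentation

Each aponeurosis is represented by 19 landmarks at fixed columns
`x_j = 16 + 32 j` px, spanning the 608 px image width. Only the row
(depth) coordinates move.

**Shape model.** Training shapes (38-vectors) are averaged and their
covariance eigendecomposed; the smallest set of leading modes reaching
98% of total variance is kept (`variance_fraction`, default 0.98). No
Procrustes alignment is applied: the absolute position of the aponeurosis
relative to the skin-mounted probe *is* the measurand, so translation must
stay inside the shape space rather than being factored out as pose. A
degenerate training set (identical shapes) yields a valid zero-mode model
that always returns the mean.

**Profile model.** At each landmark and each resolution level (the image
is Gaussian-smoothed and decimated by two per level), the intensity
derivative is sampled along the local boundary normal — perpendicular to
the line joining the neighbouring landmarks, which for these near-
horizontal boundaries nearly coincides with the image column — at
`2k + 1` points (`k = 6` by default) and normalised by its absolute sum.
Mean and covariance over the labelled frames form a Gaussian profile
model per landmark and level.

**Search.** Coarse-to-fine; five levels for the first frame of a sequence
(whose initialisation, the PDM mean, may be far from the target), three
for subsequent frames (initialised from the previous frame's solution).
At each iteration every landmark evaluates `2 * search_range + 1`
candidate offsets (`search_range = 4` steps) along its normal and takes
the one minimising the Mahalanobis distance to its profile model, with
ties broken toward the smallest displacement for stability. The updated
point set is projected onto the PDM with every mode coefficient clamped
to ±3 standard deviations, the x-coordinates are re-pinned to the
standard columns, and iteration stops when fewer than 10% of landmarks
move more than 1 px or after `max_iter = 20` iterations. Non-convergence
returns the best shape with a flag rather than an error; a failed frame
carries the previous shape forward and is flagged.

**Numerical choices.** The profile covariance is regularised by adding
`1e-6` times its mean diagonal to the diagonal, so single-frame training
and flat image patches stay invertible; a profile that would leave the
image is clamped to the edge and the landmark flagged in the model
metadata. Profile half-length, search range, convergence rule and
variance fraction are engineering defaults exposed as arguments — the
method itself does not prescribe them.

**Per-source training.** A model is bound to one image source
(participant / probe setup); the CLI refuses to apply it across sources
without `--force`, since profile statistics do not transfer reliably
between probe placements.

## Synthetic ultrasound

`generate_image_sequence()` renders, per frame, two bright bands with
Gaussian cross-section (`band_sigma_px = 3`) over a multiplicative
speckle field: Rayleigh-distributed noise smoothed with a Gaussian kernel
(`speckle_sigma_px = 1.2`) and normalised to unit mean, scaled over a low
background. Both boundaries are quadratic curves translating vertically
with a prescribed trajectory: a low-frequency gait component plus any
number of sinusoidal oscillation components, all below Nyquist. The exact
landmark rows at the 19 standard columns are returned as ground truth, so
segmentation accuracy and spectral recovery are directly checkable.

The default image is 608 x 512 px for 60 x 50 mm (≈ 0.0987 x 0.0977
mm/px) so that the 19 landmarks at 32 px spacing span the width; actual
probe pixel dimensions vary between devices, and this choice is recorded
in the scene configuration rather than assumed elsewhere.

What the generator does *not* emulate: anisotropic speckle correlation,
fascicle striations, attenuation with depth, out-of-plane motion,
probe-pressure deformation, or boundary shape change beyond vertical
translation of a fixed curve. Passing tests therefore demonstrate that
the pipeline recovers known motion under realistic speckle statistics —
not that it is robust to every in vivo imaging artifact.

## Force traces and the impact input frequency

The estimator defines the input frequency from the interval `Δt` between
the maximal rate of force development (RFD, the central-difference time
derivative of the vertical force) and the first force maximum after it:
that interval spans a quarter of a whole oscillation of the impact
transient, so `f = 1/(4 Δt)` under the default `quarter_wave` convention.
A literal reading of "inverse of the time between" gives `f = 1/Δt`; both
conventions are implemented (`direct_inverse`), they differ by exactly a
factor of four, and every result records which one produced it. The
quarter-wave convention is the default because it yields physiologically
plausible 10–20 Hz magnitudes for observed rise times of 10–25 ms.

The search for the impact is confined to the first 25% of stance
(`impact_window_fraction`): transients occur in early stance, and the
late-stance push-off peak must not be mistaken for an impact. For
walking-like traces without a distinct transient the estimator falls back
to the window's maximum (the first hump).

The synthetic running trace is a raised-cosine impact transient — whose
steepest rise is at a quarter period and whose peak is at a half period,
making `Δt = 1/(4 f)` exact by construction — plus a delayed active bump
whose onset slope is zero so superposition cannot disturb the early-stance
timing; walking is the classic double hump whose first hump rises at the
impact frequency. Traces are generated noiselessly, so timing estimates in
the tests are read from the raw samples; the zero-phase 60 Hz 4th-order
Butterworth low-pass (the conventional treatment for measured force) is
applied for stance detection, and zero-phase filtering is used throughout
the package precisely so that no timing estimate is lag-shifted. Stance
detection itself is a 20 N threshold crossing with sub-100 ms intervals
discarded.

## EMG wavelet intensity

Center frequencies follow `cf_j = (1/scale) (j + q)^r` with `scale = 0.3`,
`q = 1.45`, `r = 1.959` — the standard parameterisation, which places the
11 bands at 6.90–395.44 Hz. Each wavelet is a frequency-domain gain
`(f/cf)^(cf·scale) exp((1 − f/cf) cf·scale)`, unimodal with its maximum
at `cf`; gains are evaluated on the trace's FFT grid, peak-normalised to
1, and zeroed at DC.

Intensity is computed as the squared analytic-signal envelope of each
band-filtered trace divided by two, i.e. the instantaneous mean-square
power (a unit sinusoid at a center frequency gives 0.5). This analytic-
signal demodulation is an equivalent, simpler alternative to the
original's Gauss-filtered instantaneous power for bands of these widths,
and is documented as such. Peak-gain normalisation is the default; a
`"sum"` option jointly rescales the bank so the summed gain plateaus near
one, for users who need the band sum to approximately reconstruct signal
power. The first band (6.90 Hz) is always excluded from the total
intensity to suppress motion artifact. Condition-wise intensities are
normalised by the single maximum across all conditions.

## Displacement spectra

Transverse displacement is `d_j(t) = −(y_j(t) − y_j,standing) · mm_per_px`:
row index grows with depth, so positive displacement is toward the skin.
The quiet-standing reference is subtracted exactly once.

Before the FFT, each landmark series is high-passed (zero-phase 4th-order
Butterworth) at the condition's stride frequency — the seven per-condition
cutoffs 1.3, 1.8, 2.4, 2.6, 2.7, 2.9, 3.1 Hz are accepted directly as
configuration — to remove gross gait motion. Spectra are computed on the
native ~80 Hz stance segments with no taper (a window would change the
peak-power units; one can be added by the caller before
`power_spectrum()` if leakage control matters more than units), one-sided
normalisation `P(f) = 2 |X(f)|² / N²` so a unit sinusoid yields ≈ 0.5 mm²,
truncated to 0–40 Hz. The 100-point stance resampling exists for trace
reporting only and is never a spectral input, because spectra need a
physical time base.

CF50 is found by trapezoidal cumulative integration with linear
interpolation inside the crossing bin; an all-zero series reports CF50 = 0
with an explicit flag. Per-stance metrics are computed first and then
averaged across stances (the alternative — averaging spectra before
extracting metrics — is a caller-level choice).

Regions: 1-based landmarks 2–6 (distal), 8–12 (mid), 14–18 (proximal);
indices are 0-based internally and converted at the boundary. The region
metric is the mean over its five landmarks (median is a trivial caller
substitution).

## Statistics

One-way repeated-measures ANOVA uses the classical within-subject
partition (`F = MS_cond / MS_err`, df `(k−1, (k−1)(n−1))`); the two-way
design tests each main effect against its own subject-by-factor
interaction term, the standard univariate convention, with the
interaction reported. No sphericity correction is applied, matching plain
repeated-measures reporting practice; users who need Greenhouse–Geisser
can apply it downstream. Zero-variance designs return `F = 0, p = 1`
rather than NaN; missing cells are an error (no imputation). Post-hoc
tests are all pairwise paired t-tests with `p_adj = min(1, m·p)`; a
zero-variance difference vector reports `p = 1` when its mean is also
zero and is flagged degenerate otherwise. Trend fits are ordinary
least-squares polynomials with `r² = 1 − SS_res/SS_tot`.

## The synthetic study

`run_synthetic_study()` mirrors the experimental design — N participants
(default 3) x 7 locomotion conditions (3 walking, 4 running speeds) x 4
stance phases — on synthetic data, with walking and running analysed as
one 7-level condition factor. Per participant an ASM is trained on
ground-truth labels (every 10th frame of an 80-frame training sequence
generated at the widest-motion condition, so the PDM spans all
conditions), a quiet-standing reference is segmented from a static scene,
and every stance is a fresh speckle realisation starting at a seeded
random gait phase. All seeds derive from one base seed; identical
configurations produce identical reports.

The condition table injects strictly increasing impact frequencies
(8–20 Hz) and oscillation frequencies (5–20 Hz), so monotonicity of the
recovered input frequency and cumulative frequency across conditions is a
known ground truth. Two amplitude choices matter and are deliberate:

* **Oscillation amplitudes follow a velocity cap** (~60 mm/s: amplitude
  proportional to 1/frequency, capped at 2 mm). Real displacement spectra
  fall off with frequency, and at 80 frames/s a high-frequency component
  of constant amplitude would move landmarks many pixels per frame —
  beyond both physiological plausibility and any tracker's inter-frame
  search basin.
* **The gait component is 1 mm at the stride frequency.** The high-pass
  sits exactly at that frequency and removes only part of it (a zero-phase
  4th-order Butterworth attenuates its own cutoff to one half), so the
  oscillation power must dominate the residual for the spectral metrics
  to reflect the injected content; 1 mm of within-stance gross motion is
  within the range seen in vivo.

Study images are 608 x 288 px (the full width is required by the landmark
columns; depth is cropped to the band of interest) and stance durations
are 0.75–0.65 s for walking and 0.40–0.35 s for running, i.e. 60 down to
28 frames per stance at 80 Hz. These sizes keep a full 3-participant
study to a few minutes while every stance still satisfies the minimum
length of the zero-phase high-pass (27 samples for order 4).

## Known limitations

* Only transverse (depth-direction) motion is modelled and measured;
  proximo-distal displacement and travelling-wave behaviour along the
  muscle are out of scope.
* The segmentation benchmark is noiseless in the sense that boundary
  geometry is exact; reported sub-0.1 px errors on synthetic scenes say
  nothing about manual-labelling disagreement on real images, where ~1 mm
  is the realistic validation bound.
* Short running stances (≈ 28 frames) give coarse FFT grids (≈ 2.9 Hz
  bins); cumulative frequencies from such windows carry that resolution
  limit, as they do in vivo.
* The EMG intensity is an analytic-signal approximation of the original
  wavelet intensity definition; band-resolved timing differences below a
  few milliseconds should not be over-interpreted.
* `rm_anova_two_way()` assumes a complete crossed within-subject design;
  unbalanced or missing data need a mixed-model approach outside this
  package.
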