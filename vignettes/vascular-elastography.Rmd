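---
title: "Non-invasive vascular elastography with imbiomark: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive vascular elastography with imbiomark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbiomark)
```

## The measurement problem

Arterial stiffness is a strong independent correlate of cardiovascular risk,
but direct mechanical testing requires excised tissue. Ultrasound speckle —
the stable interference pattern of sub-resolution scatterers — acts as a
material marker: if a small region of the arterial wall deforms between two
frames acquired milliseconds apart, the deformation of its speckle pattern
estimates the deformation of the tissue itself. Over a cardiac cycle the
pressure pulse cyclically strains the wall; a stiff wall strains less at a
given pulse. The per-frame-pair *axial strain* (along the beam) is therefore
a relative, pressure-conditional stiffness readout that can be followed
non-invasively over an animal's whole lifetime or applied to pediatric
echocardiography loops.

`imbiomark` implements the full chain: a synthetic pulsating-vessel phantom
with analytic ground truth, sequence containers, rigid pre-registration for
bulk cardiac motion, the windowed affine speckle-tracking estimator, strain
elastogram assembly, cyclic biomarker extraction (PSS/PDS, MSS/MDS), the
pooling schemes, and the one-way group statistics with a Monte-Carlo Dunnett
procedure for locating a stiffness turning point along age.

## The motion model

Each frame is partitioned into measurement windows (MWs). Between
consecutive frames t and t + dt the tissue under one window is assumed to
move affinely: a translation $(T_1, T_2)$ (lateral, axial) plus a 2x2
deformation matrix

$$\Delta = \begin{pmatrix}\Delta_{xx} & \Delta_{xy}\\ \Delta_{yx} & \Delta_{yy}\end{pmatrix},$$

where $\Delta_{xx}$ is the lateral strain, $\Delta_{yy}$ the axial strain
and the off-diagonal entries the shears. The parameters minimise the sum of
squared differences between the window at t and the affinely warped window
at t + dt. Two stages mirror standard practice:

1. `estimate_translation()` — integer lag by normalized cross-correlation
   over a search range, refined to sub-sample precision by a parabolic fit
   of the correlation peak in each axis. A peak on the search boundary is
   flagged non-converged.
2. `estimate_deformation()` — damped Gauss-Newton iterative least squares
   over all six parameters, initialised at the correlation translation and
   $\Delta = 0$, warping by bicubic (Catmull-Rom) interpolation with its
   analytic gradient. Iteration stops when the parameter update falls below
   `tol` (default 1e-6) or after `max_iter` (50) iterations; entries of
   $\Delta$ are clamped at ±0.2 so decorrelated speckle cannot drive the
   optimizer to absurd deformations.

Only the axial strain $\Delta_{yy}$ is reported downstream: axial sampling
(at 500 MHz for a 40 MHz probe, one RF sample every
$c/2f_s \approx 1.54\ \mu m$) is 1-2 orders of magnitude finer than the
lateral line pitch, so the axial component is by far the best conditioned.

Numerical choices worth knowing:

* **Interpolation.** Catmull-Rom bicubic (a = -0.5). Sub-percent strains
  move samples by hundredths of a sample across a window; bilinear warping
  flattens the SSD bowl and biases strain low. The warped coordinates may
  leave the supplied patch; those samples are dropped, and an estimate is
  only attempted when at least half the window remains.
* **Joint refinement.** The Gauss-Newton stage re-estimates the
  translations together with $\Delta$ rather than freezing them; the
  correlation translation is only the starting point.
* **Determinism.** No stochastic step anywhere in the estimator; identical
  inputs give identical estimates.

The test suite checks the optimizer against a brute-force SSD grid search
(independent pure-R bicubic, 1e-4 strain grid): on speckle windows with pure
axial strain the two agree within one grid step.

## Windows, elastograms and conventions

Window geometry follows high-frequency small-vessel practice: 108 µm axial
× 312 µm lateral with 90% overlap in both axes. Physical sizes are converted
through the acquisition geometry (axial spacing $c/2f_s$, lateral line
pitch), giving 70 × 10 samples at the default rat configuration. The window
grid has `floor((extent - window)/step) + 1` positions per axis with
`step = max(1, round((1 - overlap) * window))`. Which of the two quoted
dimensions is axial is genuinely ambiguous in the field's shorthand; the
package takes 108 µm axial (so several windows fit through a ~150 µm wall)
and both numbers are configurable in `track_sequence()`.

An elastogram is the $\Delta_{yy}$ field on the window grid for one frame
pair. Conventions:

* **Sign.** Reported strain is compression-positive: systole compresses the
  wall (positive values), diastole dilates it (negative). The raw
  engineering strain is the negation; the convention is recorded in the
  object's `sign` attribute.
* **Segmentation.** Wall masks are inputs (from the phantom's ground truth
  or a mask file), not computed; a window belongs to a wall if its centre
  sample carries that label. High-frequency RF attenuates with depth, so
  the rat pipeline keeps the near wall only; the human ascending-aorta
  pipeline uses near and far walls.
* **Median filter.** The 5 × 5 post-filter operates on elastogram cells
  (window-grid pixels), not RF samples — it is the elastogram that is
  filtered. Missing cells stay missing and medians are taken over the
  available neighbours.
* **Display.** Blue for positive (compression), yellow for negative
  (dilation), missing cells transparent over the B-mode background.

## From elastograms to biomarkers

`mas_curve()` averages a fixed region of interest — 5 × 9 cells
(axial × lateral) for rat carotid RF, 3 × 9 for human ascending aorta — over
every frame pair, giving the mean axial strain (MAS) time series in percent.
Without explicit placement the ROI centres on the grid cell with the largest
time-averaged strain magnitude, i.e. the most strongly pulsating part of the
wall band; placement is configurable because that automatic rule is a
package choice, not an estimate of anyone's manual ROI.

`detect_cycles()` estimates the cardiac period from the autocorrelation of
the MAS curve (parabolically refined, then re-estimated from the located
peak spacing), anchors systolic peaks at the global maximum and finds one
extremum per expected cycle; an ECG channel, when available, replaces all of
this with R-peak gating. Two guards matter at the sequence edges: an
amplitude threshold (a quarter of the anchor's elevation above the curve
median) rejects flank samples picked in truncated edge cycles, and
non-maximum suppression at half-period separation prevents double counting.

`summarize_stiffness()` produces either

* **PSS / PDS** (`mode = "peak"`): means of the systolic peak values and
  diastolic trough magnitudes over 3 cardiac cycles — the rodent
  biomarkers; or
* **MSS / MDS** (`mode = "mean"`): per-cycle means of the positive-strain
  and negative-strain samples, averaged over 3 cycles, together with
  `mean_strain = (|MSS| + |MDS|)/2` — the ascending-aorta biomarkers. The
  absolute-value combination is deliberate: MAS curves sometimes ride on an
  offset between the systolic and diastolic halves, and no detrending is
  applied.

Which 3 of the ~7 recorded cycles enter the average is not dictated by any
convention; the package takes the 3 most central detected cycles, since the
first and last cycles are the ones most often truncated by the recording
window. This is configurable (`n_cycles`).

`pool_measurements()` implements the two virtual-population schemes: per
animal, left/right side × systole/diastole (multiplier 4); per human
subject, triplicate recording × near/far wall (multiplier 6). The
multiplier is always exactly the product of the pooled factor level counts.

## Statistics

`group_compare()` wraps the classical one-way toolbox — ANOVA,
Kruskal-Wallis, Tukey HSD — and adds Dunnett many-to-one comparisons against
a designated baseline. The Dunnett critical value is obtained by seeded
Monte-Carlo (default 100 000 draws of the null max-|t| statistic with the
correct shared-baseline, shared-variance correlation structure) rather than
table lookup, so arbitrary group counts and unbalanced sizes are handled
uniformly; the tests cross-check the adjusted p-values against the
multivariate-t implementation in `multcomp`. `turning_point()` reports the
earliest age whose Dunnett-adjusted comparison with the youngest group is
significant at α = 0.05 — the age at which a stiffness change "mainly takes
place". Only the named procedures are applied; no additional multiplicity
layer is stacked on top.

## The phantom: what it emulates and what it does not

No arterial RF or B-mode recordings ship with the package, so every
downstream claim is validated on `generate_sequence()`: a longitudinal
vessel section — echogenic near/far wall bands around a hypoechoic lumen —
whose walls undergo periodic axial compression.

Acquisition defaults reproduce a high-frequency biomicroscope: 40 MHz
centre frequency, 110% fractional bandwidth at -6 dB, 500 MHz sampling in
8-bit (quantization applied only on export; the internal pipeline is
real-valued), 60 frames/s. Phantom defaults are the study conditions:
150 µm walls (small-rodent carotid scale), 900 µm lumen, heart rate
351 beats/min (anaesthetized-rat scale, giving ~10.3 frames per cycle),
7 cycles per recording, additive white noise at 0.1 of the RF RMS, and a
peak per-frame-pair wall strain of 2%. Values with no reported analogue are
package choices made once: 30 µm lateral pitch and 80 µm lateral beam width
(plausible for a 40 MHz single-element biomicroscope; ~10× coarser values
suit a cardiac probe), scatterer density 5000/mm² (≥10 scatterers per
resolution cell, i.e. fully developed speckle), wall-to-lumen amplitude
ratio 10 (~-20 dB lumen).

The motion model is analytic and exactly exported: both walls carry a
uniform through-thickness compression following a raised cosine over the
cycle, anchored at their outer edges, so the lumen dilates symmetrically
while the outer boundaries stay fixed and lumen scatterers are at rest.
`peak_axial_strain` parameterises the *per-frame-pair* strain peak — the
quantity the tracker estimates — and the cumulative raised-cosine amplitude
is solved numerically so the discrete frame-to-frame series attains that
peak exactly. Ground truth (per-pair strain, cardiac phase, wall label
masks per frame) comes from the same closed-form displacement field; the
tests verify it against finite differences of the scatterer motion at 1e-6.

RF rendering is linear superposition of a separable PSF (Gaussian-windowed
cosine axially, Gaussian laterally, truncated at 4σ) — deliberately *not* a
wave-propagation simulation. Consequences to keep in mind when reading the
validation results:

* the PSF does not deform with the tissue, exactly as in real speckle
  tracking, so strain-induced decorrelation is present;
* there is no diffraction, no reverberation, no phase aberration and only
  optional depth attenuation, so real data will decorrelate more;
* wall motion is purely axial and uniform through the thickness — no
  longitudinal wall motion, no through-plane motion, no strain gradient;
* bulk motion for the registration tests is injected rigidly, whereas real
  ascending-aorta motion is only approximately rigid.

Passing the phantom therefore demonstrates the estimator, bookkeeping,
biomarker extraction and statistics are correct under the stated physics;
it does not certify in vivo accuracy.

## Registration of ascending-aorta sequences

The ascending aorta rides on the heart: before strain tracking the B-mode
sequence is stabilized by rigid registration (2 translations + 1 rotation
about the image centre) of every frame to a fixed reference — the first
frame by default; whether one should register to a fixed frame or
cumulatively frame-to-frame is an open choice, and fixed-reference was
picked for determinism and testability. The search is exhaustive NCC on a
coarse grid (1 sample, 0.5°), followed by a local fine rotation sweep and
parabolic refinement; correlation is computed on an interior crop because
border fill rotates with the candidate angle and biases the peak. Samples
leaving the field of view become `NA` and any measurement window touching
them is dropped. The rat RF pipeline skips registration entirely. Known
limitations: no deformable component, no ECG-based frame rejection, and
recovery is only guaranteed within the configured search radii (default
10% of the image extent, ±5°).

## Problem sizes used in the validation suite

The shipped tests validate at the study scale where it matters and at
reduced scale elsewhere: the end-to-end phantom runs the full 72-frame,
909 × 64-sample rat configuration once; estimator-oracle equivalence uses
50 independent 32 × 16-sample speckle windows; the turning-point and
group-discrimination statistics use 200 simulated replicates each; grid,
filter and container invariants use 100 randomized cases each. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Wall segmentation is an input; there is no automatic wall detector.
* Strain is relative stiffness only — no elastic-modulus, β-index or
  distensibility reconstruction, which would need pressure calibration.
* Single-scale tracking: no pyramidal scheme, so translations beyond the
  search radius (fast probe motion) must be removed by registration first.
* The Monte-Carlo Dunnett p-values carry simulation noise of order
  1/√R ≈ 0.003 at the default draw count; increase `R` for p-values near a
  decision boundary.
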