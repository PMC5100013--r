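---
title: "Root growth kinematics and zone-resolved expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root growth kinematics and zone-resolved expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkin)
```

## The kinematic model

A growing root apex is treated as a one-dimensional continuum along its
axis. Positions `x` are measured in mm from the quiescent center (QC), the
slowly dividing cell group at the apex; the velocity profile `v(x)` (mm/h)
is the speed at which material points move away from the QC, and its spatial
derivative is the elemental elongation rate,

    EER(x) = dv/dx   (h^-1),

the local relative growth rate of the tissue. The standard traits follow
from these two profiles:

* **root growth rate** — the maximum of `v(x)`, attained where elongation
  has ceased (mature tissue recedes from the QC at the whole-root rate);
* **EER_max and its abscissa** — the peak strain rate and its position;
* **growth zone (GZ) length** — the distance from the QC to where the EER
  falls below a threshold (3% by default, see below);
* **division zone (DZ) length** — delineated independently, from the drop
  of near-infrared brightness below 70% of its maximum (lower cell wall
  density beyond the meristem);
* **elongation zone (EZ) length** — `GZ - DZ`, exactly;
* **cell production rate** — `v(DZ end) / (mean meristem cell length)`
  (cells/h). Under steady growth with no division beyond the DZ, the cell
  flux `v(x)/l(x)` is conserved for `x > DZ`, so this ratio measures the
  rate at which the meristem delivers cells to the elongation zone.

`root_kinematics()` is the package's central estimator: it takes a raw
velocity profile (usually from PIV), fits a cubic smoothing spline
(`stats::smooth.spline`, `spar = 0.5` by default), differentiates the
fitted spline analytically (`predict(..., deriv = 1)`), delineates the DZ
from a brightness profile, and extracts all traits. It returns a classed
fit with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, and
`plot` methods.

## Velocimetry

Displacements between consecutive frames are estimated by windowed
normalized cross-correlation (PIV): for interrogation windows spaced along
the axis (defaults: 32 px windows, 8 px step, +/-12 px search), the integer
lag maximizing the normalized correlation is refined to subpixel precision
by a three-point parabolic fit. A parabolic fit is simpler than a Gaussian
peak model and adequate for the < 0.2 px accuracy this pipeline needs, as
the shift-recovery tests verify. Windows with correlation peaks below 0.5,
near-zero variance, or insufficient margin for the search are flagged, not
dropped. Only the axial displacement component is estimated; transverse
motion is treated as noise, since every downstream quantity is axial.

Two practical details matter for accuracy:

* **Flat-fielding.** The longitudinal brightness envelope (the DZ-to-EZ
  intensity drop) would bias each window's match towards its brighter side;
  frames are therefore divided by a running-mean column profile (16 px
  window) before correlation.
* **Coordinate frame.** The QC is placed at a fixed offset (0.5 mm, the
  root cap) behind the tracked tip — the tip is found per frame as the
  distal intensity edge, and its velocity by a Theil-Sen fit of position on
  time. Tip motion is subtracted from all window velocities, so the profile
  is the material velocity in the QC frame regardless of whether the camera
  tracked the apex or stayed fixed. Estimates from all frame pairs are
  pooled by the median within 0.1 mm position bins.

## Numerical choices

* **Smoothing spline.** `spar = 0.5` is the default roughness level.
  Knots are budgeted by physical extent — one per 0.2 mm of profile span,
  at most 45 — which keeps the spline derivative estimable from noisy
  profiles while resolving the EER's approach to zero at the GZ end.
  Smoothing is idempotent by construction: re-smoothing a profile that
  already carries a fit from the same configuration is a no-op, because a
  penalized re-fit on the denser resampled grid would otherwise apply
  additional shrinkage.
* **GZ threshold rule.** A "3%" rule is ambiguous between 3% of EER_max
  and an absolute 0.03 h^-1; both are implemented
  (`gz_rule = "relative"` / `"absolute"`), with the relative rule as the
  default because it leaves GZ length invariant under uniform rescaling of
  the growth field. The crossing is located by linear interpolation, taking
  the first down-crossing after the EER peak that stays below the threshold
  for at least 0.2 mm (noisy tails can recross); if no crossing persists,
  the first down-crossing is used, and a profile whose EER never falls
  below the threshold is an error, not a guess.
* **EER peak.** The maximum and its abscissa are refined by a parabolic
  fit through the peak grid point and its neighbours.
* **Brightness delineation.** Profiles are smoothed by a 0.2 mm moving
  average before thresholding so single-sample dips cannot trigger the 70%
  rule; the crossing is linearly interpolated. The rule is invariant to
  global brightness rescaling. When the profile is extracted from images,
  each column is summarized by the median over the rows the root occupies:
  the sparse particle texture thins out as tissue stretches through the EZ,
  which would bias a mean-based profile apically, and sub-median quantiles
  would inherit a constant offset from symmetric sensor noise.
* **Meristem cell length** is averaged over the whole DZ (cell length is
  treated as constant there); a sub-range is configurable.

## The synthetic-data generators

Every stage is validated against phantoms with known ground truth.

* **Growth field.** A unimodal, non-negative EER field on `[0, GZ]`,
  parameterized by peak rate, peak position, GZ and DZ lengths. Three
  shapes: a C^1 beta-kernel (default; realistic smooth profile), a
  triangular field (closed-form integrals anchor exact tests: peak 0.3 h^-1
  at 3 mm on a 6 mm base gives growth rate 0.9 mm/h, GZ 5.91 mm under the
  relative rule, 5.70 mm under the absolute rule), and a clipped Gaussian.
  Velocity is the exact integral of the field (piecewise quadratic, error
  function, and regularized incomplete beta respectively).
* **Step stress.** An abrupt collapse of the whole field at onset, a damped
  oscillation passing through a maximum near 45 min, and a new steady state
  (default 50% of control, reached at 2 h, exactly thereafter). The
  transient's magnitude and functional form are illustrative choices — only
  the two-phase structure and the new steady state are constrained by the
  phenomenon being emulated.
* **Image phantoms.** Gaussian-blob particle texture advected by the exact
  material trajectories (`deSolve`), modulated by a plateau-plus-logistic
  brightness envelope whose 70% crossing sits exactly at the DZ end, plus
  additive Gaussian sensor noise. Default geometry: 512 x 256 px at
  20 um/px, 20 frames at 0.1 h (one frame every 6 min), ~40 particles/mm^2.
  Both a tip-tracking camera (QC fixed in frame; the default) and a fixed
  camera (tip advances) are supported. Per-particle ground-truth
  displacements are recorded for velocimetry validation.
* **Cell length profiles** follow flux conservation exactly (meristem
  length inside the DZ, `v(x)/F` beyond), with multiplicative log-normal
  noise.
* **Expression tables.** Log-normal FPKM baselines over the full
  2 zone x 2 treatment x 2 time design with 4 replicates (32 columns),
  log-normal replicate noise (sd 0.5 on the log2 scale by default), and
  disjoint planted gene sets: zone-preferred effects applied to all columns
  of the preferred zone, stress effects to the PEG columns of one zone at
  the times implied by the timing class (early-only / sustained / late).

What the phantoms do **not** emulate: root bending and transverse motion,
photorealistic optics, focus loss at stress onset, cell-file structure in
images, count-level sequencing noise (overdispersion), library-size
artefacts, or correlated genes. Passing the recovery tests therefore shows
that the estimators are correct and well calibrated under the stated noise
models — not that they are robust to every artefact of real rigs and
libraries.

## Differential-expression classification

The inputs are FPKM tables, not reads, so the engine is deliberately
simple and transparent: for each of the eight canonical comparisons (EZ vs
DZ within each treatment x time; PEG vs CTL within each zone x time),

* `log2fc = log2((mean FPKM_num + 1) / (mean FPKM_den + 1))` (pseudocount
  configurable),
* a two-sided Welch t-test on per-replicate `log2(FPKM + 1)` values, with a
  variance floor of 1e-6 on the log2 scale (two identical constant sides
  give p = 1),
* Benjamini-Hochberg q-values within the comparison, over expressed genes
  only (a gene is expressed when its mean FPKM reaches 1 in at least one
  sampling unit; others are `NOTEST` everywhere),
* DEG status requires all three gates: p < 0.05, q < 0.05, and
  `|log2fc| >= 2`.

This stand-in is not a count-based negative-binomial model and should not
be treated as one; it is calibrated on simulated tables (null
false-discovery fraction below 1%, planted-effect recall above 80% at
|log2fc| = 3 with four replicates). "Consistently under the four
conditions" is operationalized as significant with the same sign in all
four zone comparisons; the 4-fold core sets coincide with that definition
at the default threshold and are reported alongside. Multiple testing is
corrected within each comparison, over all expressed genes, not across
comparisons. Classification summaries enforce their partition invariants
(DZ-preferred + EZ-preferred equals the all-four set; core sets within
preferred sets; all-four within at-least-one) and raise an error on
violation rather than reporting silently.

## Cohort statistics

Traits measured on the same roots before stress and at 0.5 h and 3 h are
compared with a one-way repeated-measures ANOVA (time as the within-subject
factor; no sphericity correction, which cannot be estimated reliably at
n = 7) followed by two-sided paired t-tests against the pre-stress state,
starred at the conventional levels with no multiplicity correction.
Degenerate inputs are flagged explicitly: identical values give F = 0,
p = 1; zero within-pair variance gives p = NA (or an infinite t when the
differences are constant and non-zero).

## Problem sizes

The test-suite and the acceptance script use: 20 random growth fields x 3
noise seeds of 512 x 256 px, 20-frame phantoms for end-to-end recovery;
5000-gene tables for null calibration and 2000-gene tables for recall; 50
seeds for brightness-delineation precision; 200 simulated panels for the
ANOVA power check. These sizes make every property estimable with
comfortable margins while keeping a full run in minutes.

## Known limitations

* PIV assumes a straight, axially aligned root; curved midlines are out of
  scope.
* The tip tracker needs a clear intensity edge; occlusion or focus loss is
  not handled (low-correlation frame pairs are flagged, but no biological
  exclusion rule is applied).
* The DE engine ignores gene length and library size beyond what FPKM
  normalization already absorbed, and models no mean-variance trend.
* Trait uncertainty is not propagated into the cohort tests; each root's
  traits enter as point estimates.
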