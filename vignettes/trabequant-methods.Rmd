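---
title: "trabequant: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trabequant: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabequant)
```

## The problem

Inflammatory arthritis is accompanied by trabecular bone loss that standard
densitometry summarizes into a single areal density. High-resolution
gradient-echo (GRE) MRI of the knee (in-plane 0.234 mm, 1.5 mm slices)
resolves the trabecular network well enough to quantify its architecture
*in vivo*: bone volume fraction (BVF), trabecular thickness (Tb.Th), spacing
(Tb.Sp) and number (Tb.N = BVF/Tb.Th). FNa-PET of the same joint localizes
hypermetabolic (actively remodelling) regions via standardized uptake values
(SUV). trabequant implements the full analysis chain — BVF mapping,
bone segmentation, ROI construction, aperture-map morphometry, SUV
quantification, per-bone PET-to-MR fusion, and the before/after-treatment
group comparison — together with a synthetic-data module that makes every
stage testable against known ground truth.

## BVF mapping

On GRE images trabecular bone is dark and marrow bright, and a voxel's
intensity is, to good approximation, a linear mixture of the two pure-phase
signals weighted by the bone fraction it contains. The BVF map inverts this
mixture,

$$\mathrm{BVF}(x) = \mathrm{clamp}\!\left(
  \frac{I_{marrow}-I(x)}{I_{marrow}-I_{bone}},\,0,\,1\right),$$

and is stored in $[0,1]$ (an 8-bit 0–255 scaling is treated as a display
encoding). The pure-phase anchors are not observable directly in vivo;
`estimate_references()` defaults to the 1st/99th intensity percentiles
inside the bone mask, which is robust to outliers and, on simulated
acquisitions, lands within 10 % of the configured pure-phase intensities.
Scaling is per bone mask; whether a global or per-bone scaling is more
faithful to the original protocol is unknowable from the published record,
and per-bone is the safer choice under coil-sensitivity shading.

## Segmentation

Bone is delineated with the two-phase piecewise-constant Mumford–Shah
(Chan–Vese) model
$$E = \mu\,|\partial\Omega| + \lambda_1\!\sum_{in}(I-c_1)^2
      + \lambda_2\!\sum_{out}(I-c_2)^2 .$$
Rather than a level-set PDE, `chan_vese_segment()` minimizes the discrete
energy directly: exact region-mean updates of $c_1, c_2$ alternate with
checkerboard-parallel label flips, each flip accepted only if it strictly
lowers the energy. Voxels of one parity share no 6-neighbour edges, so
parallel flips cannot interact and the energy trace is non-increasing *by
construction* — a property a gradient-descent level set does not guarantee,
and one the test suite asserts on arbitrary inputs (including agreement with
the exhaustively enumerated global optimum on tiny grids). Defaults
($\mu = 0.25$ on normalized intensities, $\lambda_1=\lambda_2=1$, tolerance
$10^{-3}$, 200 sweeps, checkerboard init) are standard; the original
protocol reports none.

Filled contours become solid masks (`fill_and_close()`, per-slice hole
filling). The cortical shell is then removed by `strip_cortical()`:
**inward peeling** (erosion by the discrete disk) of 10 in-plane pixels =
2.34 mm. The original description calls this a "closing process", but
morphological closing cannot remove a shell; peeling is the only operation
consistent with the stated goal and the stated 2.34 mm. Peeling is 2D
per slice — at 1.5 mm slice thickness a 10-voxel through-plane erosion
would destroy every ROI.

The 8-label ROI scheme covers patella (ROI1 whole; 1a/1b/1c = upper, lower
and central thirds along the mask's first principal axis, sign resolved
toward +z), distal femur (ROI2) and proximal tibia (ROI3, with ROI3a an
attachment-site band — default 15 mm, config-driven — and ROI3b the
opposite band). The anatomical definitions of ROI3a/3b (ligament
attachment; absence of hypermetabolism) have no unique geometric
translation, so the bands are explicit configuration rather than hidden
heuristics.

## Morphometry

Following the 3-plane in-vivo protocol, morphometry is 2D: the slice with
the largest ROI area (ties toward the lowest index) and its two neighbours
are analysed as three replicates. Each BVF slice is binarized by a local
mean threshold (window 4.7 mm ≈ 20 px — wide enough to contain at least one
thickness + spacing period, so the local statistic mixes both phases;
offset 0; strict `>` so exact ties resolve to marrow). The thresholding
algorithm and window of the original work are uncited details; these
defaults are package decisions.

### Aperture maps

Tb.Th and Tb.Sp are mean *aperture-map* values: for every pixel, the
diameter of the largest disk fully inscribed in its phase that covers it
(bone phase for Tb.Th; marrow∩ROI for Tb.Sp, so disks are clipped to the
ROI and edges do not inflate spacing). The discrete disk family is defined
for **every** integer diameter $d$: pixel $q$ belongs to the disk centred
at $c$ iff $|q-c| \le d/2$, with odd-$d$ disks centred on the pixel grid
and even-$d$ disks on the half grid (centres of 2×2 pixel blocks). The
even diameters matter: a strip of width $w$ pixels then admits a
diameter-$w$ disk for every $w$, whereas an odd-only convention collapses a
2-pixel strip (≈ 0.47 mm at this resolution — a typical trabecular spacing)
to diameter 1. Closed forms under this convention, frozen in the tests:
a width-$w$ strip has aperture $w$ everywhere in its interior; a rasterized
disk of radius $R$ has maximal aperture $2R-1$.

The fast implementation derives each candidate centre's maximal diameter
from exact squared Euclidean distance transforms (on the pixel grid and the
half grid) and propagates disks in decreasing diameter order. An
independent brute-force oracle (`aperture_map_naive()`) checks every
centre/diameter by explicit membership; the two are asserted bit-identical
on randomized slices.

Tb.N is BVF/Tb.Th by definition. Reported replicate means define the mean
Tb.N as (mean BVF)/(mean Tb.Th), so the identity holds per replicate *and*
on means. Notably, the published reference table does **not** satisfy this
identity (12 of 24 cells deviate beyond printed rounding, worst by 0.106),
which is consistent with its Tb.N being a mean of per-replicate ratios; the
corresponding acceptance check on the published numbers therefore fails by
design and is documented rather than hidden.

## SUV and PET–MR fusion

SUV uses the body-weight convention with unit tissue density:
$\mathrm{SUV} = C\,[\mathrm{kBq/mL}] \cdot \mathrm{weight\,[g]} /
\mathrm{dose\,[kBq]}$, so a uniformly distributed dose gives SUV ≡ 1. A
region is hypermetabolic when its SUV**mean** is ≥ 2.5 (inclusive); the
mean, rather than the max, is what the reference narrative uses to call
regions abnormal. Decay correction is out of scope.

Fusion estimates one affine per bone (centroid + principal-axes + scale
moment matching, with a similarity fallback for degenerate masks) and
merges them log-Euclideanly: the stationary velocity field
$v(x) = \sum_i w_i(x) (\log M_i)\tilde x$ uses weights obtained by
smoothing each bone indicator with a Gaussian of σ = 5 mm and normalizing
voxel-wise; the field is exponentiated by scaling-and-squaring of the
displacement field. The depth is adaptive twice over: enough steps that the
half-step displacement is below half a voxel (stability) *and* that the
first-order initialization error — bounded via a finite-difference estimate
of the velocity Jacobian — stays below $10^{-3}$ voxel (accuracy). Border
samples during self-composition are linearly extrapolated, which is exact
for affine velocity fields. Where all raw weights vanish the map is the
identity; with one component of weight 1 the field reproduces the affine to
$<10^{-3}$ mm; with constant weights it equals the matrix exponential of
the weighted log mean (the two-rotation mean test). PET is resampled onto
the MR grid (pull-back, linear for intensities, nearest for masks),
preserving the high-resolution anatomy as the reference frame.

## Statistics and reporting

Percent differences are $(p-c)/c \times 100$ at full precision, rounded to
integers only in narrative output. Regional summaries are mean ± sample SD
(n−1) of per-ROI percent differences. The t-test is the pooled (classical
Student) variant by default, computable from raw samples or from
(mean, SD, n) summaries, two-sided, with significance at α = 0.01 and no
multiple-testing correction (matching the reference analysis; the report
footnotes the test count). Because a single patient yields n = 1 at the
subject level, two conventions are implemented and reported: replicate-level
(all control replicates vs the patient's 3 replicates, the default) and
subject-level (7 subject means vs 3 replicates). Neither reproduces every
published significance marker — the effective n of the original tests is
not recoverable — so the census of the published table uses its transcribed
markers (24 significant before, 9 after). The count of cells significant
before and no longer after is 18 by those markers; the published abstract
says 15 of 24 "normalized", an internal inconsistency we surface rather
than resolve.

## The synthetic world

The generator states one fixed world; none of its parameters are tuned to
test outcomes.

* **Microstructure**: plate lattices with thickness 0.25 mm and spacing
  0.45 mm (BVF 0.357, Tb.N 1.429 mm⁻¹ in closed form) match the reference
  control values (Tb.Th ≈ 0.26 mm, Tb.Sp ≈ 0.43–0.56 mm, BVF ≈ 0.34–0.39).
  Rod lattices and thresholded Gaussian random fields (correlation length =
  thickness, quantile-thresholded to the target fraction) provide
  non-plate geometries; the Gaussian field's thickness truth is
  self-declared via the brute-force oracle.
* **Acquisition**: phantoms are generated at ~30 µm and degraded by *exact
  box averaging* to 0.234 × 0.234 × 1.5 mm — partial volume is modelled,
  not ignored, because the voxel is larger than a trabecula and that bias
  is the dominant measurement effect. Acceptance phantoms use an in-plane
  extent of 9.8 mm = 14 lattice periods so the analytic volume fraction is
  commensurate with the grid. Pure-phase intensities 20 (bone) and 200
  (marrow) on an arbitrary scanner scale; Rician noise (magnitude MR) at
  SNR 25 relative to marrow, a typical high-field GRE figure; Gaussian
  noise available for analytic checks. No T1/T2* or flip-angle modelling.
* **PET**: uniform background SUV with Gaussian foci (σ = radius/3) whose
  peaks sit in the published SUVmax range; activity is constructed so that
  `compute_suv()` inverts it exactly for the stated dose (3 MBq/kg
  convention) and weight.
* **Cohort**: 7 controls and one before/after patient, 3 replicates per
  subject per cell, drawn i.i.d. around the published control means with
  the published SDs (log-normal with exact-mean parameterization by
  default, since all metrics are positive; normal available for
  calibration checks). There is deliberately *no* subject-level random
  effect: the replicate scatter is not published separately, and the i.i.d.
  model is the one under which the replicate-level pooled t-test is exactly
  calibrated — which the type-I acceptance check then verifies. Patient
  cells are scaled multiplicatively (distribution and SD scale together).
  The four metrics are drawn independently; Tb.N = BVF/Tb.Th is enforced
  for image-derived metrics but not for cohort draws, both because the
  published table itself violates it and because cell-independent effects
  are needed for exact significance-census constructions.

### What a green test does and does not establish

The phantoms verify the *measurement chain*: that the pipeline recovers
known microstructure through realistic partial volume and noise, that the
aperture primitive is exact, that fusion reproduces closed-form transforms,
and that the statistics are calibrated. They do not establish in-vivo
validity: no marrow heterogeneity, susceptibility effects, motion, coil
shading, registration error against CT, or anatomical shape variability is
simulated, and the lattice geometry is far more regular than trabecular
bone. Recovery tolerances (Tb.Th 25 %, Tb.Sp 15 %, Tb.N 20 % at the
reference geometry) quantify discretization bias at ~1–2 pixel feature
sizes, not biological accuracy.

## Numerical details worth knowing

* NIfTI-1 I/O is implemented in-package (no R NIfTI package is available in
  the target environment): float64 payloads round-trip bit-for-bit, masks
  are uint8, geometry lives in an axis-aligned RAS sform; the writer is
  validated against Python's nibabel in the test suite.
* Distance transforms are exact squared-Euclidean (Felzenszwalb–Huttenlocher
  lower envelopes), with everything outside the image treated as
  background; the half-grid variant evaluates the same envelopes at offset
  query points.
* Matrix logs/exps of 4×4 affines use inverse scaling-and-squaring with
  Denman–Beavers square roots, and Taylor/squaring respectively; positive
  determinant of the linear part is enforced at construction so the
  principal log exists.
* All randomness flows through explicit seeds (`with_seed()` scopes the
  RNG and restores the caller's state); identical spec + seed gives
  bit-identical phantoms, acquisitions and cohorts.
* Degenerate inputs are first-class: constant images, empty phases and
  empty ROIs raise typed conditions; unusable replicate slices are flagged
  and at least two are required.

## Known limitations

2D morphometry inherits the anisotropic-voxel protocol instead of 3D local
thickness; the Chan–Vese ICM optimizer can in principle stop in a local
minimum on heavily textured images (multiple inits are available); the
moment-matching registration assumes non-degenerate, roughly corresponding
bone shapes and modest rotations; and the reported SUV model omits decay
and partial-volume corrections.
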