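# trabequant

In-vivo trabecular bone microarchitecture quantification from gradient-echo
MRI, with FNa-PET SUV analysis and per-bone PET-to-MR fusion.

## What it does, and for whom

High-resolution GRE MRI of the knee (0.234 × 0.234 mm in-plane, 1.5 mm
slices) resolves the trabecular network well enough to measure its
architecture without radiation — relevant to rheumatologists and imaging
scientists following bone loss in inflammatory arthritis, and to anyone
validating MR-based bone morphometry. trabequant implements the full chain:

* **BVF mapping** — voxel intensity is a linear bone/marrow mixture;
  `BVF(x) = clamp((I_marrow − I(x)) / (I_marrow − I_bone), 0, 1)`.
* **Segmentation** — Chan-Vese two-phase piecewise-constant energy
  `E = µ|∂Ω| + λ₁Σ_in(I−c₁)² + λ₂Σ_out(I−c₂)²`, minimized by a
  provably-descending discrete scheme; per-slice hole filling; cortical
  stripping by 10-pixel (2.34 mm) in-plane peeling; the 8-label knee ROI
  scheme (patella ROI1/1a/1b/1c, femur ROI2, tibia ROI3/3a/3b).
* **Morphometry** — three central slices per ROI, local-mean binarization,
  aperture maps (largest-inscribed-disk diameters from exact Euclidean
  distance transforms, verified against a brute-force oracle): BVF, Tb.Th,
  Tb.Sp, and Tb.N = BVF/Tb.Th.
* **PET** — body-weight SUV (`SUV = C·weight/dose`, SUV ≡ 1 for a uniform
  dose), per-ROI SUVmean/SUVmax, hypermetabolic flag at SUVmean ≥ 2.5.
* **Fusion** — per-bone affine registration (moment matching) merged
  log-Euclideanly: `v(x) = Σᵢ wᵢ(x)(log Mᵢ)x̃`, exponentiated by adaptive
  scaling-and-squaring into a dense deformation field.
* **Reporting** — percent differences vs control means, pooled Student's
  t-tests at p < 0.01, regional mean ± SD narratives, significance census.
* **Synthetic data** — plate/rod lattices and Gaussian-field phantoms with
  analytic ground truth, exact box-average partial volume, Rician noise,
  PET foci, and a control/patient cohort generator; every stage is testable
  without patient data.

A transcribed reference dataset (8 knee ROIs × 4 metrics, 7 controls vs a
PsA patient before/after one year of anti-TNFα treatment, plus per-ROI SUV)
ships in `inst/extdata/psa_knee_tables.json` and drives the desk-arithmetic
checks.

## Worked example

Closed loop: lattice phantom with known truth → simulated GRE acquisition →
BVF map → morphometry.

```r
library(trabequant)

spec <- phantom_spec("plate_lattice", thickness = 0.25, spacing = 0.45,
                     extent_mm = c(9.8, 9.8, 7.5),
                     highres_voxel = c(0.0234, 0.0234, 0.03))
lat <- generate_lattice(spec)
str(lat$truth)
#> List of 4
#>  $ bvf  : num 0.357
#>  $ tb_th: num 0.25
#>  $ tb_sp: num 0.45
#>  $ tb_n : num 1.43

mri <- simulate_gre(lat$mask, acquisition_spec(snr = 25, seed = 7))
mri
#> <volume_image> 41x41x5 voxels, spacing 0.234x0.234x1.5 mm, origin 0, 0, 0 mm
#>   range [1.284, 228.1]

bvf <- compute_bvf_map(mri, bone_ref = 20, marrow_ref = 200)
d <- dim(bvf$data)
roi <- array(FALSE, d); roi[4:(d[1]-3), 4:(d[2]-3), 2:4] <- TRUE
roi[4:6, , c(2, 4)] <- FALSE        # taper so the central slice is unique
metrics_for_roi(bvf, binary_mask(roi, mri$spacing), study_config())
#> <morpho_metrics> BVF 0.343  Tb.Th 0.234 mm  Tb.Sp 0.457 mm  Tb.N 1.468 /mm (3 replicates)
```

Tb.Th comes back 0.234 mm (−6 %: a one-pixel trabecula at this resolution),
Tb.Sp 0.457 mm (+2 %) and Tb.N 1.468 mm⁻¹ (+3 %) — discretization bias at
a sub-pixel feature size, inside the package's stated recovery tolerances.

Desk arithmetic on the bundled reference tables:

```r
rows <- comparison_from_tables()
subset(narrative_summaries(rows), region == "patella" & metric == "bvf")
#>    region metric  phase   mean    sd n_rois mean_rounded
#> 1 patella    bvf before -23.44 10.01      4          -23
#> 2 patella    bvf  after  -1.66  4.15      4           -2
```

i.e. the patient's patellar BVF was 23 ± 10 % below controls before
treatment and statistically indistinguishable (−2 ± 4 %) after a year of
therapy.

## Command line

`inst/cli/trabequant.R` exposes `bvf`, `phantom`, `segment`, `morpho`,
`suv` and `report` subcommands over NIfTI-1 volumes (`.nii`/`.nii.gz`; the
reader/writer is built in and validated against nibabel):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","trabequant.R",package="trabequant"))')" \
  phantom --kind plate --t 0.25 --s 0.45 --out-dir phantom/
```

## Package layout

`R/volume.R` + `R/nifti.R` (data model, NIfTI I/O) · `R/bvf.R` + `R/config.R`
(imaging core) · `R/phantom.R` (synthetic data) · `R/segment.R`
(segmentation, ROIs) · `R/morpho.R` (aperture morphometry) · `R/fusion.R`
(SUV, registration, poly-affine) · `R/stats_report.R` (comparison
arithmetic, reports). The methods vignette
(`vignettes/trabequant-methods.Rmd`) documents every model, default and
deviation in detail.
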