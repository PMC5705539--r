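---
title: "Voxel-level 90Y PET dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level 90Y PET dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y90voxdose)
```

## Scope and model

`y90voxdose` is a phantom-validation toolkit for quantitative ⁹⁰Y PET/CT
dosimetry, the imaging problem that arises after hepatic
radioembolization: microspheres are a permanent implant, ⁹⁰Y is a
near-pure β⁻ emitter, and PET imaging rests entirely on the rare
internal pair production of the ⁹⁰Zr 0⁺–0⁺ transition, with a positron
branch ratio of 3.186 × 10⁻⁵. Three consequences shape everything in
the package:

1. **Calibration is a rescaling.** A scanner calibrated with a
   conventional positron emitter quantifies ⁹⁰Y once its calibration
   factor is divided by the branch ratio
   (`calibration_factor_y90()`). Uncertainty in the branch ratio
   (≈ 1.5 %) propagates directly into every activity estimate.
2. **Counting statistics are brutal.** Only ~3 decays in 10⁵ yield a
   positron, so even multi-MBq/mL objects produce a handful of detected
   counts per voxel. Images of uniformly filled volumes look mottled and
   their voxel histograms are positively skewed.
3. **Dose integrates over the full physical decay.** With no biological
   clearance, cumulated activity per voxel is
   `Ã = C · v_voxel · T½/ln 2`.

The dose model is deliberately minimal and matches what clinical
voxel-dose tools do on phantoms: unit density (ρ = 1 g/cm³) everywhere,
no tissue heterogeneity, no wall/interface perturbations, and three
algorithms sharing one contract:

- **Local deposition (LD)**: `D = C × ld_constant(nuclide)`, with
  `ld_constant = (T½/ln 2) · Ē · 1.602×10⁻¹³ J/MeV · 10³ mL/kg`.
  For ⁹⁰Y (T½ = 2.67 d, Ē = 0.932 MeV) this is ≈ 4.97 × 10⁻⁵ Gy·s·mL.
- **Kernel convolution**: `D = S ⊗ Ã` with a voxel S-value kernel
  (Gy per decay). A delta kernel reduces this exactly to LD.
- **MIRD average**: `D̄ = C × ld_constant` for a uniformly filled
  soft-tissue volume with absorbed fraction 1 (volume and mass cancel).

On uniform activity the three coincide (radiation equilibrium); the
test suite asserts this identity to the kernel's declared energy
leakage.

### The 1.44 versus 1/ln 2 choice

The permanent-implant time integral contributes a factor
`1/ln 2 = 1.4427`, often rounded to 1.44 in clinical practice, which
shifts every dose by 0.19 %. Both conventions are in circulation, so
`ld_constant()` (and the functions built on it) defaults to the exact
`1/ln 2` and exposes `rounded = TRUE` to select 1.44, which
reproduces the widely quoted 4.966 × 10⁻⁵-scale constant. The delta
kernel is built from the exact convention, so
`kernel_convolve_dose()` with a delta kernel equals
`local_deposition_dose()` to machine precision, and differs from the
1.44-rounded map by that documented 0.19 %.

### Mean beta energy

Evaluated decay data give a mean β⁻ energy of 933.7 keV; voxel-dose
practice conventionally uses 0.932 MeV in the LD constant. The package
default (`y90_constants()`) is 0.932 MeV; any `nuclide_constants()`
object with the evaluated value can be substituted, changing doses by
0.18 %.

## The phantom simulator

`build_phantom()` rasterizes cylinder/sphere/box compartments painted
in order (later compartments overwrite earlier ones, so nested
structures are declared outside-in). Edge voxels get volume-weighted
concentrations from 3×3×3 sub-voxel sampling; binary masks threshold
occupancy at 0.5, which reproduces nominal compartment volumes within
about 1 % for sphere/cylinder objects of a few mL on the default
2.73 × 2.73 × 3.27 mm grid. Box faces that alias against the grid can
deviate by a few mL more — always within one sub-voxel layer of the
analytic volume.

The three built-in phantoms encode the standard validation conditions:

- `phantom_uniform_cylinder()` — 5640 mL cylinder at 273 kBq/mL
  (calibration validation).
- `phantom_iec_body()` — six spheres of 0.52–26.52 mL at 2.28 MBq/mL
  with an 8:1 sphere-to-background ratio (recovery coefficients).
- `phantom_anthropomorphic()` — 13.7 L torso of cold water containing a
  1200 mL liver, cold lungs (900/1100 mL), a cold 200 mL spine, and a
  19.13 mL cylindrical lesion insert (⌀ 28.5 mm × 30 mm) at a 6:1
  insert-to-liver ratio; defaults are the day-1 condition
  (5.5 / 0.89 MBq/mL).

`simulate_pet()` emulates a *post-reconstruction* image, not the
sinogram chain: expected detected positron counts per voxel
(`C · v_voxel · BR · t · sensitivity`), isotropic Gaussian PSF blur of
the expected-count field, a flat additive spurious-count floor, Poisson
sampling under an explicit seed, and inversion back to Bq/mL. Expected
counts are exactly linear in scan time — decay during a ≤ 30 min ⁹⁰Y
scan is below 0.6 % and is neglected here, while
`emitted_positrons()` uses the full decay-corrected integral
`(1 − e^{−λt})/λ`.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| voxel size | 2.73 × 2.73 × 3.27 | mm | clinical PET reconstruction grid (voxel volume 0.024371 mL) |
| PSF FWHM | 6 | mm | typical reconstructed ⁹⁰Y-PET resolution |
| sensitivity | 0.003 | counts/positron | see below |
| background counts | 0 | counts/voxel | residual scatter/randoms floor, off by default |
| scan time | user-set | s | 900–1800 s are realistic clinical values |

The effective sensitivity is the one genuinely free knob: absolute
detected-count totals for a given scanner are rarely published. The
default 0.003 was fixed once so that the day-1 lesion insert in a
15-min scan lands at roughly 10 detected counts per voxel, which
reproduces the visual mottle and homogeneity-index scale
(HI ≈ 0.3–0.4) reported for real day-1 ⁹⁰Y acquisitions. It is a
single effective constant folding scanner sensitivity and the
count-to-noise amplification of iterative reconstruction; absolute
noise magnitudes from the simulator should be read as
order-of-magnitude, not calibrated.

### What the simulator does *not* model

No OSEM reconstruction (noise is independent Poisson per voxel, whereas
reconstructed noise is spatially correlated and object-dependent), no
attenuation/scatter physics beyond a flat floor, no randoms structure,
no dead time, no PMMA wall effects, no motion. Passing tests therefore
demonstrate the correctness of the quantification and dosimetry
algebra and the counting-statistics behaviour of the chain — they do
not certify performance on real reconstructed images.

## Quantification conventions

Several estimators needed a fixed convention; each is chosen once and
tested:

- **Quantiles**: linear interpolation between order statistics
  (R type 7), so `{1,2,3,4}` gives quartiles 1.75 / 3.25.
- **Skewness**: adjusted Fisher–Pearson coefficient
  `g1·sqrt(n(n−1))/(n−2)`; degenerate inputs report 0.
- **dAVH**: fraction of VOI volume per concentration bin over bin
  width; integrates to 1 to 10⁻⁹ by construction (telescoping of the
  discrete cumulative derivative). Default bin width (max−min)/100.
- **Homogeneity index**: volume-weighted CV; equals sd/mean for equal
  voxel volumes, is scale-invariant, and for Poisson-limited counts
  falls as N^(−1/2).
- **RC interpolation**: linear in log(volume), clamped to the table
  ends outside its range — recovery curves are smooth in log-volume
  and extrapolating them is not defensible from six spheres.
- **RC lookup volume**: an explicit argument (`pve_correct(mean, V,
  table)`); whether a contoured or nominal volume is used is the
  caller's reportable choice.
- **PVE applicability**: spill-out matters for objects smaller than
  about three PSF widths; for larger VOIs (e.g. a liver) correction is
  conventionally skipped — the package leaves that decision to the
  caller rather than silently gating it.

## The dose kernel

No public voxel S-value table ships with the package; kernels are
first-class inputs (`dose_kernel()`, NIfTI + JSON sidecar). Two
generators are included:

- `delta_kernel()` — all energy in the source voxel; the LD limit.
- `beta_point_kernel()` — a *synthetic* analytic kernel: an
  apparent-absorption point kernel `E·ν·e^{−νr}/(4πr²)` with
  `1/ν = 2.5 mm` (the ⁹⁰Y mean beta path in soft tissue), sampled at
  voxel-centre offsets (midpoint quadrature) on a spherical support of
  15 mm; the source voxel takes the residual so energy closure is
  exact at the declared leakage `e^{−6} ≈ 0.25 %`. It is smooth,
  energy-conserving and qualitatively right-ranged, but it is not a
  transport calculation and should not be used for clinical kernels.

Energy closure (`Σ S·m_voxel = Ē_J` up to declared leakage) is enforced
by the `dose_kernel()` constructor itself, so a malformed kernel fails
at load, not at use. Convolution uses FFTs with zero padding
(activity outside the phantom grid is zero by construction); tiny
negative FFT round-off values are clamped.

## The noise study

`hi_noise_study()` simulates a uniform cylinder over ≥ 4 activity
levels spanning ≥ 1.5 decades, computes HI over an interior VOI kept
three PSF widths clear of the wall (so blur of a uniform field stays
uniform and the measured dispersion is pure counting noise), and fits
`HI = a·N^b` by OLS on log–log axes, `u_b` being the slope's standard
error. The default design is 5 levels × 3 replicates, mirroring a
5-day × 2-VOI acquisition campaign. In the Poisson-limited regime the
exponent converges to −1/2; the acceptance test requires the 5 × 3
design at 6 mm PSF to land within [−0.61, −0.47]. At very high counts
HI approaches a floor set by residual non-uniformity and the fit
degenerates; the study errors on non-positive HI rather than reporting
a meaningless slope.

## TLD evaluation

`tld_dose()` implements the strictly multiplicative measurement
equation `D_w = TL · N_Dw · k_fv · H · k_mat` with quadrature
(uncorrelated) combination of relative uncertainties. The correction
factors are Monte-Carlo-derived inputs in real use; they default to 1
with zero uncertainty precisely so that a user cannot forget them
silently. `aggregate_chips()` uses inverse-variance weighting with
absolute standard uncertainties `σᵢ = Dᵢ·uᵢ`; the weighted-mean
uncertainty `1/√Σw` can never exceed the best chip's. Outlier handling
defaults to manual contamination flags; a closed-form iterated Grubbs
test (α = 0.05) is opt-in and reports every exclusion.
`dose_per_emitted_particle()` normalizes by
`N = C·V·(1−e^{−λt})/λ` — the solution volume after stick insertion is
a mandatory argument because the normalization is directly proportional
to it.

## Numerical choices and degenerate inputs

- Poisson sampling runs under a local seed and restores the caller's
  RNG stream; replicate studies derive child seeds by fixed increments.
- Constant images: dAVH/dDVH fall back to a single bin; skewness and
  HI of an all-zero VOI error rather than returning NaN.
- Negative voxels (possible in real reconstructions) are clamped to
  zero before dosimetry with a reported count.
- Geometry mismatches between image and mask, empty masks, unit-tag
  mismatches, and out-of-grid compartments are hard errors naming the
  offender.

## Problem sizes

The package's own test and acceptance runs use: the anthropomorphic
phantom at full size (118 × 88 × 62 voxels), the IEC phantom at
94 × 94 × 63, the noise study on a 60 mm cylinder (≈ 35³ grid,
15 simulations), and 100-replicate unbiasedness checks on a ≈ 30³
grid. These sizes keep the full suite under a minute on one CPU while
leaving every statistic comfortably inside its asymptotic regime; all
of them scale up by passing larger grids or more replicates.

## Known limitations

- Independent-Poisson noise underestimates the spatial correlation of
  iteratively reconstructed PET noise; the HI power-law *exponent* is
  robust to this, its *amplitude* is not.
- The synthetic beta kernel is an analytic stand-in, not dosimetry-grade.
- No CT-density heterogeneity, so lung/bone interfaces are out of scope.
- Uncertainties are propagated as uncorrelated; correlated calibration
  chains (e.g. one reader for all chips) are not yet representable.
- Masks are voxel-resolution binary; no sub-voxel or mesh contours.
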