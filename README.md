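# y90voxdose

Voxel-level dosimetry and quantification for yttrium-90 PET/CT phantom
studies.

After radioembolization (SIRT), the ⁹⁰Y-laden microspheres lodged in the
hepatic arterial tree act as a permanent implant, and the rare internal
pair production of the ⁹⁰Zr 0⁺–0⁺ transition (branch ratio
≈ 3.186 × 10⁻⁵) makes the activity distribution imageable by PET.
`y90voxdose` implements the full chain a physicist uses to validate
quantitative ⁹⁰Y-PET dosimetry on phantoms:

- **Phantom simulation** — software phantoms (uniform calibration
  cylinder, IEC body phantom with six spheres, anthropomorphic torso
  with a hepatic-lesion insert) rasterized with sub-voxel precision, and
  a post-reconstruction PET noise model: expected positron counts per
  voxel, Gaussian PSF blur, Poisson sampling, inversion back to Bq/mL.
- **Quantification** — VOI statistics with quartiles and skewness,
  differential activity-volume histograms (dAVH), the homogeneity index
  (volume-weighted CV), recovery coefficients RC(V) and partial-volume
  correction, branch-ratio calibration rescaling.
- **Dosimetry** — three non-Monte-Carlo dose algorithms on the same
  contract: local deposition, dose-point-kernel convolution, and the
  MIRD uniform-activity average, plus differential DVHs.
- **Noise analysis** — the power law HI = a·N^b versus emitted positrons
  (b → −1/2 for counting noise).
- **TLD evaluation** — the multiplicative measurement equation
  `D_w = TL · N_Dw · k_fv · H · k_mat` with quadrature uncertainty
  propagation, inverse-variance chip aggregation, and normalization to
  dose per emitted beta particle.

## The core model

For a permanent implant the cumulated decays per voxel are
`Ã = C · v_voxel · T½ / ln 2` (C in Bq/mL). With unit density and the
assumption that each decay's beta energy Ē is absorbed where it is
emitted (local deposition),

```
D_voxel [Gy] = C_voxel [Bq/mL] × (T½/ln2) · Ē · 1.602×10⁻¹³ × 10³
             ≈ C_voxel × 4.97×10⁻⁵ [Gy·s·mL]        (⁹⁰Y: T½ = 2.67 d, Ē = 0.932 MeV)
```

Kernel convolution generalizes this: `D = S ⊗ Ã` with a voxel S-value
kernel `S(Δ)` (Gy per decay) whose energy closure
`Σ S·m_voxel = Ē·1.602×10⁻¹³ J` is enforced at construction. A delta
kernel makes the two algorithms identical; on uniform activity both
match the MIRD average (radiation equilibrium).

## Worked example

Day-1 study condition: lesion insert at 5.5 MBq/mL in a 0.89 MBq/mL
liver (6:1), 15-min scan, 6 mm PSF.

```r
library(y90voxdose)
nuc <- y90_constants()

ph  <- build_phantom(phantom_anthropomorphic())   # 5.5 / 0.89 MBq/mL defaults
acq <- pet_acq_params(scan_time_s = 900, psf_fwhm_mm = 6, seed = 42)
img <- simulate_pet(ph$activity, nuc, acq)

voi_stats(img, ph$masks$insert)
#> <voi_stats> n = 765 (18.64 mL); mean 4.653e+06, sd 1.69e+06,
#>   [q1 3.339e+06, q3 5.724e+06], range [4.77e+05, 1.002e+07], skewness 0.341
homogeneity_index(img, ph$masks$insert)           # 0.36
```

The uncorrected mean underestimates the true 5.5 MBq/mL by −15.4 %
(partial-volume spill-out plus noise); the recovered values are
positively skewed, as low-count PET images are. Recovery coefficients
measured on the simulated IEC spheres correct this:

```r
iec <- build_phantom(phantom_iec_body())
ref <- simulate_pet(iec$activity, nuc,
                    pet_acq_params(900, psf_fwhm_mm = 6, sensitivity = 1, seed = 7))
sph <- grep("^sphere_", names(iec$masks), value = TRUE)
rc  <- recovery_coefficients(
  vapply(iec$masks[sph], function(m) voi_stats(ref, m)$mean, numeric(1)),
  2.28e6, vapply(iec$masks[sph], mask_volume_ml, numeric(1)))
rc$rc                                             # 0.49 0.62 0.69 0.74 0.81 0.85

pve_correct(voi_stats(img, ph$masks$insert)$mean,
            mask_volume_ml(ph$masks$insert), rc)  # 5.60 MBq/mL (+1.8 %)
```

Dose, three ways:

```r
dose <- local_deposition_dose(img, nuc)
dose_summary(dose, ph$masks$insert)               # 231 +/- 84 Gy
mird_average_dose(5.5e6, nuc)                     # 273 Gy (true concentration)
kernel_convolve_dose(img, beta_point_kernel(nuc, img$voxel_size_mm), nuc)
```

And the noise law — homogeneity index versus emitted positrons over two
decades of activity:

```r
hi_noise_study(c(0.1, 0.32, 1, 3.2, 10) * 1e6, pet_acq_params(900, seed = 1))
#> <power_law_fit> y = 356.3 * x^(-0.491 +/- 0.006), r^2 = 0.998
```

The fitted exponent sits at the −1/2 expected when image noise is
dominated by counting statistics.

A YAML-driven pipeline (`run_pipeline()`) and a thin command-line
wrapper (`inst/cli/y90voxdose.R`, subcommands `simulate-phantom`,
`quantify`, `dose`, `hi-fit`, `hi-study`, `tld`, `run`) tie the stages
together; reports are deterministic JSON given a seed.

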