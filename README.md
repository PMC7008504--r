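# sfdi

Processing chain for spatial frequency domain imaging (SFDI) — a
wide-field diffuse optical technique that projects sinusoidal
illumination patterns onto tissue and, from the remitted light, maps the
absorption coefficient μa and reduced scattering coefficient μs′
(mm⁻¹) pixel by pixel. Absorption measured at several wavelengths then
yields oxy- and deoxyhemoglobin concentrations, and the same projected
fringes support phase-stepping surface profilometry. The package is
aimed at groups building or validating low-cost SFDI instruments who
need a transparent, fully testable software chain rather than a vendor
black box.

## What it implements

- **Forward model** — semi-infinite diffusion approximation in the
  spatial frequency domain:
  `Rd = 3 A a′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A))` with
  `μtr = μa + μs′`, `a′ = μs′/μtr`,
  `μeff′(fx) = sqrt(3 μa μtr + (2π fx)²)`, plus an independent photon
  Monte Carlo cross-check (Henyey–Greenstein scattering, Fresnel
  boundary, Hankel-transformed radial reflectance).
- **Demodulation** — three-phase AC/DC amplitude recovery,
  `m_AC = (√2/3)·√((I1−I2)² + (I2−I3)² + (I3−I1)²)`, exact for ideal
  sinusoids.
- **Calibration** — instrument-response removal against a characterized
  tissue-mimicking phantom, with cubic-spline / power-law spectral
  interpolation of the phantom characterization.
- **Lookup-table inversion** — per-pixel `(Rd(f1), Rd(f2)) → (μa, μs′)`
  via inverse interpolation of a two-frequency table, with out-of-domain
  flagging instead of clamping.
- **Chromophore unmixing** — per-pixel least squares on
  `μa(λ) = Σ εk(λ) ck` (optionally nonnegative, solved exactly), scatter
  power-law fits `μs′ = a (λ/800)⁻ᵇ`.
- **Profilometry** — fringe phase extraction, quality-guided phase
  unwrapping, per-pixel phase-to-height calibration and
  intensity–height correction.
- **Synthetic scene simulator** — renders raw frame stacks (gain map,
  modulation, sensor noise, 10-bit quantization) from known ground
  truth, so the whole chain is testable without hardware.
- **Agreement statistics** — ROI summaries, percent difference,
  Bland–Altman limits of agreement with their uncertainty, drift
  summaries.

## Worked example

Simulate the nine-phantom accuracy experiment (a 3×3 block scene
spanning μa ∈ [0.005, 0.07] and μs′ ∈ [0.5, 2] mm⁻¹), process it through
demodulation → calibration → inversion, and compare block means against
ground truth:

```r
library(sfdi)

scene <- make_phantom_grid_scene(3, 3)              # 256x256 px, 0.3 mm pitch
phantom <- phantom_spec(800, 0.007, 0.93)           # calibration phantom
lut <- build_lut(c(0, 0.1))                         # two-frequency table

inst <- instrument_model(noise = "default", seed = 21)
sample_stack <- simulate_raw_stack(scene, inst, 800)
ref_stack <- simulate_reference_stack(phantom,
  instrument_model(noise = "default", seed = 22), 800)

res <- process_stacks(sample_stack, ref_stack, phantom, lut)
summary <- scene_block_summary(res$property_maps[["800"]], scene)
summary[, c("mu_a_true", "mu_a_mean", "mu_a_pct_err",
            "mu_s_true", "mu_s_mean", "mu_s_pct_err")]
```

```
# A tibble: 9 x 6
  mu_a_true mu_a_mean mu_a_pct_err mu_s_true mu_s_mean mu_s_pct_err
      <dbl>     <dbl>        <dbl>     <dbl>     <dbl>        <dbl>
1    0.005    0.00501        0.226      0.5      0.501        0.229
2    0.005    0.00503        0.686      1.25     1.26         0.421
3    0.005    0.00503        0.579      2        2.01         0.399
4    0.0375   0.0376         0.212      0.5      0.501        0.286
5    0.0375   0.0378         0.722      1.25     1.26         0.600
6    0.0375   0.0381         1.47       2        2.02         1.24
7    0.07     0.0705         0.648      0.5      0.503        0.555
8    0.07     0.0708         1.20       1.25     1.26         1.06
9    0.07     0.0714         1.97       2        2.03         1.75
```

Each row is one simulated phantom: the per-block mean of the recovered
per-pixel property map sits within ~2% of ground truth under the
default 10-bit sensor noise model (noiseless runs recover within 0.1%).
`res$rd_maps` holds the calibrated reflectance maps and, with an
extinction table and ≥2 wavelengths, `res$chromophores` the hemoglobin
concentration maps.

A thin command-line wrapper over the same functions lives at
`inst/cli/sfdi.R` (subcommands `simulate`, `build-lut`, `process`,
`profile`, `compare`, `drift`).

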