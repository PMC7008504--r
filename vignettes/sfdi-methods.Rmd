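---
title: "Models and methods behind the sfdi processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sfdi processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Spatial frequency domain imaging (SFDI) projects sinusoidal illumination
patterns onto a turbid sample and images the remitted light. Demodulating
phase-shifted frames yields the sample's diffuse reflectance as a function
of spatial frequency — its spatial modulation transfer function — and
because absorption and scattering attenuate different spatial frequencies
differently, reflectance measured at two frequencies separates the
absorption coefficient $\mu_a$ from the reduced scattering coefficient
$\mu_s'$ at every pixel. This vignette documents the models, parameter
choices and numerical decisions in each stage of the chain, and what the
package's synthetic validation does and does not demonstrate about real
instruments.

## The forward model

`diffuse_reflectance()` implements the standard semi-infinite
diffusion-approximation solution in the spatial frequency domain. With
$\mu_{tr} = \mu_a + \mu_s'$, $a' = \mu_s'/\mu_{tr}$ and
$\mu_{eff}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}$,

$$R_d(f_x) = \frac{3 A a'}
  {(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)},$$

where $A = (1-R_{eff})/(2(1+R_{eff}))$ and
$R_{eff} = 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$ encode the
refractive-index-mismatch boundary condition. The default tissue index is
$n = 1.4$, the conventional soft-tissue value; it is configurable
everywhere a medium is described. Two structural properties anchor the
test suite: the conservation limit $R_d = 1$ exactly at
$\mu_a = 0, f_x = 0$, and monotone decrease of $R_d$ in both $\mu_a$ and
$f_x$.

The monotonicity in $\mu_a$ holds only while the medium remains
scattering-dominated at the probing frequency, i.e. while
$\mu_{tr} \gtrsim 2\pi f_x$. Outside that regime (for example
$\mu_s' = 0.1\,\mathrm{mm^{-1}}$ at $f_x = 0.1\,\mathrm{mm^{-1}}$) the
closed form genuinely folds: adding absorption *raises* the predicted AC
reflectance because $\mu_{eff}'/\mu_{tr}$ shrinks. The monotonicity
checks therefore run on the instrument's operating domain
($\mu_s' \in [0.5, 5]$, $f_x \le 0.15\,\mathrm{mm^{-1}}$,
$\mu_a \le 0.5\,\mathrm{mm^{-1}}$), which contains the physiological
phantom range with margin.

## The Monte Carlo cross-check

`monte_carlo_rd()` is an independent photon-transport oracle used to
validate the diffusion closed form, never as the production inversion
path. Photon packets random-walk in a semi-infinite medium with
Henyey–Greenstein scattering at anisotropy $g$ and
$\mu_s = \mu_s'/(1-g)$, weight attenuation by the single-scattering
albedo, Russian roulette below weight $10^{-4}$, and sampled unpolarized
Fresnel reflection (with total internal reflection) at the boundary.
Escaping weight is binned by exit radius (0.1 mm bins to 50 mm) and
$R_d(f_x)$ is obtained as the zeroth-order Hankel transform of the radial
profile; per-photon accumulation also yields a standard error for every
requested frequency. A dedicated PRNG stream makes runs bitwise
reproducible per seed without touching R's global generator, and photons
deeper than 150 mm are terminated (their round-trip attenuation is below
$e^{-30}$ for any supported $\mu_a$, so the induced bias is far below
sampling error).

The anisotropy default, $g = 0.8$, was chosen by a convergence study
rather than taken from the similarity shortcut. Isotropic scattering at
the reduced coefficient ($g = 0$) reproduces the diffusion model well at
$f_x = 0$ but over-backscatters at short pathlengths, inflating
high-frequency reflectance well beyond the 15% agreement band at
$\mu_s' = 0.5\,\mathrm{mm^{-1}}$; with forward-peaked scattering at the
tissue-typical $g = 0.8$ the two models agree within 15% everywhere the
diffusion approximation claims validity ($\mu_s'/\mu_a \ge 10$, $f_x \le
0.1\,\mathrm{mm^{-1}}$). This frequency-dependent sensitivity to the
phase function is a known sub-diffusive transport effect, and it sets a
real limit on diffusion-based lookup tables: at the extreme corner of the
validation grid ($\mu_a = 0.07$, $\mu_s' = 0.5\,\mathrm{mm^{-1}}$, ratio
$\approx 7$) transport and diffusion separate by more than 15% at
$f_x = 0.1\,\mathrm{mm^{-1}}$, and the corresponding agreement check is
expected to fail there — the acceptance suite reports that node's
deviation rather than hiding it. Absolute optical properties recovered through a
diffusion-derived table will differ accordingly from those of a true
Monte Carlo table for strongly absorbing, weakly scattering media; the
lookup-table archive format exists precisely so an externally generated
transport table can be dropped in.

## Demodulation

Three frames per (wavelength, frequency) channel are acquired at
projection phases $0, 2\pi/3, 4\pi/3$. For an ideal triplet
$I_i = O + A\cos(\phi + p_i)$,

$$m_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}
 = A, \qquad m_{DC} = \tfrac13 (I_1+I_2+I_3) = O,$$

identically in $\phi$ and $O$; the estimator is also invariant to frame
order. The planar (DC) channel defaults to the dedicated $f_x = 0$
triplet when present and falls back to the DC estimator on the lowest AC
triplet otherwise, with the choice recorded in the result. Pixels at the
sensor's bit-depth ceiling in any contributing frame are flagged invalid
rather than demodulated silently.

## Calibration

The camera never observes reflectance directly: every channel is scaled
by an unknown multiplicative instrument response (source power, optics,
pixel gain). Measuring a phantom with known $\mu_a(\lambda),
\mu_s'(\lambda)$ under identical settings and ratioing,

$$R_d^{samp}(x) = \frac{m^{samp}(x)}{m^{ref}(x)}\; R_d^{pred},$$

cancels the response exactly, including its spatial structure. The
phantom's predicted reflectance comes from the forward model evaluated at
properties interpolated to the measurement wavelength: absorption through
a natural cubic spline over the characterization points, reduced
scattering through the power law $\mu_s' = a(\lambda/\lambda_0)^{-b}$
with $\lambda_0 = 800$ nm, fitted in log space (exact with two points;
a single-point specification only answers exact-wavelength queries).
Queries outside the characterized span are refused rather than
extrapolated. Reference pixels below $10^{-3}$ of the reference maximum
(a noise floor the user can move) are masked instead of divided through.

## Lookup-table inversion

The two-frequency table stores $R_d$ at both frequencies over a grid that
is log-spaced in $\mu_a$ (reflectance varies fastest at low absorption)
and linear in $\mu_s'$, by default $128 \times 128$ over
$[0.001, 0.5] \times [0.1, 5]\,\mathrm{mm^{-1}}$ — the physiological
phantom range with wide margin. Inversion treats the pair of bilinear
surfaces as a forward map of continuous grid coordinates and runs a
damped, step-limited Newton iteration seeded at the nearest node of a
coarse sub-lattice; this is inverse interpolation over the structured LUT
mesh with piecewise-linear accuracy, equivalent to triangulating the
scattered image points but without a triangulation dependency. The
forward residual at the solution is kept per pixel; solutions whose
relative residual exceeds $10^{-3}$ (targets outside the hull of the LUT
image, including nonphysical pairs such as $R_d > 1$ or AC exceeding DC)
are flagged out-of-domain rather than clamped, because clamping would
silently bias $\mu_a$ at the extremes. On the default table, noiseless
round trips recover properties to well under 0.1% everywhere strictly
inside the domain.

## Chromophore unmixing

Absorption at wavelength $\lambda$ is modeled as
$\mu_a(\lambda) = \sum_k \varepsilon_k(\lambda) c_k$ over the fitted
chromophores (by default oxy- and deoxyhemoglobin; units mm⁻¹, µM, and
mm⁻¹µM⁻¹). With at least as many wavelengths as chromophores the
per-pixel least-squares solve is a single QR factorization applied to all
pixels at once. Nonnegativity is on by default — concentrations are
physical — and pixels whose unconstrained solution leaves the feasible
quadrant are re-solved exactly by enumerating active sets, which is the
exact NNLS solution for the small chromophore counts used here. The
shipped extinction table is a synthetic but physically shaped fixture
(660–900 nm in 5 nm steps, isosbestic crossing at 800 nm, magnitudes of
order $10^{-4}\,\mathrm{mm^{-1}\mu M^{-1}}$), clearly labelled as such;
any literature compilation in the same CSV layout can replace it, and the
solver is generic in the number of chromophore columns. Water and lipid
are deliberately excluded from the default table: three measurement
wavelengths support only two unknowns robustly.

Spectral harmonization between instruments with different wavelength sets
uses the same two primitives exposed directly:
`interpolate_mu_a_spline()` (natural cubic spline, cross-checked in the
tests against an independently coded tridiagonal solver) and
`fit_scatter_power_law()`.

## Profilometry

Fringe phase is extracted from the three-step triplet as
$\varphi = \operatorname{atan2}(\sqrt3(I_3 - I_2),\; 2I_1 - I_2 - I_3)$,
the estimator consistent with the $0, 2\pi/3, 4\pi/3$ phase set, and
wrapped phase is unwrapped by quality-guided flood fill with local
modulation amplitude as the quality measure — chosen over row-wise
unwrapping for robustness to masked regions, since the scan order reaches
low-quality pixels last. Surface measurement follows standard
fringe-projection practice: the wrapped difference between object and
flat-reference measurements removes the projection carrier before
unwrapping, and a known-flat margin of the scene anchors the remaining
global $2\pi$ multiple (`rebase_phase()`). Height calibration fits, per
pixel, a line of phase versus known height from flat-phantom scans;
wrapped calibration maps are unwrapped temporally through the wrapped
successive differences, which is exact while consecutive height steps
move the phase by less than $\pi$. The phase-to-height relation is taken
as per-pixel linear, with the triangulation geometry folded into the
fitted gain (default 2 mm/rad in the simulator; with the default
0.3 mm pixel pitch this keeps the steepest usable surface slope, e.g.
the rim of a 17.5 mm hemisphere, below the $\pi$-per-pixel wrap limit).
The companion intensity–height model fits per-pixel intensity against
height and re-references images to the calibration plane; it is applied
to raw intensities, before demodulation.

## The synthetic scene generator

`simulate_raw_stack()` inverts the processing chain for validation: per
wavelength, frequency and phase,

$$I_i(x) = G(x)\left[R_d(0) + m\,R_d(f_x)\cos(2\pi f_x x + p_i +
  h(x)/g_h)\right],$$

with per-pixel reflectance from the forward model, multiplicative gain
map $G$ (the simulated instrument response), modulation depth $m = 0.8$,
and surface height $h$ encoded through the phase–height gain $g_h$ on AC
channels. Image formation is plain-cosine with per-pixel reflectance — no
lateral light transport blur — so block edges in piecewise scenes are
sharp; block statistics therefore exclude a 2-pixel guard band. The
default field is $256 \times 256$ pixels at 0.3 mm pitch (a ~7.7 cm
illuminated field, the scale of a small benchtop system).

The sensor model mirrors a 10-bit CMOS camera: exposure of 600 counts per
unit reflectance (about 80% of full scale for the brightest calibration
target), Poisson shot noise at the photoelectron level with 15
photoelectrons per count, Gaussian read noise of 2 counts, and 10-bit
clipping/quantization. Modeling shot noise at the electron rather than
the count level matters: counts are not photon counts, and treating them
as Poisson draws exaggerates shot noise several-fold, which propagates
through the nonlinear inversion as a systematic (Jensen) bias of order
10% in block means. Every noise stage is individually skippable and all
draws derive from the instrument seed, leaving R's global RNG untouched.

What passing the synthetic chain shows — and what it does not: gain
cancellation, demodulation identities, inversion round trips and
concentration recovery are validated end to end, but the generator shares
its forward model with the inversion, renders no lateral photon
migration, no specular component (real systems suppress it with crossed
polarizers), no projector nonlinearity, and no phantom
mischaracterization. Agreement with a physical reference instrument, as
opposed to internal consistency, cannot be established at desk scale.

## Agreement statistics

`bland_altman()` reports the mean difference, the limits of agreement
$\bar d \pm 1.96\,s_d$ (the band expected to contain ~95% of paired
differences under Gaussian assumptions), and the uncertainty of the
limits themselves: standard error $\sqrt{3 s_d^2/n}$ scaled by the $t$
quantile at $n-1$ degrees of freedom. The 1.96 multiplier is fixed for
the limits; the $t$ quantile enters only their confidence half-width.
Sample (n−1) standard deviations are used throughout the statistics
module, and differences are oriented instrument-under-test minus
reference. `drift_summary()` reduces repeated phantom measurements to a
per-wavelength standard deviation and least-squares trend slope; the
tests check white-noise series against a permutation null band.

## Problem sizes and numerical conventions

The shipped validation uses the sizes a desk-scale study supports: the
nine-phantom scene at $256\times256$ pixels, hemisphere reconstruction at
$256\times256$, Monte Carlo cross-checks at $10^6$ photons per node, and
Bland–Altman oracles at $n = 10^5$. Pixel indexing is row-major and
0-based in all file formats and ROI bounds, with ROIs half-open
$[r_0,r_1)\times[c_0,c_1)$; physical quantities are mm and mm⁻¹ with
wavelengths in nm. Maps are serialized as 32-bit float TIFF with JSON
sidecars (values scaled into $[0,1]$ with the factor recorded), so round
trips are exact for integer sensor counts and float32-accurate otherwise.

## Known limitations

Only the two-frequency inversion path is implemented (not multi-frequency
fitting), media are homogeneous and semi-infinite (no layered models or
tomography), chromophore fitting ships with two chromophores, and the
profilometric height map is not fed back to correct optical-property maps
beyond the intensity–height step. Error propagation from uncertainty in
the calibration phantom's characterization is out of scope; the validity
mask is the only guard.
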