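---
title: "Estimating membrane mechanics from vesicle fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane mechanics from vesicle fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesimech)
```

## The model

A fluid lipid membrane resists bending with a rigidity $\kappa$ (units J,
typically 10--20 $k_BT$ for phosphatidylcholine bilayers) and resists area
change with a tension $\sigma$ (N/m). For a quasi-spherical vesicle of mean
radius $R$, the shape is written as a sphere plus small radial undulations,

$$ r(\theta, \phi) = R\Big(1 + \sum_{l \ge 2, m} a_{lm}\,
   Y_{lm}(\theta, \phi)\Big), $$

with $Y_{lm}$ the real, unit-normalised spherical harmonics. For vanishing
spontaneous curvature, equipartition of the Helfrich curvature energy over
the modes gives the Milner--Safran spectrum

$$ \langle a_{lm}^2 \rangle \;=\; \frac{k_B T}
   {\kappa\,(l-1)(l+2)\,\big[l(l+1) + \bar\sigma\big]},
   \qquad \bar\sigma = \frac{\sigma R^2}{\kappa}, $$

independent of $m$, with independent zero-mean Gaussian amplitudes. The
$l = 0$ (volume) and $l = 1$ (translation) modes are not shape
fluctuations and are excluded everywhere. All estimators in this package
are inversions of this one closed form, approached through two very
different observables:

* **SPHA** (spectral harmonics analysis) works on particle-resolved
  vesicle trajectories: per-leaflet sphere fits, a radius-subtracted
  displacement field on a $(\theta, \phi)$ grid, leaflet averaging, a
  spherical-harmonic transform, and a weighted fit of the power per degree.
* **Flicker-noise spectroscopy** works on time-lapse equatorial contours
  of a giant unilamellar vesicle (GUV): the angular autocorrelation
  $\xi(\gamma)$ of the relative radial displacement is, by the addition
  theorem, $\sum_l B_l P_l(\cos\gamma)$ with
  $B_l = \frac{2l+1}{4\pi}\langle a_{lm}^2\rangle$, so a Legendre
  decomposition of $\xi$ exposes the same spectrum. Two estimators are
  provided: the average-based (AVB) fit of the time-averaged
  $\langle B_l \rangle$, and the statistical (SA) fit of the per-frame
  $B_l(t)$ distributions.

Because the real data behind the published tables (MD trajectories,
microscope videos) are not deposited, the package carries synthetic-data
generators that draw from exactly this mode model. Every estimator is then
testable by parameter recovery: generate at a known $\kappa$, analyse,
compare.

## The synthetic generators and what they emulate

`gen_vesicle_ensemble()` builds a two-leaflet vesicle: head particles sit
on quasi-uniform (Fibonacci-lattice) directions on surfaces at
$r(\theta,\phi) \pm t/2$, where $t$ is the head-to-head bilayer thickness,
with per-leaflet lipid counts derived from the initial-construction rule
(starting area per lipid 68.1 Å² on average, scaled by 0.95 for the inner
and 1.05 for the outer leaflet on a 20 nm mid-surface sphere). Tail-carbon
pairs are radially inset toward the bilayer midplane, and optional peptide
particles are placed in the interphase band between head and acyl-chain
radii — mirroring where amyloid-β monomers reside in a bilayer. Defaults:
$R = 20$ nm, $t = 3.43$ nm, $T = 296.15$ K (23 °C, the imaging
temperature), $\kappa = 7.3\times10^{-20}$ J, $\bar\sigma = 0$, mode
content $l = 2..14$, and isotropic positional noise of 0.1 nm — a modest
sub-headgroup roughness on top of the continuum surface, chosen so that
its white-noise floor stays a few percent of the weakest fitted mode
($l = 12$) of the default spectrum.

Per frame, mode amplitudes are drawn independently; frames are
statistically independent, which is all the equal-time estimators here
use. The lipid lattice directions are fixed across frames (only the radial
field and the positional noise are redrawn). This costs nothing for
equal-time statistics and makes generation deterministic given seed and
configuration. What the generator deliberately does *not* emulate:
hydrodynamic time correlations, lipid diffusion, peptide conformations,
or protrusion modes beyond `l_max`. Recovery tests on these data therefore
validate the estimator inversion chain, not the continuum model's fidelity
to molecular reality.

`gen_contour_series()` evaluates the same mode model on the equator,
producing per-frame contour radii $\rho(\phi_i)$ at 512 uniform angles,
with defaults of a 10 μm GUV at $\kappa = 10.5\times10^{-20}$ J, 0.133 μm
pixel size, and 0.02 μm per-point detection noise (about 0.15 px,
the plausible scale of sub-pixel tracking error). `render_guv_images()`
turns contours into 512×512 images — a bright ring with Gaussian radial
cross-section and Poisson photon noise — so the sub-pixel contour detector
can be validated by round trip. No focal-depth or finite-integration-time
corrections are modelled; analyses of synthetic contours are internally
consistent without them, and the omission is stated rather than guessed.

`gen_wave_trajectory()` produces a planar membrane executing a damped
standing wave, $z(x,t) = A_0 e^{-t/\tau}\cos(\omega t)\sin(2\pi x/\lambda
+ \varphi)$, sampled at fixed random positions — plumbing for the
pressure-wave amplitude tracker. The defaults (1 nm initial amplitude,
30 nm wavelength and box, $\omega = 0.05$ rad/ps, $\tau = 500$ ps, 2 ps
frames) put several amplitude oscillations inside a sub-nanosecond
window, the regime in which a membrane relaxes after an impulsive water
kick.

## Parameters that matter, and their defaults

| Parameter | Default | Why |
|---|---|---|
| grid (`n_theta` × `n_phi`) | 64 × 128 | ~1 lipid per cell per leaflet for ~7400-lipid leaflets; latitude bands uniform in $\cos\theta$ so every cell has equal solid angle |
| `fill_strategy` | `"idw"` | inverse-great-circle-distance fill of empty cells from occupied neighbours; avoids the spectral leakage that zero-filling causes |
| SPHA `l_range` | 2..12 | low degrees carry the bending signal; higher degrees are grid- and noise-contaminated |
| flicker `l_range` | 2..10 | same reasoning at 512 contour points |
| QC `k_mad` | 3 | the outlier rule for per-frame mean radius is unstated in the source protocol; 3 MADs is the conventional robust cut |
| `envelope_floor` | 0.02 | extrema search stops once the smoothed amplitude envelope decays below 2% of its maximum, so fit noise does not masquerade as oscillation |
| temperature | 296.15 K | the stated imaging temperature (23 °C) |

The equal-area latitude banding departs from a uniform-$\theta$ grid: with
quasi-uniform surface sampling a uniform-$\theta$ grid leaves near-polar
cells essentially empty, defeating the "one lipid per cell" sizing that
motivates the resolution in the first place, and equal-area cells make the
quadrature weights a single constant $4\pi/N_{\rm cells}$.

## Numerical choices

* **Sphere fits** use algebraic (linearised) least squares followed by one
  geometric Gauss--Newton step: deterministic, no starting guess, and
  agreeing with a full nonlinear fit to $10^{-6}$ on test clouds. Inputs
  with fewer than 4 points or a coplanar/collinear configuration are
  rejected.
* **The spectrum fit** runs on $\log$ power with delta-method weights
  $({\rm SE}/P)^{-2}$. Sampling errors of a mean-square spectrum are
  multiplicative (chi-square), so the log fit is the natural weighted
  least squares; it is also far better conditioned across the four decades
  a vesicle spectrum spans. Initialisation is by exact linear inversion
  (the reciprocal spectrum is linear in $\kappa$ and
  $\kappa\bar\sigma$), refined by Levenberg--Marquardt with a port-NLS
  fallback. $\bar\sigma$ is bounded below by $-6 + \varepsilon$, where the
  $l = 2$ mode variance diverges.
* **The SA estimator** fits each degree's per-frame $B_l(t)$ sample with a
  gamma family whose shape is fixed at $(2l+1)/2$ — the quadratic form of
  $2l+1$ Gaussian amplitudes — and whose scale is estimated from the
  gamma likelihood's estimating equation $\hat s = \bar B_l/k$. A single
  frame's autocorrelation mixes degrees, so individual $B_l(t)$ samples
  can undershoot zero at weakly excited degrees; the estimating-equation
  form stays defined there, the negative fraction is reported per degree,
  and histograms with the fitted density are emitted for inspection. The
  exact statistical-approach formulation in the experimental literature is
  not restated in the source; this gamma formulation is validated by
  recovery on the generator, not claimed to reproduce the original code.
* **Contour detection** casts rays from the intensity centroid, samples
  profiles bilinearly at 0.25 px steps, and refines the peak with a
  least-squares parabola on the log intensity over a ±1.5 px window —
  exact for a Gaussian ring cross-section. Centroid centring necessarily
  absorbs the contour's first angular harmonic (a pure $m = 1$ contour
  term is indistinguishable from a centre shift at first order); this is
  the correct translation-invariant behaviour and does not perturb the
  $l \ge 2$ spectrum in expectation.
* **Legendre decomposition** integrates
  $\frac{2l+1}{2}\int_0^\pi \xi(\gamma) P_l(\cos\gamma)\sin\gamma\,
  d\gamma$ by trapezoid on the sampled lags; the $\sin\gamma$ factor
  vanishing at both endpoints makes the rule effectively second order.
  Per-frame mean subtraction removes the azimuthal $m = 0$ content of the
  contour, which shifts only the $l = 0$ coefficient, not the fitted
  degrees.
* **Degenerate inputs** error early and explicitly: empty leaflets,
  fluctuation-free series (the SA distributions collapse), flat membranes
  in the sine fitter (flagged `degenerate` rather than fit), series with
  more than half their frames QC-masked.

## Scale of the validation runs

The bundled tests recover $\kappa$ through the full SPHA pipeline on
2000-frame ensembles of ~14,800 lipids (both at the reference POPC
rigidity and at a peptide-softened value, tolerance 10%), and through the
flicker estimators on 5000-contour series (AVB 15%, SA 20%, SA/AVB
cross-agreement 10%). Property checks run at smaller sizes chosen so each
assertion's sampling error sits well inside its tolerance: e.g. 800-frame
ensembles for the chi-square band test of generated mode variances, and
400 + 5000 frames for the addition-theorem consistency between the 3D
spectrum and its equatorial cut. Observed recovery error at these sizes is
~1% for SPHA and ~1--3% for the flicker estimators, an order of magnitude
inside the tolerances.

## A worked example

```{r example, eval = FALSE}
library(vesimech)

## simulate a vesicle at a known rigidity and recover it
traj <- gen_vesicle_ensemble(vesicle_config(
  kappa = 7.3e-20, n_frames = 200, detail = "heads", seed = 1))
fit <- spha_kappa(traj)
glance(fit)

## flicker spectroscopy on synthetic GUV contours
cs <- gen_contour_series(contour_config(kappa = 10.5e-20,
                                        n_frames = 2000, seed = 1))
res <- flicker_kappa(cs)
glance(res$AVB); glance(res$SA)

## structural parameters
st <- membrane_thickness(traj)
tidy(st)

autoplot(attr(fit, "spectrum"), fit = fit)
```

## Known limitations

* Estimates degrade gracefully but measurably when the true tension is
  large ($\bar\sigma \gtrsim 10^3$): the low-$l$ modes then carry little
  bending information and the $(\kappa, \bar\sigma)$ covariance grows.
* The SPHA grid transform attenuates power by a few percent at the top of
  the fitted range (cell-averaging acts as a low-pass); with the default
  grid and `l_range` this biases $\kappa$ by roughly +2--3%, small against
  the 10% recovery tolerance but not zero.
* The image renderer is a minimal optical model (Gaussian ring + Poisson
  noise); it validates the detector, not a microscope.
* The pressure-impulse calculator implements
  $\Delta v_z = I A / (m N)$ as a standalone unit converter. The source
  protocol prints mutually inconsistent impulse units (10 μN/m²·s versus
  1 mPa·s); the calculator takes SI Pa·s and leaves that discrepancy to
  the caller.
* Statistical comparison of wave-response timing ("maxima occur later")
  is reported as lags and extrema rates without a significance procedure,
  since none is specified for it; rigidity and structural populations are
  compared with ANOVA + Tukey and Kruskal--Wallis in
  `compare_populations()`.
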