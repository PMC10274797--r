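---
title: "Speckle microrheology: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle microrheology: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specklerheo)
```

## The measurement model

Backscattered coherent light from a turbid sample forms fully developed
speckle; thermal displacements of the native scatterers decorrelate it. The
chain from raw frames to a viscoelastic spectrum is:

1. **Intensity autocorrelation.** Over a circular ROI at the 1/e radius of
   the diffuse reflectance profile (DRP), and over all frame pairs separated
   by lag $t$,
   $$g_{2,\mathrm{raw}}(t) = \frac{\langle I(t_0)\,I(t_0+t)\rangle}
   {\langle I(t_0)\rangle\langle I(t_0+t)\rangle},\qquad
   g_2(t) = \frac{g_{2,\mathrm{raw}}(t)-1}{g_{2,\mathrm{raw}}(0)-1} + 1 .$$
   The lag-0 reference is the *same-frame second moment*, which pins
   $g_2(0) = 2$ and cancels any multiplicative coherence factor
   $\beta \in (0,1]$ (partial polarization, incoherent background). The
   alternative reference — the smallest nonzero lag — would under-normalize
   whenever the first lag already carries decay; we use the same-frame moment
   and note the alternative.

2. **MSD inversion.** The empirical bridge between the single-scattering
   (DLS) and diffusive (DWS) limits is
   $$g_2(t) - 1 = \exp\!\left(-2\gamma\,[k^2\langle\Delta r^2(t)\rangle]^{\zeta}\right),$$
   with $k = 2\pi n/\lambda$ the in-medium wavenumber. $(\gamma,\zeta) =
   (2/3, 1)$ reproduces DLS at 180°; $(5/3, 0.5)$ reproduces DWS
   backscattering; turbid tissue falls in between. *Dimensional grouping:*
   the exponent must act on the dimensionless product $k^2\langle\Delta
   r^2\rangle$ — raising only the MSD to $\zeta$ is dimensionally
   inconsistent for $\zeta \neq 1$ and fails to reproduce either printed
   limit. This grouping is used throughout.

3. **Algebraic GSER.** With $\alpha(\omega)$ the local log-log slope of the
   MSD at $t = 1/\omega$,
   $$|G^*(\omega)| = \frac{k_B T}{\pi a\,\Gamma(1+\alpha(\omega))\,
   \langle\Delta r^2(1/\omega)\rangle},\quad
   G' = |G^*|\cos\frac{\pi\alpha}{2},\quad
   G'' = |G^*|\sin\frac{\pi\alpha}{2}.$$
   $\alpha = 0$ is an elastic solid, $\alpha = 1$ a viscous fluid,
   $\alpha = 0.5$ the crossover $G' = G''$. The particle radius $a$ only
   scales the moduli; it never changes their frequency dependence. Spectra
   are cropped to the physically accessible band $1/\tau < \omega < F_s$.

## Fixed estimation numerics

$\alpha(\omega)$ is estimated with a fixed recipe — these are not tunables:

* resample $\log\langle\Delta r^2\rangle$ onto a log-$\omega$ grid at
  **30 points/decade** ($\omega = 1/t$);
* slope of $\log\langle\Delta r^2\rangle$ vs $\log t$ by least squares over a
  **7-point window** centred at $t = 1/\omega$;
* smooth $\alpha$ with a **15-point centred moving average**;
* clamp to $[0, 1]$ (the algebraic GSER's domain; raw values are kept for
  diagnostics, clamps are logged). The smoothed, clamped $\alpha$ is the one
  used inside $\Gamma(1+\alpha)$ and the phase factor.

Windows shrink symmetrically at the grid edges rather than padding; edge
half-windows are flagged lower-confidence (`$edge`) and excluded from slope
fits in the examples and tests.

**Masking.** Lags where the pattern has fully decorrelated are masked before
inversion: invalid where $g_2 - 1 < \max(0.03,\; 3\,\hat\sigma_{\rm tail})$,
with $\hat\sigma_{\rm tail}$ the standard deviation of $g_2-1$ over the last
decade of lags. The 0.03 floor sits below typical speckle-contrast noise for
the ensemble sizes involved and is configurable. The $3\hat\sigma$ rule is
applied *only when the tail is actually decorrelated* (tail mean below twice
the floor): for slowly relaxing, elastic-plateau-type samples the tail spread
is decay, not noise, and would otherwise swallow the usable band. Masking is
applied before resampling; the alternative order (resample, then mask) would
interpolate across invalid points.

**Envelope flattening.** The ensemble estimator assumes a homogeneous mean
intensity, but the DRP envelope varies across the ROI and leaves a spurious
baseline in $g_2 - 1$ of $(C-1)/(2C-1)$ with
$C = \langle e^2\rangle/\langle e\rangle^2 \approx 1.08$ inside the 1/e disc.
`compute_g2(..., flatten = "radial")` (default) divides each pixel by the
azimuthally averaged time-mean intensity at its radius — a static,
speckle-free envelope estimate. Per-pixel temporal means
(`flatten = "pixel"`) are *not* used by default: over a finite record they
high-pass the dynamics and measurably suppress long-lag correlations.

## Monte Carlo calibration of (γ, ζ)

Photons are random-walked through a semi-infinite medium: exponential free
paths at rate $\mu_s = \mu_s'/(1-g)$, Henyey–Greenstein scattering with
anisotropy $g$, absorption by weight attenuation $e^{-\mu_a s}$, a matched
boundary (mismatched mode is a config option), and detection within a given
radius of the injection point (180° backscattering, detector co-located with
the source). The field autocorrelation is synthesized over the detected
path-length distribution with the DWS kernel
$g_1 = \sum_s w(s)\exp(-(k^2\langle\Delta r^2\rangle/3)(s/l^*))$, and
$\ln(-\ln(g_2-1))$ is regressed on $\ln(k^2\langle\Delta r^2\rangle)$: slope
$\zeta$, intercept $\ln 2\gamma$. Fits use the experimentally measurable part
of the decay, $g_2 - 1 \in (0.01, 0.95)$ by default — outside it the
double-log transform amplifies the extreme tails, which are dominated by the
shortest/longest paths rather than the decay being inverted. Fitted values
are clipped to $[2/3, 5/3]\times[0.5, 1]$ with a warning; the raw fit is kept
in the calibration's `source`.

Two analytic limiting distributions are provided for validation:
`single_scattering_paths()` (a path of $2l^*$ — one scattering event at one
transport mean free path, in and out), whose DWS transform is exactly the DLS
backscatter form, and `diffusive_path_distribution()`, which samples the
first-passage (Lévy) law of the diffusion approximation released at
$z_e = (5/3)l^*$ and transforms exactly to $\zeta = 0.5$, $\gamma = 5/3$. Raw
transport at finite $\mu_s'$ contains genuine low-order scattering and lands
*between* the limits — which is the point of the per-sample calibration.

The lookup table spans soft-tissue optics: $\mu_s' \in [10^2, 10^4]$ m⁻¹
(5 log-spaced nodes), $\mu_a \in [1, 10^3]$ m⁻¹ (4 nodes),
$g \in \{0, 0.8, 0.9\}$, default $10^5$ photons/node; queries interpolate
bilinearly in $(\log\mu_s', \log(\mu_a+1))$ within the nearest-$g$ slice and
clamp to the hull with a warning. Optical properties are estimated from a
measured DRP by nonlinear least squares against the steady-state
diffusion-approximation reflectance of a semi-infinite medium (two-source
dipole model), on a log scale with free amplitude.

## The synthetic-data generator: what it emulates

`synthesize_speckle_movie()` emulates a high-speed backscattering speckle
instrument: fully developed speckle (circular complex Gaussian field),
**3.5 pixels/speckle** by default (the design value of the emulated sensor,
measured as the FWHM of the spatial intensity autocovariance), a Gaussian DRP
intensity envelope, a static background realizing $\beta < 1$, optional
Poisson shot noise, and quantization to the sensor bit depth. Movies are
bit-identical under a fixed seed, and every seeded operation logs its seed.

**Field statistics.** Each pixel of the pre-filter white field carries a
*stationary circular complex Gaussian process* with temporal autocovariance
$\rho(t) = \exp(-D(t)/2)$, $D(t) = 2\gamma(k^2\langle\Delta
r^2(t)\rangle)^\zeta$, generated exactly by circulant embedding; the spatial
low-pass then preserves joint Gaussianity, so the Siegert relation
$g_2 - 1 = \beta|g_1|^2$ holds *exactly*. The superficially natural
alternative — phase-only modulation of a fixed-amplitude field (fBm phases) —
was implemented first and rejected: the static amplitude leaves a
non-decorrelating self-term floor in $g_2-1$ of order
$\sum|h|^4/(\sum|h|^2)^2 \approx 2/14$ per speckle for a 3.5 px kernel, which
biased end-to-end viscosity recovery by 8–18%. The circulant construction
also realizes arbitrary monotone MSD schedules (multi-regime included)
exactly, with the autocovariance extended past the record length by the local
log-log slope of $D$.

**What the generator does not emulate:** spatially heterogeneous samples (one
MSD schedule for the whole frame), detector read noise and fixed-pattern
noise, exposure-time blurring within a frame, polarization mixing beyond the
scalar $\beta$, and sensor saturation nonlinearity (values clip at the bit
ceiling). A green end-to-end test therefore establishes the correctness of
the estimator chain on ideal fully developed speckle — not robustness to
instrument artifacts.

**Defaults as the stated world.** Temperature 295 K (room temperature),
refractive index 1.33, wavelength 637 nm, particle radius 1.5 µm, a
128×32-pixel-class sensor emulated at desk scale as 64×64; test movies use
4000–8000 frames at 10–20 kHz so that more than three decades of lag are
spanned in under a minute of compute. Full-rate instrument recordings
(hundreds of kHz for seconds, ~2.7M frames) are supported by the streaming
correlator and the multi-tau lag set (~16 lags/octave from 1 frame to
$T/10$); all-pairs correlation at every integer lag is infeasible at that
scale and the direct correlator is kept only as a test oracle.

## Fingerprint extraction choices

* Crossings and features are localized by linear interpolation in
  $\log\omega$, ties toward lower $\omega$.
* Plateaus are interior local minima of the smoothed $\alpha$ with
  *topographic* prominence $\ge 0.05$ (walk outward until the terrain drops
  below the candidate; the lower enclosing maximum sets the prominence) —
  robust to multiplicative noise, and only the deepest minimum of a basin
  survives. These minima coincide with local minima of $G''$;
  $G^0 = G'(\omega^0)$.
* Regime boundaries: transitions break regimes exactly at $\omega_T$;
  a plateau and the following scaling anchor (the $\alpha$ maximum after it,
  band edge allowed) are separated at their log-midpoint. Labels are
  ascending Roman numerals from I; a scaling interval split by an
  $\omega_\gamma$ gets sub-labels a/b. For spectra with repeated undulations
  the labels are reported with their feature evidence (the `regimes` table)
  rather than asserted as canonical.
* $\omega_\gamma$ is the sign change of the second difference of the
  smoothed log-log derivative of $G''$, edges trimmed; zero or multiple
  material inflections return "absent" with the multiplicity.
* Power-law fit intervals shrink by one grid step at each end to avoid
  curvature contamination; each fit reports its standard error.
* Exporting aggregated repeats records the spread *method* verbatim in the
  table (`spread_method`) — the aggregation convention (across repeats vs
  across sub-ensembles) must be explicit, never guessed.

## Generalized-Maxwell MSDs

For generalized Maxwell models the MSD is obtained by evaluating the model's
exact $G^*(\omega)$ and inverting the algebraic GSER
($\alpha$ from the phase, $\langle\Delta r^2\rangle = k_BT/(\pi a |G^*|
\Gamma(1+\alpha))$) rather than by numerically inverting the creep
compliance. This is the exact inverse of the pipeline's forward map, so
round-trip tests are well-posed; it differs from the true thermal MSD only by
the approximation already inherent in the algebraic GSER. Newtonian,
power-law and single-Maxwell models use their closed forms (the Maxwell creep
compliance $J(t) = (1+t/\tau_r)/G_0$).

## Known limitations

* The empirical $(\gamma,\zeta)$ form holds per-sample over the fitted decay
  window; strongly layered or anisotropic media violate the semi-infinite
  homogeneous Monte Carlo geometry.
* $\alpha$-clamping at 0 and 1 biases spectra whose true local slope exceeds
  1 (ballistic-like) or is slightly negative (noise around a plateau).
* The 15-point smoother limits how sharp a regime transition can appear
  (about half a decade at 30 points/decade); $\omega$-type parameters are
  grid-stable to one step, as the tests assert.
* Stiff samples whose plateau sits at $k^2\langle\Delta r^2\rangle \ll 0.1$
  pin $g_2-1$ near its ceiling, where the log inversion amplifies estimator
  noise; conditioning is best when the decay crosses the middle of the
  $[0.03, 1]$ window.
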