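---
title: "Models and methods behind speckleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speckleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleflow)
```

# What the package simulates

Diffuse correlation spectroscopy (DCS) and speckle contrast optical
spectroscopy (SCOS) both infer deep-tissue blood flow from the fluctuations of
multiply scattered coherent light. DCS samples the *temporal* intensity
autocorrelation $g_2(\tau)$ of one or a few speckle modes on a photon-counting
detector; SCOS samples the *spatial* blurring of a multi-speckle pattern
integrated over a camera exposure, quantified by the speckle contrast
$K = \sigma_I / \langle I \rangle$. speckleflow builds a complete simulated
measurement chain for both: light transport, instrument throughput,
measurement noise, blood-flow-index inversion, and the derived performance
metrics used to compare operating conditions (cerebral sensitivity,
coefficient of variation, contrast-to-noise ratio).

# Forward models

**Field correlation.** The measured intensity correlation is linked to the
field correlation by the Siegert relation $g_2 = 1 + \beta |g_1|^2$, with the
coherence parameter $\beta$ set by the number of detected speckle modes
(`siegert_g2()`). Two forward routes to $g_1$ are provided:

* `semi_infinite_g1()` — the analytic solution of the correlation diffusion
  equation for a homogeneous semi-infinite medium in reflectance geometry,
  with $K(\tau) = \sqrt{3\mu_a\mu_s' + 6 k^2 \mu_s'^2\,\mathrm{BFi}\,\tau}$,
  image sources at $r_1=\sqrt{\rho^2+\ell^{*2}}$ and
  $r_b=\sqrt{\rho^2+(\ell^*+2z_b)^2}$, and the extrapolated boundary
  $z_b = \tfrac{2}{3\mu_s'}(1+R_\mathrm{eff})/(1-R_\mathrm{eff})$. Scatterer
  motion is diffusive, $\langle\Delta r^2(\tau)\rangle = 6\,\mathrm{BFi}\,\tau$.
* `g1_from_histories()` — the pathlength-resolved discrete sum over detected
  photons, each weighted by $\exp(-\sum_i \mu_{a,i} L_{n,i})$ and dephased by
  $\exp(-\tfrac13 \sum_i k_i^2 Y_{n,i}\, 6\,\mathrm{BFi}_i\, \tau)$, where
  $L_{n,i}$ and $Y_{n,i}$ are the per-tissue partial pathlength and
  dimensionless momentum transfer of photon $n$.

*Wavenumber convention.* Published forms of these expressions are
inconsistent about whether the vacuum or in-medium wavenumber appears with
the momentum-transfer sum. We use the in-medium wavenumber
$k = 2\pi n/\lambda$ everywhere, per tissue in the history sum, which makes
the pathlength-integral and history-sum formulations mutually consistent.
The analytic and history routes agree to within Monte Carlo sampling error on
homogeneous slabs (this is a standing test), and the analytic route matches an
independent 50-digit transcription at $10^{-10}$.

**Speckle contrast.** The noise-free ("fundamental") squared contrast at
exposure $T_{exp}$ is the exposure-weighted integral
$K_f^2 = \tfrac{2\beta}{T_{exp}}\int_0^{T_{exp}} g_1^2(\tau)\,
(1-\tau/T_{exp})\,d\tau$ (`speckle_contrast_from_g1()`), and the measured
squared contrast adds shot, read and dark terms in quadrature:
$K^2 = K_f^2 + K_s^2 + K_r^2 + K_d^2$ with $K_s^2 = 1/\langle S\rangle$,
$K_r^2 = \sigma_r^2/\langle S\rangle^2$, $K_d^2 = S_d/\langle S\rangle^2$ in
photoelectron units (`shot_read_dark_contrast()`). Dark noise defaults to
zero: it only matters for exposures of tens of milliseconds, beyond the
operating range studied here.

# The synthetic transport model

`run_layered_mc()` is a dynamic light scattering Monte Carlo on planar layered
slabs (scalp / skull / CSF / brain presets via `slab_head_model()`, with
10/15/20 mm extracerebral depth). Design choices:

* **Similarity relation.** Transport uses isotropic scattering at the reduced
  scattering coefficient $\mu_s'$. This halves runtime relative to an
  anisotropic phase function and leaves the momentum-transfer formulation
  valid: for isotropic scattering $E[1-\cos\theta] = 1$ per event, so the
  expected momentum transfer per unit optical depth is exactly one (tested).
* **Analytic absorption.** No weight is lost in flight; the absorption weight
  $\exp(-\sum\mu_a L)$ is applied downstream from the recorded partial
  pathlengths. Photons are terminated when that implicit weight falls below
  $10^{-7}$; the history schema carries no per-photon weight column, so a
  roulette boost could not be represented — the cutoff bias
  ($<10^{-7}$ relative) is far below sampling error.
* **Detection.** Detectors are thin annuli centred on the pencil source
  (azimuthal symmetry makes an annulus statistically equivalent to a small
  fiber tip at that separation, with far better photon economy), with an
  optional numerical-aperture cut applied to the refracted exit angle. The
  tissue–air interface applies unpolarized Fresnel reflection.
* **CSF** is treated as an ordinary diffusing layer with its (very low)
  scattering coefficient; boundary marching handles its long steps exactly,
  so no step cap is needed.

What the generator emulates: layered extracerebral anatomy at controlled
depth, per-tissue dynamics, absolute diffuse reflectance for flux
calibration. What it does not: curved MRI-derived geometry, lateral
heterogeneity, vessel-scale structure, and the $10^9$-photon statistics of a
production run. Trend-level conclusions (how metrics move with separation,
depth, exposure, modes) transfer; absolute CNR values shift with geometry and
should not be read as head-model predictions.

`parametric_histories()` draws history rows from declared distributions — a
fast fixture for tests and a way to study the estimator in closed-form cases.
History tables round-trip through a self-describing tab-separated text format
(`write_history_table()` / `read_history_table()`).

# Noise models

**DCS.** `dcs_noise_sigma()` implements the analytic standard deviation of a
photon-counting correlogram at bin width $T$ and averaging time $t$, with a
count-rate-independent speckle term scaled by $\beta^2$ and shot terms scaled
by $1/\langle n\rangle$ and $1/\langle n\rangle^2$. It is validated against a
brute-force pipeline: `photon_timestamps()` generates doubly stochastic
Poisson arrivals riding on a simulated multi-mode speckle intensity (complex
AR(1) channels), with independent dark counts and a non-paralyzable detector
hold-off, and `multitau_autocorrelation()` reduces them to $g_2$. Two caveats
found in that validation and worth knowing:

* The analytic model assumes a *fixed* bin width. A multi-tau correlator
  coarsens bins at long lags and so shows much less variance there; the
  validation therefore runs the correlator with `coarsen = FALSE`.
* In the speckle-dominated (high count rate) regime the analytic speckle term
  is a leading-order approximation that *underestimates* the simulated noise
  by an amount growing with $\beta$: about 6% at $\beta = 0.25$, 26% at
  $\beta = 0.5$, and 39% at $\beta = 1$ in our 500-stream ensembles. In the
  shot-limited regime agreement is within a few percent at all $\beta$.
  Pipeline CoV predictions at high count rates are accordingly optimistic by
  up to tens of percent for few-mode detection; comparative trends are
  unaffected because all configurations share the model.

**SCOS.** `speckle_field_sequence()` synthesizes fully developed speckle in
the Fourier domain: independent circular-Gaussian amplitudes on a circular
aperture sized so the sensor carries $n_\mathrm{pix}/(s/p)^2$ speckle modes —
the same convention under which the minimum usable speckle-to-pixel ratio is
$\sqrt{n_\mathrm{pix}/n_\mathrm{modes}}$. Temporal evolution is an AR(1)
mixing of the aperture modes whose step coefficients follow the target
$g_1$ ratio; within an exposure the correlation to the exposure start
reproduces the target exactly (and exactly stationarily for exponential
targets), and separate exposures are independent. Fields are oversampled by
$\lceil 2/(s/p)\rceil$ so the speckle grain is always resolved before pixel
binning; unpolarized detection averages two independent polarization fields.
`measured_contrast_stats()` integrates substeps into exposures, applies
Poisson shot noise and Gaussian read noise at the configured photoelectrons
per pixel, and returns the per-frame contrast budget, the spread
$\sigma(K^2)$ of the shot/read-corrected contrast, the empirical $\beta(s/p)$
(cached per ratio by `speckle_beta()`), and the effective number of
independent observations $\mathrm{NIO} = 2\,\overline{K_f^2}^2 /
\mathrm{var}(K_f^2)$ — about $0.95\,n_\mathrm{pix}$ at $s/p = 0.4$,
reproducing the published saturation of parallel speckle averaging.

# Instruments and illumination

Detector, laser and fiber presets mirror three reference systems: an 850 nm
silicon SPAD DCS channel (QE 55%, 22 ns hold-off, dark rates 0–1500 cps), a
1064 nm SNSPD channel (QE 90%, 33 ns hold-off), and an 850 nm CMOS SCOS
camera (QE 20%, 2.5 e$^-$ read noise, 150 Hz, 2.5 Mpx). Skin-safe power per
spot comes from the ANSI Z136.1 CW skin exposure limit times the spot area;
the 1064 nm preset stores its nominal 100 mW configuration value while the
calculator returns 96.2 mW — presets take precedence when reproducing the
reference scenarios. Guided modes are counted exactly by LP-mode cutoffs
(Bessel zeros) for single/few-mode fibers and by $V^2/2$ per fiber for
bundles. Four delivery strategies are modeled (`illumination_plan()`): single
CW spot at the ANSI limit, multiple CW spots, pulse-width modulation at fixed
frame rate, and pulse-width modulation at reduced frame rate; for DCS the
pulsed mode runs the full laser power at duty cycle
$P_\mathrm{ANSI}/P_\mathrm{max}$ (the physically meaningful orientation of
that ratio — average power must stay at the skin limit). Absolute detected
flux is anchored at 10 kcps (850 nm) and 67.1 kcps (1064 nm) per mode per
ANSI-limited source at 25 mm, and scaled along separation by the simulated
diffuse reflectance curve.

For SCOS, each detected mode occupies $(s/p)^2$ pixels: above the minimum
ratio the bundle image overfills the sensor and modes (photons) are lost;
shrinking $s/p$ concentrates all modes onto the sensor and raises
photoelectrons per pixel as $1/(s/p)^2$. This allocation is what makes small
speckles win at photon-starved separations, and the package reproduces that
ordering.

# Inversion and performance metrics

Both inversions are bounded scalar minimizations on $\log_{10}\mathrm{BFi}$
over $[10^{-12}, 10^{-4}]\,\mathrm{cm^2/s}$, deterministic, with $\beta$ and
the homogeneous fitting optics held fixed (0.15/8.5 cm$^{-1}$ at 850 nm,
0.15/6.2 cm$^{-1}$ at 1064 nm, $n = 1.4$). `fit_bfi_from_g2()` does
unweighted least squares of the semi-infinite $g_2$ over the delay range
selected by `fit_range_cutoff()` (a fraction of the *amplitude* decay,
computed once on the noiseless curve so noise does not jitter the range;
defining the fraction on amplitude rather than delay is a package choice —
the alternative is one argument away). `fit_bfi_from_contrast()` matches the
modeled $K_f^2(T_{exp};\mathrm{BFi})$, a strictly decreasing map, so the
single-exposure inverse is unique; multi-exposure input is accepted. Fits
that rail against the search bounds are excluded and counted; ensembles with
more than 5% failures are flagged invalid.

The exposure integral is evaluated by adaptive quadrature after truncating
the domain where $g_1 < 10^{-7}$ — without the truncation a correlation that
decays orders of magnitude faster than the exposure defeats the adaptive
subdivision.

`evaluate_configuration()` chains everything for one operating point and
returns sensitivity $(\Delta\mathrm{BFi}/\mathrm{BFi})/(\Delta\mathrm{CBF}/
\mathrm{CBF})$ under a +20% brain-flow activation, the CoV of the fitted
ensemble at the output sample rate (working thresholds: sensitivity
$\geq 0.10$, CoV $\leq 0.1$ against typical physiological variability), and
their ratio CNR (target $\geq 1$). Noise realizations use common random
numbers across the baseline and activated states: sensitivity is a ratio of
ensemble means, and sharing draws cancels most of its sampling error while
leaving the CoV untouched. Ten-hertz sampling is accounted as averaging time
$t = \mathrm{duty}/f_\mathrm{sample}$ for DCS and
$\lfloor f_s/f_\mathrm{sample}\rfloor$ frames per sample for SCOS (one fit
per frame-averaged sample; per-frame fitting is the exposed alternative).
`sweep_performance()` drives the four standard studies (fit range / exposure,
delivery strategy, modal content and $s/p$, extracerebral thickness) over a
5–40 mm separation grid.

# Problem sizes and statistical stability

Slab runs of $10^6$ photons (seconds each) put $10^3$–$10^5$ photons on each
annulus and hold the history-vs-analytic discrepancy under 0.02 in $g_1$;
speckle-noise estimates use 24–32 pixel grids with 32 frames; noise-model
ensembles use 150–500 streams; fitted ensembles use 100–400 realizations.
One desk-scale caveat discovered this way: at the calibrated slab flux the
30 mm single-CW-source DCS channel at 10 Hz has CoV of 2–3 — the fitted
ensemble rails across the search bounds and the CNR *estimator* becomes
degenerate (its value flips with the RNG stream). Comparisons at that
separation (e.g. the dark-count penalty of single-mode vs few-mode fiber)
are therefore run at a 0.1 Hz sample rate where the estimator is regular and
seed-stable; the underlying mechanism — dark counts deflate the effective
$\beta$ and inflate $\langle n\rangle$ — does not depend on averaging time.

# Known limitations

Homodyne detection only; no interferometric or heterodyne variants. Detector
saturation is represented only as a hold-off rate cap (no correlation
distortion or camera clipping). Camera illumination is assumed uniform;
coupling losses enter only as a scalar per-mode throughput factor. No
afterpulsing, crosstalk, or fixed-pattern noise. Physiological fluctuations
are not modeled — the CoV is instrument noise only. Planar slabs stand in
for curved anatomy, so absolute metric values are geometry-specific even
though the operating trends are robust.
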