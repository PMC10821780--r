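# speckleflow

Simulated performance of diffuse optical cerebral blood flow monitors.

Diffuse correlation spectroscopy (DCS) and speckle contrast optical
spectroscopy (SCOS) both measure cerebral blood flow from the fluctuations of
multiply scattered coherent light — DCS through the temporal intensity
autocorrelation `g2(τ) = 1 + β|g1(τ)|²` of a few speckle modes on a
photon-counting detector, SCOS through the spatial speckle contrast
`K = σ_I/⟨I⟩` of a camera image integrated over an exposure, with
`Kf² = (2β/T_exp) ∫₀^T_exp g1²(τ)(1 − τ/T_exp) dτ`. Whether a planned system
can actually resolve a cerebral flow change depends on an interlocking set of
choices: source–detector separation, laser delivery strategy under skin-safety
limits, detector hardware, detected mode count or speckle-to-pixel ratio,
fitting range or exposure time. speckleflow is a simulation toolkit for
making those choices quantitatively, aimed at researchers designing or
comparing DCS/SCOS instruments.

The package provides:

* a layered-slab dynamic light scattering **Monte Carlo**
  (`run_layered_mc()`) producing per-photon, per-tissue partial pathlengths
  and momentum transfer, plus diffuse reflectance for absolute flux
  calibration;
* **forward models**: the semi-infinite correlation diffusion solution
  (`semi_infinite_g1()`), the pathlength-resolved history sum
  (`g1_from_histories()`), the Siegert relation and the exposure-integrated
  speckle contrast;
* **noise models**: the analytic correlation-noise formula
  (`dcs_noise_sigma()`), a photon timestamp generator with speckle-driven
  intensity, dark counts and detector dead time, a multi-tau software
  correlator, and a dynamic speckle simulator with shot/read noise for
  contrast statistics;
* **instrument models**: ANSI skin-limit power, LP-mode and bundle mode
  counting, saturation limits, four laser delivery strategies, and hardware
  presets for an 850 nm Si-SPAD DCS channel, a 1064 nm SNSPD DCS channel and
  an 850 nm CMOS SCOS camera;
* **inversion**: blood flow index (BFi, cm²/s) fits from noisy g2 curves and
  from squared speckle contrast;
* a **performance pipeline** (`evaluate_configuration()`,
  `sweep_performance()`) computing cerebral sensitivity, coefficient of
  variation at a chosen sample rate, and contrast-to-noise ratio
  (CNR = sensitivity/CoV) under a +20% brain-flow activation.

## Worked example

Simulate a head-like slab (15 mm scalp-to-brain depth), then evaluate an
850 nm single-mode-fiber DCS measurement at 20 mm separation, 10 Hz sampling:

```r
library(speckleflow)

props  <- head_tissue_properties(850)
optics <- setNames(lapply(seq_len(nrow(props)), function(i)
  optical_properties(props$mu_a[i], props$mu_s_prime[i])), props$tissue)

run <- run_layered_mc(slab_head_model(15), optics, 1e6, seed = 7)
run
#> Layered-slab MC: 1e+06 photons launched, 236813 detected, seed 7
#>   id sds_mm detected_count reflectance_per_mm2
#> 1  1      5         114956        1.135220e-03
#> 2  2     10          52598        1.555342e-04
#> 3  3     15          27574        2.963478e-05
#> 4  4     20          15968        6.885597e-06
#> 5  5     25          10295        1.745074e-06
#> 6  6     30           6922        5.233081e-07
#> 7  7     35           5014        1.784951e-07
#> 8  8     40           3486        6.374694e-08

cfg <- measurement_config(
  technique = "dcs", sds_mm = 20,
  detector  = detector_preset("dcs_850_sispad"),
  laser     = laser_preset("laser_850"),
  fiber     = fiber_preset("smf_780hp"),
  n_realizations = 100, seed = 1
)
metrics <- evaluate_configuration(cfg, run)
metrics
#> Performance: sensitivity 0.0791 [low], CoV 0.121 [high], CNR 0.654 [low]
```

Reading the output: the detected count rate at 20 mm is ~43 kcps, and fitting
100 noisy realizations of the correlation curve recovers 7.9% of the imposed
20% cerebral flow change (sensitivity 0.079), with an ensemble scatter of 12%
(CoV 0.121) — so at 10 Hz this channel sits just below the working thresholds
(sensitivity ≥ 0.10, CoV ≤ 0.1, CNR ≥ 1). Sweeps over separation, fitting
range, exposure time, delivery strategy, mode count and extracerebral depth
are driven by `sweep_performance()`; a command-line wrapper is installed at
`inst/cli/speckleflow`.

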