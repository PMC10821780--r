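# Example run configuration for the command-line interface.
seed: 7
technique: dcs
detector: dcs_850_sispad
laser: laser_850
fiber: smf_780hp
strategy: cw_single
sds_mm: [15, 20, 25]
fit_fraction: 1.0
sample_rate: 10
n_realizations: 100
geometry:
  depth_mm: 15
  n_photons: 1.0e+6
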