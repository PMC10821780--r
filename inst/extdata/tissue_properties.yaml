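# Per-tissue optical and flow properties of the four-layer head model at the
# two native wavelengths (mu in 1/cm, BFi in cm^2/s). The same values are
# returned by head_tissue_properties(); this file is the config-file form.
wavelength_850:
  scalp: {mu_a: 0.164, mu_s_prime: 7.4, bfi_baseline: 1.0e-8, bfi_perturbed: 1.0e-8}
  skull: {mu_a: 0.155, mu_s_prime: 8.1, bfi_baseline: 1.0e-10, bfi_perturbed: 1.0e-10}
  csf:   {mu_a: 0.017, mu_s_prime: 0.1, bfi_baseline: 1.0e-10, bfi_perturbed: 1.0e-10}
  brain: {mu_a: 0.170, mu_s_prime: 11.6, bfi_baseline: 6.0e-8, bfi_perturbed: 7.2e-8}
wavelength_1064:
  scalp: {mu_a: 0.11,  mu_s_prime: 5.3, bfi_baseline: 1.0e-8, bfi_perturbed: 1.0e-8}
  skull: {mu_a: 0.13,  mu_s_prime: 5.8, bfi_baseline: 1.0e-10, bfi_perturbed: 1.0e-10}
  csf:   {mu_a: 0.122, mu_s_prime: 0.07, bfi_baseline: 1.0e-10, bfi_perturbed: 1.0e-10}
  brain: {mu_a: 0.17,  mu_s_prime: 8.3, bfi_baseline: 6.0e-8, bfi_perturbed: 7.2e-8}
refractive_index: 1.4
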