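# Demonstration pipeline configuration: a compact resin-microsphere phantom
# imaged with the SPECT-like and PET-like simulators. Runs in well under a
# minute on one CPU.
seed: 11
phantom:
  liver_semiaxes_mm: [70, 50, 40]
  tumor_centers_mm: [30, 0, 0]
  tumor_radii_mm: 25
  true_TN: 3.0
  perfused_fraction: 0.62
  net_activity_GBq: 1.20
  lung_shunt_true: 0.05
  device: resin
  spacing_mm: [4, 4, 4]
density_g_per_mL: 1.03
lung_mass_kg: 1.0
spect:
  psf_fwhm_mm: 12
  counts_per_GBq: 1000000
  noise: poisson
pet:
  psf_fwhm_mm: 5
  counts_per_GBq: 1000000
  noise: poisson
planar:
  counts_per_GBq: 1000000
  noise: poisson
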