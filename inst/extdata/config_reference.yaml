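# Reference configuration for the diatomdose pipeline.
# Every key is optional; omitted keys keep the package defaults shown here.

seed: 1
primaries: 1.0e6        # analog decays per nuclide (dose-rate stage)
nano_primaries: 8000    # nucleus-aimed weighted emissions (nano stage)
n_nucleosomes: 30000    # cylindrical targets in the nucleus
genome_mbp: 27          # genome size used for damage normalisation
erica_threshold: 10     # screening dose rate, uGy/h

activities:             # reference activity concentrations
  c_rn: 1000            # Rn-222 in the water phase, Bq/L
  c_ra: 30              # Ra-226 in the dry sediment, Bq/g

geometry:               # concentric spheres, um
  r_nucleus: 0.5
  r_microorganism: 10
  frustule_thickness: 2 # used by the frustuled configurations

materials:
  sediment_density: 1.20               # g/cm^3
  sediment_mass_stopping_ratio: 0.77   # alpha mass stopping vs water
  silicate_mass_stopping_ratio: 0.90

ts:                     # nanoscale track-structure sampling
  mean_site_energy: 100 # eV per energy-transfer point (calibration knob)
  max_site_energy: 5000 # eV, truncation of the site-energy distribution
  electron_fraction: 0.40
  displacement_mean: 2  # nm, electron-site radial displacement scale
  step_nm: 50

damage:                 # DBSCAN strand-break scorer
  eps: 3.3              # nm
  min_ssb_for_dsb: 2
  s_point_prob: 0.08    # adopted sensitive-point probability
  ramp_min: 5           # eV
  ramp_max: 37.5        # eV

configurations:
  - water_column
  - dry_sediment
  - benthic_mixture
  - benthic_mixture_frustule
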