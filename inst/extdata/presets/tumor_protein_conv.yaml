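# As tumor_protein_noconv, but with functional lymphatics sustaining radial
# interstitial convection (fluid velocity at the capillary wall 0.5 um/s,
# a package default within the reported 0.1-2 um/s range).
# Measured/literature values: MW, Kd (DARPin Ec1 vs EpCAM), plasma half-life
# (laronidase), cell density, receptor density (EpCAM on MCF-7; 5.3e5 also
# reported), EpCAM internalization rate, target copy number.
# Transport coefficients, void fraction, geometry, escape fraction, cytosolic
# kinetics and half-lives are package defaults (see the methods vignette).
agent:
  molecular_weight_kda: 70
  kd_receptor_m: 6.8e-11
  kon_receptor_per_m_s: 1.0e+5
  plasma_half_life_h: 2.55
  cytosolic_half_life_h: 6
  mode: binder
  k_cat_per_min: 0
  kd_target_m: 3.0e-10
  kon_target_per_m_s: 1.0e+6
  escape_fraction: 0.012
tissue:
  capillary_radius_um: 8
  krogh_radius_um: 108
  void_fraction: 0.1
  vascular_permeability_cm_s: 7.0e-7
  interstitial_diffusivity_cm2_s: 1.0e-8
  reference_mw_kda: 70
  fluid_velocity_um_s: 0.5
  cell_density_per_ml: 2.9e+8
  receptors_per_cell: 5.4e+5
  k_internalize_per_min: 0.002
  receptor_steady_state: true
target:
  copies_per_cell: 1.0e+4
  cytosol_volume_per_cell_pl: 1
  target_half_life_h: 24
regimen:
  pattern: single
  peak_m: 1.0e-6
simulation:
  n_shells: 100
  t_end_h: 72
  dt_out_h: 0.25
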