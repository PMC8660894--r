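gwp100:
  ch4: 25.0
  n2o: 298.0
embodied_ef:
  n_fertilizer: 4.96
  p_fertilizer: 1.35
  k_fertilizer: 0.58
  seed: 0.9
  pesticide: 18.0
  manure: 0.01
embodied_energy:
  n_fertilizer: 65.0
  p_fertilizer: 9.0
  k_fertilizer: 6.8
  seed: 20.0
  pesticide: 300.0
  manure: 0.3
fuel_ef: 3.1
fuel_energy: 40.0
labor_energy: 2.0
grain_energy: 15.199999999999999
dm_fraction: 0.86
energy_dry_matter: yes
n_removal_dry_matter: no
ch4:
  table_label: IPCC-2019-refinement-style Tier 1 defaults
  ef_baseline: 1.19
  sf_water:
    continuously_flooded: 1.0
    single_drainage: 0.71
    multiple_drainage: 0.55
    rainfed_regular: 0.54
    rainfed_drought_prone: 0.16
    upland: 0.0
  sf_preseason:
    nonflooded_short: 1.0
    nonflooded_long: 0.89
    flooded_pre: 2.41
  cfoa:
    straw_short: 1.0
    straw_long: 0.19
    compost: 0.17
    farmyard_manure: 0.21
    green_manure: 0.45
  sfo_exponent: 0.59
n2o_direct_model:
  form: exponential
  params:
  - 0.54
  - 0.0063
indirect_n2o_fraction: 0.2
bnf_lowland: 30.0
bnf_upland_fraction: 0.1
grain_n_conc: 0.011
straw_grain_ratio: 1.0
straw_n_conc: 0.0065
straw_n_loss:
  retained: 0.0
  removed: 1.0
  burned: 0.8
surplus_strategy: aboveground_proxy
eiq_table:
  insectin_a: 32.0
  insectin_b: 45.0
  herbin_a: 20.0
  herbin_b: 26.0
  fungin_a: 38.0
  fungin_b: 48.0
excess_n_threshold: 75.0
ysnb_target: 8.0
closure_target: 0.75
large_gap_cutoff: 0.6
large_nbal_cutoff: 100.0
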