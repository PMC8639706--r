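# Example pipeline scenario: an anoxic-marine-zone station with a secondary
# chlorophyll maximum (SCM) and a secondary nitrite maximum (SNM).
# Fields mirror the arguments of pipeline_config() / profile_template().
seed: 1
do_ceiling: 18000
target_pct: 100
template:
  station: AMZ-EX1
  DO_surface: 200000      # nM (200 uM at the surface)
  DO_deep: 5              # nM in the anoxic core
  oxycline_depth: 60      # m
  oxycline_width: 10      # m
  scm_max: 1.5            # mg m^-3 secondary chlorophyll maximum
  scm_depth: 120
  snm_max: 2000           # nM nitrite in the SNM (> 1 uM: AMZ criterion)
  snm_depth: 170
  vmax_NO_max: 150        # nmol L^-1 day^-1 nitrite oxidation
  Km_NO: 100              # nM O2 (high affinity)
  vmax_het_surface: 2500  # nmol L^-1 day^-1 heterotrophic respiration
  Km_het: 1800            # nM O2 (lower affinity than the nitrite oxidizers)
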