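# Default configuration for noctura's end-to-end desk-scale run.
# Any field omitted from a user file keeps the value shown here.
thresholds:
  alpha_rhythm: 0.05      # Fisher g rhythmicity threshold
  alpha: 0.05             # significance level everywhere else
  period_min: 18          # chi-square periodogram search grid (hours)
  period_max: 30
  period_step: 0.1
sim:
  n_pop: 300              # males phenotyped per selection cycle
  n_selected: 25          # extreme males selected per cycle
  n_cycles: 10
  nd_mean: 0.75           # founder mean ND ratio
  Vp: 0.02                # phenotypic variance of the ND ratio
  total_activity_per_day: 1200
  masking_m: 0.6          # share of excess nocturnality that is light-driven
  tau_mean: 24.2          # free-running period (hours)
  tau_sd: 0.2
selection:
  h2_diurnal: 0.371
  h2_nocturnal: 0.084
  drift_reps: 100         # parametric-bootstrap replicates for Var(h2)
parent_offspring:
  h2: 0.14
  n_families: 105
  n_progeny: 4
masking:
  genotype_nd: {N: 1.2, C: 0.75, D: 0.4}
  n_per_genotype: 8
  ld_days: 3
  dd_days: 4
  bin_minutes: 30
qct:
  n_per_cell: 20
  sd: 0.15
  complemented_means: {D: 0.4, C: 0.7, N: 1.1}
  null_mean: 0.75
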