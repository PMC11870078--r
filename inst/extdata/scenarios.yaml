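# Preset simulation grid: three families x three dispersion levels.
# Means and SD levels are mL for VT and breaths/min for BF.
bf:
  parameter: bf
  rest_mean: 18
  end_mean: 39
  sd_levels: [2, 4, 6]
  trends: [flat, linear, exponential]
  sighs: false
  n_cycles: 300
  n_reps: 10000
vt:
  parameter: vt
  rest_mean: 790
  end_mean: 2130
  sd_levels: [60, 270, 500]
  trends: [flat, linear, logarithmic]
  sighs: false
  n_cycles: 300
  n_reps: 10000
vt_sighs:
  parameter: vt
  rest_mean: 790
  end_mean: 2130
  sd_levels: [60, 270, 500]
  trends: [flat, linear, logarithmic]
  sighs: true
  n_cycles: 300
  n_reps: 10000
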