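# Informative priors for the MCI-detection analysis
prevalence: [25.422, 281.851]
sensitivity:
  MoCA: [824.530, 146.329]
  MMSE: [269.497, 110.668]
  ADAS-cog: [35.209, 9.552]
specificity:
  MoCA: [440.462, 117.819]
  MMSE: [469.554, 192.381]
  ADAS-cog: [56.016, 11.479]
covariance:
  - tests: [MoCA, MMSE]
    lower: -1
    upper: 1
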