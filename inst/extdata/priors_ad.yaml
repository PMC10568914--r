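# Informative priors for the AD-detection analysis
prevalence: [2.819, 16.021]
sensitivity:
  MoCA: [270.154, 20.020]
  MMSE: [464.322, 50.770]
  ADAS-cog: [125.247, 13.288]
specificity:
  MoCA: [192.121, 22.472]
  MMSE: [514.797, 69.080]
  ADAS-cog: [113.235, 9.448]
covariance:
  - tests: [MoCA, MMSE]
    lower: -1
    upper: 1
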