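# Demonstration run configuration: a 50,000-person synthetic linked cohort
# evaluated for colorectal and lung cancer ascertainment at +/-3 and +/-12
# months.  Omitted sections fall back to package defaults; indicator
# definitions here override the shipped battery.
generator:
  n_persons: 50000
seed: 1
windows: [3, 12]
ppv_floor: 0.8
cancer_types: [colorectal, lung]
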