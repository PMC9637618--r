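n_per_sex:
  male: 450.0
  female: 450.0
true_partials:
  male:
  - - 0.0
    - 0.35
    - 0.35
    - 0.3
    - 0.35
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.3
  - - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - -0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.35
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  female:
  - - 0.0
    - 0.35
    - 0.35
    - 0.3
    - 0.35
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
  - - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.0
    - 0.35
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.35
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
margins:
  IL6:
    kind: zero_inflated_lognormal
    p_zero: 0.1
    meanlog: 0.3
    sdlog: 0.8
  IL8:
    kind: zero_inflated_lognormal
    p_zero: 0.05
    meanlog: 1.5
    sdlog: 0.6
  IL10:
    kind: zero_inflated_lognormal
    p_zero: 0.35
    meanlog: 0.2
    sdlog: 0.9
  IL12:
    kind: zero_inflated_lognormal
    p_zero: 0.25
    meanlog: 0.5
    sdlog: 0.9
  CRP:
    kind: zero_inflated_lognormal
    p_zero: 0.05
    meanlog: 0.8
    sdlog: 1.0
  depression:
    kind: count_binomialish
    size: 15.0
    prob: 0.12
  cognition:
    kind: gaussian
    mean: -0.5
    sd: 0.9
  education:
    kind: ordinal_cutpoints
    cutpoints:
    - -1.2
    - -0.4
    - 0.3
    - 1.0
    lower: 1.0
  alcohol:
    kind: ordinal_cutpoints
    cutpoints:
    - -0.8
    - -0.2
    - 0.3
    - 0.8
    - 1.3
    lower: 1.0
  cvd_risk:
    kind: gaussian
    mean: 25.0
    sd: 10.0
  apoe4:
    kind: bernoulli
    prob: 0.25
missing_rate:
  IL6: 0.05
  IL8: 0.05
  IL10: 0.05
  IL12: 0.05
  CRP: 0.05
  depression: 0.05
  cognition: 0.05
  education: 0.05
  alcohol: 0.05
  cvd_risk: 0.05
  apoe4: 0.05
attrition:
  intercept: -1.992430164690206
  age: 0.06
  depression: 0.12
  cognition: -0.35
wave2_shift:
  IL6: 0.0
  IL8: 0.0
  IL10: 0.0
  IL12: 0.0
  CRP: 0.0
  depression: 0.0
  cognition: 0.0
  education: 0.0
  alcohol: 0.0
  cvd_risk: 0.0
  apoe4: 0.0
autocorr: 0.7
frozen:
- education
- apoe4
seed: 2024
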