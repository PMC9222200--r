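{
  "description": "Published logistic cerebral-palsy risk coefficients for kinematic video features. Betas are per-unit log-odds (V_my in px/s, Q_* in percentage points). No intercept was published (null): linear-predictor ranking only. Standard errors are back-calculated from the published Wald statistics, se = |beta|/sqrt(W).",
  "multivariable": {
    "variables": ["V_my", "Q_med", "Q_sd", "Q_min"],
    "beta": [0.75, 0.08, 1.13, -0.89],
    "se": [0.312770, 0.043905, 0.507383, 0.467128],
    "wald": [5.75, 3.32, 4.96, 3.63]
  },
  "univariate": {
    "variables": ["V_my", "Q_med", "Q_sd", "Q_min"],
    "beta": [0.78, 0.07, 1.54, -1.079],
    "se": [0.309290, 0.039567, 0.474801, 0.440134],
    "wald": [6.36, 3.13, 10.52, 6.01]
  },
  "intercept": null
}
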