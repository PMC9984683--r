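# SYNTHETIC logistic coefficients for the IMPACT-style baseline.
# These are NOT the published IMPACT model coefficients; they exist so that
# examples and tests can exercise impact_score() without reproducing the
# external model. Replace with the published coefficient set for real use.
intercept: -2.0
coefficients:
  age: 0.035
  motor: -0.25
  pupils: 0.6
  hypoxia: 0.4
  hypotension: 0.5
  ct_class: 0.3
  tsah: 0.3
  epidural: -0.2
  glucose: 0.1
  hemoglobin: -0.2
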