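# Scenario grid for the simulation study: scenario 0 is the null model,
# scenarios 1-36 vary the percentage of causal rare variants (of all SNVs
# with MAF <= 0.03 in the gene), the effect-size constant c in
# beta_i = c * |log10(MAF_i)|, and the percentage of causal effects with
# positive sign.
scenarios:
  - {scenario: 0,  causal_percent: 0,  c: 0.0, positive_percent: 100}
  - {scenario: 1,  causal_percent: 5,  c: 0.6, positive_percent: 100}
  - {scenario: 2,  causal_percent: 5,  c: 0.3, positive_percent: 100}
  - {scenario: 3,  causal_percent: 5,  c: 0.2, positive_percent: 100}
  - {scenario: 4,  causal_percent: 10, c: 0.6, positive_percent: 100}
  - {scenario: 5,  causal_percent: 10, c: 0.3, positive_percent: 100}
  - {scenario: 6,  causal_percent: 10, c: 0.2, positive_percent: 100}
  - {scenario: 7,  causal_percent: 20, c: 0.6, positive_percent: 100}
  - {scenario: 8,  causal_percent: 20, c: 0.3, positive_percent: 100}
  - {scenario: 9,  causal_percent: 20, c: 0.2, positive_percent: 100}
  - {scenario: 10, causal_percent: 50, c: 0.6, positive_percent: 100}
  - {scenario: 11, causal_percent: 50, c: 0.3, positive_percent: 100}
  - {scenario: 12, causal_percent: 50, c: 0.2, positive_percent: 100}
  - {scenario: 13, causal_percent: 5,  c: 0.6, positive_percent: 80}
  - {scenario: 14, causal_percent: 5,  c: 0.3, positive_percent: 80}
  - {scenario: 15, causal_percent: 5,  c: 0.2, positive_percent: 80}
  - {scenario: 16, causal_percent: 10, c: 0.6, positive_percent: 80}
  - {scenario: 17, causal_percent: 10, c: 0.3, positive_percent: 80}
  - {scenario: 18, causal_percent: 10, c: 0.2, positive_percent: 80}
  - {scenario: 19, causal_percent: 20, c: 0.6, positive_percent: 80}
  - {scenario: 20, causal_percent: 20, c: 0.3, positive_percent: 80}
  - {scenario: 21, causal_percent: 20, c: 0.2, positive_percent: 80}
  - {scenario: 22, causal_percent: 50, c: 0.6, positive_percent: 80}
  - {scenario: 23, causal_percent: 50, c: 0.3, positive_percent: 80}
  - {scenario: 24, causal_percent: 50, c: 0.2, positive_percent: 80}
  - {scenario: 25, causal_percent: 5,  c: 0.6, positive_percent: 50}
  - {scenario: 26, causal_percent: 5,  c: 0.3, positive_percent: 50}
  - {scenario: 27, causal_percent: 5,  c: 0.2, positive_percent: 50}
  - {scenario: 28, causal_percent: 10, c: 0.6, positive_percent: 50}
  - {scenario: 29, causal_percent: 10, c: 0.3, positive_percent: 50}
  - {scenario: 30, causal_percent: 10, c: 0.2, positive_percent: 50}
  - {scenario: 31, causal_percent: 20, c: 0.6, positive_percent: 50}
  - {scenario: 32, causal_percent: 20, c: 0.3, positive_percent: 50}
  - {scenario: 33, causal_percent: 20, c: 0.2, positive_percent: 50}
  - {scenario: 34, causal_percent: 50, c: 0.6, positive_percent: 50}
  - {scenario: 35, causal_percent: 50, c: 0.3, positive_percent: 50}
  - {scenario: 36, causal_percent: 50, c: 0.2, positive_percent: 50}
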