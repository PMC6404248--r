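# Epistasis between the variable allele and a linked resistance locus:
# a alone is subcritical (support {0.9, 1.0}); rescue requires R.
phenotype: {mean: 0.95, variance: 0.0025}
memory: {p: 0.9}
demography: {N0: 10000, K: 20000, mu: 0.1, q: 0,
             density_dependent: false, max_time: 10000}
environment: {scenario: one_shift}
resistance: {enabled: true, beta_R: 2, mu_R: 1.0e-6}
entry_mode: random
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: p, values: [0.5, 0.75, 0.9, 0.95]}
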