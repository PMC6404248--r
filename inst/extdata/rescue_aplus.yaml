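# Rescue from recurrent mutation entering with the beneficial phenotype,
# single abrupt environmental shift, density-independent births.
phenotype: {mean: 0.95, variance: 0.09}
memory: {p: 0.75}
demography: {N0: 1000, K: 5000, mu: 1.0e-5, q: 0,
             density_dependent: false, max_time: 10000}
environment: {scenario: one_shift}
resistance: {enabled: false}
entry_mode: a_plus
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: p, values: [0, 0.25, 0.5, 0.75, 1]}
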