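# Rescue by a resistance mutation in periodically changing environments,
# for a population carrying one variable-allele copy; the comparison arm
# (wild type only) is produced by the epistasis driver.
phenotype: {mean: 1.5, variance: 0.16}
memory: {p: 0.85}
demography: {N0: 500, K: 5000, mu: 0, q: 1,
             density_dependent: true, max_time: 10000}
environment: {scenario: periodic, "n": 13, M: 1, initial: random}
resistance: {enabled: true, beta_R: 1.5, mu_R: 1.0e-5}
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: p, values: [0, 0.25, 0.5, 0.7, 0.85, 0.95, 1]}
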