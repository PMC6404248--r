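# Persistence as a function of phenotypic variance at fixed epoch length.
# Variance is capped at 0.25 here: with E(phi_a) = 1.5 and M = 1 a larger
# spread would put the upper phenotype beyond 2M, i.e. at a negative
# reflected birth rate.
phenotype: {mean: 1.5, variance: 0.16}
memory: {p: 0.85}
demography: {N0: 500, K: 10000, mu: 0, q: 1,
             density_dependent: true, max_time: 10000}
environment: {scenario: periodic, "n": 13, M: 1, initial: random}
resistance: {enabled: false}
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: variance, values: [0.01, 0.04, 0.09, 0.16, 0.25],
          objective: extinction_time}
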