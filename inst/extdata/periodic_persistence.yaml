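# Mean time to extinction in periodically alternating environments:
# a single variable-allele copy with a random phenotype, epochs of n
# lifespans, reflection midpoint M = 1 (so the wild type has birth rate
# 0.5 in its bad environment and 1.5 in its good one).
phenotype: {mean: 1.5, variance: 0.16}
memory: {p: 0.85}
demography: {N0: 500, K: 10000, mu: 0, q: 1,
             density_dependent: true, max_time: 10000}
environment: {scenario: periodic, "n": 13, M: 1, initial: random}
resistance: {enabled: false}
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: p, values: [0, 0.25, 0.5, 0.7, 0.85, 0.95, 1],
          objective: extinction_time}
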