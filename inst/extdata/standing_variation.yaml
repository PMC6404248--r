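# Rescue from standing variation: q copies of the variable allele, at
# epimutation-selection balance, present at the environmental shift.
# The number of standing copies is a free choice of the study design;
# q = 5 here.
phenotype: {mean: 0.95, variance: 0.09}
memory: {p: 0.75}
demography: {N0: 2500, K: 5000, mu: 0, q: 5,
             density_dependent: false, max_time: 10000}
environment: {scenario: one_shift}
resistance: {enabled: false}
init_phenotype: balance
run:
  replicates: 10000
  seed: 1
  sweep: {parameter: p, values: [0, 0.25, 0.5, 0.75, 1]}
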