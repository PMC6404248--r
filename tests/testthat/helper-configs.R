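# Shared study configurations, built in code from the packaged parameter
# sets so every test works from the same conditions.

cfg_new_mutation <- function(entry = c("a_plus", "a_minus"), p = 0.75,
                             variance = 0.09) {
  sim_config(phenotype_two_point(0.95, variance), p = p,
             N0 = 1000, K = 5000, mu = 1e-5,
             density_dependent = FALSE, scenario = "one_shift",
             entry_mode = match.arg(entry))
}

cfg_standing <- function(p = 0.75, q = 5) {
  sim_config(phenotype_two_point(0.95, 0.09), p = p,
             N0 = 2500, K = 5000, mu = 0, q = q,
             density_dependent = FALSE, scenario = "one_shift",
             init_phenotype = "balance")
}

cfg_periodic <- function(p = 0.85, variance = 0.16, n = 13,
                         max_time = 300) {
  sim_config(phenotype_two_point(1.5, variance), p = p,
             N0 = 500, K = 10000, mu = 0, q = 1,
             density_dependent = TRUE, max_time = max_time,
             scenario = "periodic", n = n, M = 1, initial_env = "random")
}

cfg_resistance <- function(p = 0.95, mu_a = 0.1) {
  sim_config(phenotype_two_point(0.95, 0.0025), p = p,
             N0 = 10000, K = 20000, mu = mu_a,
             density_dependent = FALSE, scenario = "one_shift",
             entry_mode = "random",
             resistance = TRUE, beta_R = 2, mu_R = 1e-6)
}

# single fixed-phenotype lineage: a linear birth-death process with birth
# rate b and death rate 1, "rescued" when it grows to K
cfg_linear_bd <- function(b, N0 = 1, K = 1e9) {
  sim_config(phenotype_two_point(b, 0), p = 1, N0 = N0, K = K,
             density_dependent = FALSE, scenario = "one_shift", phiA = b)
}

# independent oracle for the balance quadratic: numeric root in [0, 1]
balance_root_oracle <- function(lo, hi, u) {
  if (u == 0) return(1)
  g <- function(x) (lo - hi) * x^2 - (lo - hi + u * (lo + hi)) * x + lo * u
  stats::uniroot(g, c(0, 1), tol = 1e-14)$root
}
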