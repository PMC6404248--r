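test_that("balance frequency matches the quadratic's root in [0, 1]", {
  d <- phenotype_two_point(0.95, 0.09)
  # no epimutation: selection fixes the fitter phenotype
  expect_identical(equilibrium_fa_plus(d, memory_model(1)), 1)
  # full resampling of a symmetric two-point: every newborn is 50/50
  expect_equal(equilibrium_fa_plus(d, memory_model(0)), 0.5)
  # interior case against an independent root-finder
  expect_equal(equilibrium_fa_plus(d, memory_model(0.8)),
               balance_root_oracle(0.65, 1.25, 0.1), tolerance = 1e-10)
  expect_equal(equilibrium_fa_plus(d, memory_model(0.8)), 0.8161,
               tolerance = 1e-4)
  # degenerate distribution: balance undefined
  expect_error(equilibrium_fa_plus(phenotype_two_point(0.95, 0),
                                   memory_model(0.5)), "two-point")
})

test_that("effective birth rate interpolates between the mean and the top atom", {
  d <- phenotype_two_point(0.95, 0.09)
  expect_equal(effective_birth_rate(d, memory_model(1)), 1.25)
  expect_equal(effective_birth_rate(d, memory_model(0)), 0.95)
  expect_equal(effective_birth_rate(d, memory_model(0.8)), 1.1397,
               tolerance = 1e-4)
  # monotone nondecreasing in p; bounded by the support
  ps <- seq(0, 1, by = 0.05)
  sas <- vapply(ps, function(p) effective_birth_rate(d, memory_model(p)), 0)
  expect_true(all(diff(sas) >= -1e-12))
  expect_true(all(sas >= d$phi_minus - 1e-12 & sas <= d$phi_plus + 1e-12))
  # fa+ nonincreasing in u
  us <- seq(0, 0.5, by = 0.025)
  fs <- vapply(us, function(u)
    equilibrium_fa_plus(d, memory_model(1 - 2 * u)), 0)
  expect_true(all(diff(fs) <= 1e-12))
})

test_that("establishment probabilities recover branching-process limits", {
  expect_equal(establishment_prob(2), 0.5)
  expect_equal(establishment_prob(1), 0)
  expect_equal(establishment_prob(0.5), 0)
  expect_equal(establishment_prob(1.1397), 0.1226, tolerance = 1e-3)
  # quadrature form reduces to (b - 1)/b as K -> Inf
  expect_equal(establishment_prob_general(1.2), 1 / 6, tolerance = 1e-8)
  for (b in c(1.05, 1.2, 1.5, 2)) {
    expect_equal(establishment_prob_general(b),
                 establishment_prob(b), tolerance = 1e-8)
  }
  # a declining resident suppresses early establishment, monotonically in tau
  ps <- vapply(c(0, 5, 20, 200), function(tau)
    establishment_prob_general(1.2, tau, N0 = 1000, decline_rate = 0.05,
                               K = 5000), 0)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps < 1 / 6 + 1e-10))
  expect_equal(ps[4], 1 / 6, tolerance = 1e-3)
  expect_equal(establishment_prob_general(0.9, 0, 1000, 0.05, 5000), 0)
})

test_that("deterministic wild-type decline follows its closed form", {
  expect_equal(wildtype_decline(0, 1000, 0.95), 1000)
  expect_equal(wildtype_decline(20, 1000, 0.95, mu = 0), 1000 * exp(-1))
  # mu = 1: no A births contribute, pure death at rate 1
  expect_equal(wildtype_decline(3, 500, 0.95, mu = 1), 500 * exp(-3))
})

test_that("rescue with beneficial-phenotype entry matches its closed form", {
  d <- phenotype_two_point(0.95, 0.09)
  expect_equal(rescue_prob_aplus(d, memory_model(0.8), 1000, 0)$p_rescue, 0)
  r <- rescue_prob_aplus(d, memory_model(0.8), 1000, 1e-5)
  expect_equal(r$p_rescue, 0.0230, tolerance = 1e-3)
  # subcritical lineage: flagged, probability 0
  r0 <- rescue_prob_aplus(d, memory_model(0.1), 1000, 1e-5)
  expect_true(r0$subcritical)
  expect_identical(r0$p_rescue, 0)
  # p -> 1 is the maximum: sa -> phi_plus
  pmax_val <- rescue_prob_aplus(d, memory_model(1), 1000, 1e-5)$p_rescue
  r_lim <- 1 - (1 - 1e-5) * 0.95
  expect_equal(pmax_val,
               1 - exp(-1e-5 * 1000 * 0.95 * (0.25 / 1.25) / r_lim),
               tolerance = 1e-12)
  ps <- seq(0, 1, by = 0.05)
  vals <- vapply(ps, function(p)
    rescue_prob_aplus(d, memory_model(p), 1000, 1e-5)$p_rescue, 0)
  expect_true(all(diff(vals) >= 0))
  expect_lte(max(vals), pmax_val)
  # monotone in the phenotypic variance as well
  vs <- vapply(c(0.01, 0.04, 0.09, 0.16), function(v)
    rescue_prob_aplus(phenotype_two_point(0.95, v), memory_model(0.8),
                      1000, 1e-5)$p_rescue, 0)
  expect_true(all(diff(vs) > 0))
})

test_that("rescue with deleterious-phenotype entry vanishes at both memory extremes", {
  d <- phenotype_two_point(0.95, 0.09)
  m8 <- memory_model(0.8)
  expect_equal(establishment_prob_aminus(d, m8), 0.0190, tolerance = 1e-3)
  expect_equal(rescue_prob_aminus(d, m8, 1000, 1e-5)$p_rescue, 0.00361,
               tolerance = 5e-3)
  # u = 0: the lineage can never produce the beneficial phenotype
  expect_identical(establishment_prob_aminus(d, memory_model(1)), 0)
  expect_identical(rescue_prob_aminus(d, memory_model(1), 1000,
                                      1e-5)$p_rescue, 0)
  # small p: effectively subcritical lineage
  expect_identical(rescue_prob_aminus(d, memory_model(0), 1000,
                                      1e-5)$p_rescue, 0)
  # interior maximum in p
  opt <- optimal_memory_aminus(d, 1000, 1e-5)
  expect_gt(opt$p_star, 0.05)
  expect_lt(opt$p_star, 0.95)
  expect_gt(opt$p_rescue,
            rescue_prob_aminus(d, memory_model(0.05), 1000, 1e-5)$p_rescue)
  expect_gt(opt$p_rescue,
            rescue_prob_aminus(d, memory_model(0.95), 1000, 1e-5)$p_rescue)
})

test_that("standing-variation rescue follows its closed form and is monotone in q", {
  d <- phenotype_two_point(0.95, 0.09)
  expect_identical(rescue_prob_standing(d, memory_model(0.8), 0)$p_rescue, 0)
  # q = 1, p = 1: fa+ = 1, sa = 1.25, only the direct establishment term
  expect_equal(rescue_prob_standing(d, memory_model(1), 1)$p_rescue,
               1 - exp(-0.2), tolerance = 1e-12)
  v1 <- rescue_prob_standing(d, memory_model(0.8), 1)$p_rescue
  v10 <- rescue_prob_standing(d, memory_model(0.8), 10)$p_rescue
  expect_gt(v10, v1)
  # subcritical clamp
  expect_identical(rescue_prob_standing(d, memory_model(0.1), 10)$p_rescue, 0)
})

test_that("all analytic probabilities stay in [0, 1] over random parameter draws", {
  set.seed(97)
  for (i in 1:200) {
    # E < 1 keeps the low-phenotype lineage declining, the regime in which
    # the deleterious-entry formulas are defined
    E <- runif(1, 0.3, 0.99)
    v <- runif(1, 0, (0.95 * E)^2)
    d <- phenotype_two_point(E, v)
    if (d$sd == 0) next
    mem <- memory_model(runif(1))
    f <- equilibrium_fa_plus(d, mem)
    expect_true(f >= 0 && f <= 1)
    sa <- effective_birth_rate(d, mem)
    expect_true(sa >= d$phi_minus - 1e-12 && sa <= d$phi_plus + 1e-12)
    mu <- 10^runif(1, -7, -2)
    phiA <- runif(1, 0.5, 0.99)
    N0 <- sample(10:5000, 1)
    for (val in c(rescue_prob_aplus(d, mem, N0, mu, phiA)$p_rescue,
                  rescue_prob_aminus(d, mem, N0, mu, phiA)$p_rescue,
                  rescue_prob_standing(d, mem, sample(0:50, 1))$p_rescue)) {
      expect_true(val >= 0 && val <= 1)
    }
  }
})

test_that("quadrature and closed-form routes agree", {
  d <- phenotype_two_point(0.95, 0.09)
  m <- memory_model(0.8)
  a_cf <- rescue_prob_aplus(d, m, 1000, 1e-5)
  a_q <- rescue_prob_aplus(d, m, 1000, 1e-5, method = "quadrature")
  expect_equal(a_q$p_rescue, a_cf$p_rescue, tolerance = 1e-8)
  b_cf <- rescue_prob_aminus(d, m, 1000, 1e-5)
  b_q <- rescue_prob_aminus(d, m, 1000, 1e-5, method = "quadrature")
  expect_equal(b_q$p_rescue, b_cf$p_rescue, tolerance = 1e-8)
  s_cf <- rescue_prob_standing(d, m, 5)
  s_q <- rescue_prob_standing(d, m, 5, method = "quadrature")
  expect_equal(s_q$p_rescue, s_cf$p_rescue, tolerance = 1e-8)
})

test_that("the analytic summary table is deterministic and internally consistent", {
  cfg <- cfg_new_mutation("a_plus")
  tab <- analytic_rescue_table(cfg, p_grid = seq(0, 1, by = 0.25))
  tab2 <- analytic_rescue_table(cfg, p_grid = seq(0, 1, by = 0.25))
  expect_identical(tab, tab2)
  expect_equal(tab$u, (1 - tab$p) / 2)
  expect_equal(tab$sa,
               0.65 * (1 - tab$fa_plus) + 1.25 * tab$fa_plus)
  expect_true(all(tab$p_rescue_aplus >= tab$p_rescue_aminus - 1e-12))
})
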