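#' Full simulation configuration
#'
#' Assembles and validates every parameter of the birth-death model: the
#' phenotype distribution of the variable allele `a`, the phenotypic memory
#' `p`, demography, the environmental scenario, and the optional linked
#' resistance locus. The wild-type birth rate `phiA` defaults to the
#' equal-mean constraint for the chosen scenario: `E(phi_a)` after a single
#' environmental shift, and `2M - E(phi_a)` in periodic environments (so
#' that each allele's mean fitness in its preferred environment equals the
#' other's in its unpreferred one). Supplying a `phiA` that violates the
#' constraint is allowed (with a warning) for off-constraint exploration.
#'
#' @param phenotype a [phenotype_distribution()] (or constructor output).
#' @param p phenotypic memory in `[0, 1]`.
#' @param N0 initial population size.
#' @param K carrying capacity (also the rescue threshold; see
#'   `rescue_threshold`).
#' @param mu per-birth mutation probability from `A` to `a`.
#' @param q number of `a` alleles present at time 0 (standing variation;
#'   in periodic scenarios conventionally 1, a single introduced copy).
#' @param density_dependent logical; multiply birth rates by
#'   `max(0, 1 - N/K)`?
#' @param max_time simulation horizon in expected lifespans; replicates
#'   still alive at `max_time` are censored.
#' @param scenario `"one_shift"` (environment constant after the shift at
#'   time 0) or `"periodic"` (alternating every `n` time units).
#' @param n epoch duration for the periodic scenario.
#' @param M reflection midpoint for the periodic scenario.
#' @param initial_env initial environment for the periodic scenario:
#'   `"random"`, `"E1"` or `"E2"`.
#' @param entry_mode phenotype of a de novo `a` mutant: `"a_plus"` (highest
#'   atom), `"a_minus"` (lowest atom) or `"random"` (drawn from the
#'   phenotype distribution).
#' @param init_phenotype phenotypes of the `q` standing `a` copies:
#'   `"balance"` (each is the high atom with the epimutation-selection
#'   balance probability; two-point only) or `"random"` (drawn from the
#'   distribution). Defaults to `"balance"` for one-shift standing
#'   variation and `"random"` otherwise.
#' @param resistance logical; enable the linked resistance locus?
#' @param beta_R birth rate of resistance carriers (needs `beta_R > 1` for
#'   rescue through `R` to be possible).
#' @param mu_R per-birth mutation probability to `R` (conventionally
#'   smaller than `mu`).
#' @param phiA optional wild-type birth rate override.
#' @param rescue_threshold population size that counts as rescue. Defaults
#'   to `K` (density-independent) or `ceiling(0.99 * K)` (density-dependent,
#'   where holding exactly `K` is a measure-zero excursion); set to `Inf`
#'   to disable rescue detection in persistence (extinction-time) studies.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(phenotype,
                       p,
                       N0,
                       K,
                       mu = 0,
                       q = 0,
                       density_dependent = NULL,
                       max_time = 1e4,
                       scenario = c("one_shift", "periodic"),
                       n = NULL,
                       M = 1,
                       initial_env = "random",
                       entry_mode = c("random", "a_plus", "a_minus"),
                       init_phenotype = NULL,
                       resistance = FALSE,
                       beta_R = 2,
                       mu_R = 0,
                       phiA = NULL,
                       rescue_threshold = NULL) {
  scenario <- match.arg(scenario)
  entry_mode <- match.arg(entry_mode)
  if (!inherits(phenotype, "phenotype_dist"))
    stop("'phenotype' must be a phenotype_dist object")
  mem <- memory_model(p)

  if (is.null(density_dependent))
    density_dependent <- (scenario == "periodic")
  if (scenario == "periodic") {
    if (is.null(n)) stop("periodic scenario requires an epoch length 'n'")
    schedule <- environment_schedule(n, M, initial_env)
  } else {
    schedule <- NULL
  }

  if (is.null(phiA))
    phiA <- if (scenario == "one_shift") phenotype$mean else 2 * M - phenotype$mean
  # equal-mean constraint: warn, don't fail, so off-constraint regimes stay
  # reachable; the packaged replication configs satisfy it by construction
  target <- if (scenario == "one_shift") phenotype$mean else 2 * M - phenotype$mean
  if (abs(phiA - target) > 1e-8)
    warning(sprintf(
      "equal-mean constraint violated: phiA = %g but the scenario implies %g",
      phiA, target))
  if (phiA < 0) stop("'phiA' must be a nonnegative birth rate")
  if (scenario == "periodic" && any(2 * M - phenotype$support < -1e-12))
    warning("some phenotypes exceed 2M; their reflected birth rate is clamped at 0")

  if (!is.numeric(N0) || N0 < 1) stop("'N0' must be at least 1")
  if (!is.numeric(K) || (is.finite(K) && K < N0))
    stop("need 0 < N0 <= K")
  if (mu < 0 || mu > 1) stop("'mu' must be a probability")
  if (q < 0 || q > N0) stop("need 0 <= q <= N0")
  if (isTRUE(resistance)) {
    if (mu_R < 0 || mu_R > 1) stop("'mu_R' must be a probability")
    if (mu > 0 && mu_R > mu)
      warning("mu_R > mu: the resistance mutation is conventionally rarer ",
              "than mutation at the A/a locus")
    if (beta_R <= 1)
      warning("beta_R <= 1: the resistance allele is not supercritical, ",
              "rescue through R is impossible")
  }
  if (max_time <= 0) stop("'max_time' must be positive")

  if (is.null(init_phenotype))
    init_phenotype <- if (scenario == "one_shift" && q > 0 &&
                          length(phenotype$support) == 2L) "balance" else "random"
  init_phenotype <- match.arg(init_phenotype, c("balance", "random"))
  if (init_phenotype == "balance" && length(phenotype$support) != 2L)
    stop("'balance' initial phenotypes are defined for two-point ",
         "distributions only")

  if (is.null(rescue_threshold))
    rescue_threshold <- if (density_dependent) ceiling(0.99 * K) else K

  structure(list(phenotype = phenotype, memory = mem,
                 N0 = as.integer(N0), K = K, mu = mu, q = as.integer(q),
                 density_dependent = isTRUE(density_dependent),
                 max_time = max_time,
                 scenario = scenario, schedule = schedule,
                 entry_mode = entry_mode, init_phenotype = init_phenotype,
                 resistance = isTRUE(resistance),
                 beta_R = beta_R, mu_R = if (isTRUE(resistance)) mu_R else 0,
                 phiA = phiA, rescue_threshold = rescue_threshold),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (", x$scenario, ")\n", sep = "")
  cat(sprintf("  phiA = %g; a: E = %g, Var = %g, %d atoms; p = %g (u = %g)\n",
              x$phiA, x$phenotype$mean, x$phenotype$variance,
              length(x$phenotype$support), x$memory$p, x$memory$u))
  cat(sprintf("  N0 = %d, K = %g, mu = %g, q = %d, density_dependent = %s\n",
              x$N0, x$K, x$mu, x$q, x$density_dependent))
  if (x$scenario == "periodic")
    cat(sprintf("  epochs of n = %g, M = %g, initial env %s\n",
                x$schedule$n, x$schedule$M, x$schedule$initial))
  if (x$resistance)
    cat(sprintf("  resistance locus: beta_R = %g, mu_R = %g\n",
                x$beta_R, x$mu_R))
  cat(sprintf("  entry_mode = %s, rescue threshold = %g, max_time = %g\n",
              x$entry_mode, x$rescue_threshold, x$max_time))
  invisible(x)
}

#' Read a simulation configuration from a YAML (or JSON) file
#'
#' The file mirrors the arguments of [sim_config()], grouped in sections:
#' `phenotype` (`mean` + `variance`, or `k`/`mode`/`scale`, or explicit
#' `support`/`weights`), `memory` (`p`), `demography` (`N0`, `K`, `mu`, `q`,
#' `density_dependent`, `max_time`), `environment` (`scenario`, `n`, `M`,
#' `initial`), `resistance` (`enabled`, `beta_R`, `mu_R`), optional
#' `entry_mode`, and `run` (`replicates`, `seed`, and an optional `sweep`
#' block with `parameter` / `values` used by the command-line driver).
#'
#' @param path path to the configuration file.
#' @return A `sim_config`; the `run` section, if present, is attached as
#'   attribute `"run"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (sec in c("phenotype", "memory", "demography"))
    if (is.null(cfg[[sec]])) stop("config is missing the '", sec, "' section")
  ph <- cfg$phenotype
  dist <- if (!is.null(ph$support)) {
    phenotype_distribution(unlist(ph$support), unlist(ph$weights))
  } else if (!is.null(ph$k)) {
    phenotype_k_point(ph$mean, ph$k, ph$mode %||% "fixed_variance", ph$scale)
  } else {
    phenotype_two_point(ph$mean, ph$variance)
  }
  env <- cfg$environment %||% list()
  res <- cfg$resistance %||% list()
  dem <- cfg$demography
  conf <- sim_config(
    phenotype = dist,
    p = cfg$memory$p,
    N0 = dem$N0, K = dem$K %||% Inf, mu = dem$mu %||% 0, q = dem$q %||% 0,
    density_dependent = dem$density_dependent,
    max_time = dem$max_time %||% 1e4,
    scenario = env$scenario %||% "one_shift",
    # YAML 1.1 reads an unquoted key `n` as the boolean FALSE; accept both
    # spellings as well as the unambiguous alias `epoch`
    n = env$n %||% env[["FALSE"]] %||% env$epoch,
    M = env$M %||% 1, initial_env = env$initial %||% "random",
    entry_mode = cfg$entry_mode %||% "random",
    init_phenotype = cfg$init_phenotype,
    resistance = isTRUE(res$enabled),
    beta_R = res$beta_R %||% 2, mu_R = res$mu_R %||% 0,
    phiA = dem$phiA,
    rescue_threshold = dem$rescue_threshold)
  attr(conf, "run") <- cfg$run
  conf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Update one model parameter of a configuration
#'
#' Convenience setter used by the sweep drivers: rebuilds the configuration
#' with one parameter changed, recomputing derived quantities (the implied
#' `phiA`, the epimutation rate, the two-point support for a new variance).
#'
#' @param config a [sim_config()].
#' @param name one of `"p"`, `"variance"`, `"mean"`, `"mu"`, `"mu_R"`,
#'   `"beta_R"`, `"q"`, `"n"`, `"N0"`, `"K"`, `"max_time"`, `"entry_mode"`.
#' @param value the new value.
#' @return A new `sim_config`.
#' @export
set_param <- function(config, name, value) {
  stopifnot(inherits(config, "sim_config"))
  dist <- config$phenotype
  p <- config$memory$p
  args <- list(
    N0 = config$N0, K = config$K, mu = config$mu, q = config$q,
    density_dependent = config$density_dependent,
    max_time = config$max_time, scenario = config$scenario,
    n = if (!is.null(config$schedule)) config$schedule$n else NULL,
    M = if (!is.null(config$schedule)) config$schedule$M else 1,
    initial_env = if (!is.null(config$schedule)) config$schedule$initial
                  else "random",
    entry_mode = config$entry_mode, init_phenotype = config$init_phenotype,
    resistance = config$resistance, beta_R = config$beta_R,
    mu_R = config$mu_R,
    rescue_threshold = if (is.infinite(config$rescue_threshold)) Inf else NULL)
  k <- length(dist$support)
  switch(name,
    p = { p <- value },
    variance = {
      dist <- if (k == 2L || k == 1L) phenotype_two_point(dist$mean, value)
              else phenotype_k_point(dist$mean, k, "fixed_variance", value)
    },
    mean = {
      dist <- if (k == 2L || k == 1L) phenotype_two_point(value, dist$variance)
              else phenotype_k_point(value, k, "fixed_variance", dist$variance)
    },
    mu = { args$mu <- value },
    mu_R = { args$mu_R <- value },
    beta_R = { args$beta_R <- value },
    q = { args$q <- value },
    n = { args$n <- value },
    N0 = { args$N0 <- value },
    K = { args$K <- value },
    max_time = { args$max_time <- value },
    entry_mode = { args$entry_mode <- value },
    stop("unknown sweep parameter: ", name))
  do.call(sim_config, c(list(phenotype = dist, p = p), args))
}
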