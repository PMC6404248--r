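#' Run an ensemble of replicate simulations
#'
#' Exact continuous-time (Gillespie) simulation of the full birth-death
#' model described by a [sim_config()]: density-(in)dependent births,
#' unit death rates, mutation coupled to birth, phenotype inheritance with
#' memory `p`, deterministic environment switches, and the optional linked
#' resistance locus. Each replicate runs until extinction (`N = 0`), rescue
#' (`N >= rescue_threshold`, checked after every birth), or censoring at
#' `max_time`.
#'
#' @param config a [sim_config()].
#' @param replicates number of independent replicates.
#' @param seed integer seed; the whole ensemble is reproducible
#'   bit-identically from (`config`, `seed`).
#' @param trajectory_dt if positive, record the per-class composition on a
#'   regular time grid with this spacing (intended for small ensembles).
#' @return A data.frame with one row per replicate: `fate` (factor:
#'   `extinct` / `rescued` / `censored`), `time` (the fate time, or
#'   `max_time` if censored), `final_N`, `first_R_time` (NA if no
#'   resistance mutant was ever born). If `trajectory_dt > 0` the sampled
#'   trajectories are attached as attribute `"trajectory"` (columns: `rep`,
#'   `time`, `env`, `N`, one column per class).
#' @export
run_ensemble <- function(config, replicates, seed, trajectory_dt = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (replicates < 1) stop("'replicates' must be at least 1")
  set.seed(as.integer(seed))
  dist <- config$phenotype
  fa_init <- if (config$q > 0 && config$init_phenotype == "balance" &&
                 length(dist$support) == 2L && dist$sd > 0)
    equilibrium_fa_plus(dist, config$memory) else -1
  periodic <- config$scenario == "periodic"
  init_env <- if (!periodic) 0L else switch(config$schedule$initial,
                                            E1 = 0L, E2 = 1L, random = -1L)
  entry <- switch(config$entry_mode, a_plus = 0L, a_minus = 1L, random = 2L)
  res <- sim_ensemble_cpp(
    n_rep = as.integer(replicates),
    phiA = config$phiA,
    support = dist$support, weights = dist$weights,
    p_mem = config$memory$p,
    mu = config$mu, mu_R = config$mu_R, beta_R = config$beta_R,
    resistance = config$resistance,
    N0 = config$N0, K = as.double(config$K), q = config$q,
    fa_plus_init = fa_init,
    density_dependent = config$density_dependent,
    max_time = config$max_time,
    periodic = periodic,
    epoch = if (periodic) config$schedule$n else 0,
    M = if (periodic) config$schedule$M else 1,
    init_env = init_env,
    entry_mode = entry,
    rescue_threshold = config$rescue_threshold,
    traj_dt = trajectory_dt)
  out <- res$outcomes
  out$fate <- factor(c("extinct", "rescued", "censored")[out$fate + 1L],
                     levels = c("extinct", "rescued", "censored"))
  if (trajectory_dt > 0) {
    traj <- as.data.frame(res$trajectory)
    names(traj) <- c("rep", "time", "env", "N", "A",
                     paste0("a_", seq_along(dist$support)), "R")
    attr(out, "trajectory") <- traj
  }
  out
}

#' Run a single replicate
#'
#' @inheritParams run_ensemble
#' @return A one-row data.frame as in [run_ensemble()] (with the optional
#'   trajectory attribute).
#' @export
run_replicate <- function(config, seed, trajectory_dt = 0) {
  run_ensemble(config, 1L, seed, trajectory_dt)
}

#' Offspring phenotype under partial heritability
#'
#' With probability `p` the offspring keeps the parent's phenotype; with
#' probability `1 - p` it redraws independently from the phenotype
#' distribution (the redraw may coincide with the parental value, which is
#' why the net switching rate of a symmetric two-point distribution is
#' `u = (1 - p)/2`, not `1 - p`).
#'
#' @param parent_phenotype phenotype of the reproducing `a` parent.
#' @param dist a [phenotype_distribution()].
#' @param mem a [memory_model()].
#' @param n number of independent offspring to draw.
#' @return Numeric vector of `n` offspring phenotypes.
#' @export
draw_offspring_phenotype <- function(parent_phenotype, dist, mem, n = 1) {
  keep <- stats::runif(n) < mem$p
  redraw <- dist$support[sample.int(length(dist$support), n, replace = TRUE,
                                    prob = dist$weights)]
  ifelse(keep, parent_phenotype, redraw)
}

#' Offspring genotype at birth
#'
#' Mutation is coupled to birth events: an `A` parent's offspring is `a`
#' with probability `mu`; when the resistance locus is enabled, any `A` or
#' `a` parent's offspring is `R` with probability `mu_R` (`R` breeds true
#' and masks the A/a locus).
#'
#' @param parent_genotype `"A"`, `"a"` or `"R"`.
#' @param config a [sim_config()].
#' @param n number of independent offspring.
#' @return Character vector of offspring genotypes.
#' @export
mutate_at_birth <- function(parent_genotype, config, n = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (parent_genotype == "R") return(rep("R", n))
  out <- rep(parent_genotype, n)
  if (config$resistance && config$mu_R > 0)
    out[stats::runif(n) < config$mu_R] <- "R"
  if (parent_genotype == "A" && config$mu > 0) {
    still_A <- out == "A"
    out[still_A & stats::runif(n) < config$mu] <- "a"
  }
  out
}

#' Reference single-replicate simulator in plain R
#'
#' A direct, unoptimised transcription of the event loop, maintaining the
#' total birth-rate weight both incrementally and by per-event
#' recomputation. Used in the test-suite as an independent reference for
#' the compiled core on small problems; impractically slow for production
#' ensembles.
#'
#' @inheritParams run_ensemble
#' @param record logical; keep the full event-time composition history?
#' @return A list with `fate`, `time`, `final_N`, `max_rate_drift` (largest
#'   absolute discrepancy between the incremental and recomputed total
#'   rate), and, if `record`, a data.frame `history` of the composition
#'   after every event.
#' @export
run_replicate_r <- function(config, seed, record = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  dist <- config$phenotype
  k <- length(dist$support)
  periodic <- config$scenario == "periodic"
  M <- if (periodic) config$schedule$M else 1
  base_for <- function(env) {
    b <- c(env_map(config$phiA, env, M),
           env_map(dist$support, env, M),
           config$beta_R)
    pmax(b, 0)
  }
  env <- if (!periodic) "E1" else {
    init <- config$schedule$initial
    if (init == "random") sample(c("E1", "E2"), 1) else init
  }
  cnt <- c(config$N0 - config$q, rep(0, k), 0)
  if (config$q > 0) {
    fa <- if (config$init_phenotype == "balance")
      equilibrium_fa_plus(dist, config$memory) else NA
    for (i in seq_len(config$q)) {
      j <- if (!is.na(fa)) {
        if (stats::runif(1) < fa) which.max(dist$support)
        else which.min(dist$support)
      } else sample(k, 1, prob = dist$weights)
      cnt[j + 1] <- cnt[j + 1] + 1
    }
  }
  base <- base_for(env)
  S <- sum(cnt * base)
  N <- sum(cnt)
  t <- 0
  t_switch <- if (periodic) config$schedule$n else Inf
  max_drift <- 0
  hist <- if (record) list(c(time = t, env = env == "E2", cnt)) else NULL
  fate <- NA_character_
  idx_top <- which.max(dist$support) + 1
  idx_bot <- which.min(dist$support) + 1
  repeat {
    max_drift <- max(max_drift, abs(S - sum(cnt * base)))
    dens <- if (config$density_dependent) max(0, 1 - N / config$K) else 1
    totB <- dens * S
    tot <- totB + N
    te <- t + stats::rexp(1, tot)
    if (te >= t_switch && t_switch <= config$max_time) {
      t <- t_switch
      t_switch <- t_switch + config$schedule$n
      env <- if (env == "E1") "E2" else "E1"
      base <- base_for(env)
      S <- sum(cnt * base)
      next
    }
    if (te > config$max_time) { t <- config$max_time; fate <- "censored"; break }
    t <- te
    if (stats::runif(1) * tot < totB) {
      c_par <- sample(k + 2, 1, prob = cnt * base)
      off <- if (c_par == k + 2) k + 2
      else if (config$resistance && config$mu_R > 0 &&
               stats::runif(1) < config$mu_R) k + 2
      else if (c_par == 1) {
        if (config$mu > 0 && stats::runif(1) < config$mu) {
          switch(config$entry_mode,
                 a_plus = idx_top, a_minus = idx_bot,
                 random = sample(k, 1, prob = dist$weights) + 1)
        } else 1
      } else {
        if (stats::runif(1) < config$memory$p) c_par
        else sample(k, 1, prob = dist$weights) + 1
      }
      cnt[off] <- cnt[off] + 1
      N <- N + 1
      S <- S + base[off]
      if (N >= config$rescue_threshold) { fate <- "rescued"; break }
    } else {
      c_die <- sample(k + 2, 1, prob = cnt)
      cnt[c_die] <- cnt[c_die] - 1
      N <- N - 1
      S <- S - base[c_die]
      if (N <= 0) { fate <- "extinct"; break }
    }
    if (record) hist[[length(hist) + 1]] <- c(time = t, env = env == "E2", cnt)
  }
  out <- list(fate = fate, time = t, final_N = N, max_rate_drift = max_drift)
  if (record) {
    h <- as.data.frame(do.call(rbind, hist))
    names(h) <- c("time", "env", "A", paste0("a_", seq_len(k)), "R")
    out$history <- h
  }
  out
}
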