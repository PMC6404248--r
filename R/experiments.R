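#' Specification of a one-parameter ensemble sweep
#'
#' @param config base [sim_config()].
#' @param parameter name of the swept parameter (see [set_param()]).
#' @param values non-empty grid of values.
#' @param replicates replicates per grid point.
#' @param seed base seed; each grid point gets a deterministic seed derived
#'   from (`seed`, point index), so a full sweep reruns bit-identically and
#'   no two points share a random stream.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(config, parameter, values, replicates = 1000,
                       seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(values) < 1) stop("'values' must be a non-empty grid")
  structure(list(config = config, parameter = parameter,
                 values = values, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

point_seed <- function(base, i) {
  as.integer((as.numeric(base) * 1009 + i * 9973) %% 2147483647)
}

summarize_fates <- function(out, max_time) {
  n <- nrow(out)
  n_rescued <- sum(out$fate == "rescued")
  n_extinct <- sum(out$fate == "extinct")
  n_censored <- sum(out$fate == "censored")
  p_hat <- n_rescued / n
  text <- out$time[out$fate == "extinct"]
  not_resc <- out$time[out$fate != "rescued"]
  data.frame(
    n_rep = n, n_rescued = n_rescued, n_extinct = n_extinct,
    n_censored = n_censored,
    p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n),
    mean_T_ext = if (n_extinct > 0) mean(text) else NA_real_,
    se_T_ext = if (n_extinct > 1) stats::sd(text) / sqrt(n_extinct)
               else NA_real_,
    restricted_mean_T = if (length(not_resc) > 0) mean(pmin(not_resc, max_time))
                        else NA_real_,
    se_restricted_T = if (length(not_resc) > 1)
      stats::sd(pmin(not_resc, max_time)) / sqrt(length(not_resc))
      else NA_real_)
}

#' Rescue probability across a parameter sweep
#'
#' Runs an ensemble per grid point, tabulates fates with binomial standard
#' errors, and attaches the matching analytic rescue probability whenever
#' the point has a closed form (one-shift, density-independent, two-point
#' phenotype: beneficial entry, deleterious entry, or standing variation
#' with `q > 0` and `mu = 0`).
#'
#' @param spec a [sweep_spec()].
#' @return A data.frame, one row per grid point, with columns `parameter`,
#'   `value`, the fate counts, `p_hat`, `se`, `analytic_p` (NA where no
#'   closed form applies), and extinction-time summaries. Points with more
#'   than 5% censored replicates are flagged in a `censoring_warning`
#'   column.
#' @export
estimate_rescue_probability <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(seq_along(spec$values), function(i) {
    cfg <- set_param(spec$config, spec$parameter, spec$values[[i]])
    out <- run_ensemble(cfg, spec$replicates, point_seed(spec$seed, i))
    s <- summarize_fates(out, cfg$max_time)
    s$analytic_p <- analytic_for_config(cfg)
    cbind(data.frame(parameter = spec$parameter,
                     value = spec$values[[i]]), s)
  })
  res <- do.call(rbind, rows)
  res$censoring_warning <- res$n_censored / res$n_rep > 0.05
  if (any(res$censoring_warning))
    warning("some grid points censored more than 5% of replicates; ",
            "their estimates are biased toward non-rescue")
  res
}

analytic_for_config <- function(cfg) {
  ok <- cfg$scenario == "one_shift" && !cfg$density_dependent &&
    !cfg$resistance && length(cfg$phenotype$support) == 2L &&
    cfg$phenotype$sd > 0
  if (!ok) return(NA_real_)
  if (cfg$mu > 0 && cfg$q == 0) {
    switch(cfg$entry_mode,
           a_plus = rescue_prob_aplus(cfg$phenotype, cfg$memory, cfg$N0,
                                      cfg$mu, cfg$phiA)$p_rescue,
           a_minus = rescue_prob_aminus(cfg$phenotype, cfg$memory, cfg$N0,
                                        cfg$mu, cfg$phiA)$p_rescue,
           NA_real_)
  } else if (cfg$mu == 0 && cfg$q > 0 && cfg$init_phenotype == "balance") {
    rescue_prob_standing(cfg$phenotype, cfg$memory, cfg$q)$p_rescue
  } else NA_real_
}

#' Mean extinction time across a parameter sweep
#'
#' Persistence study for periodic environments: per grid point, disables
#' rescue detection (the question is how long the population lasts, not
#' whether it reaches `K`) and reports the mean extinction time over
#' extinct replicates, the censoring rate at `max_time`, and the restricted
#' mean time (mean of `min(T, max_time)` over all replicates) which remains
#' well defined and comparable when some replicates outlive the horizon.
#' A wild-type-only baseline (no `a` copies, `mu = 0`) is computed per grid
#' point alongside.
#'
#' @param spec a [sweep_spec()].
#' @return A data.frame, one row per grid point, including baseline
#'   columns (`baseline_mean_T_ext`, `baseline_restricted_T`).
#' @export
mean_extinction_time <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  # the wild-type-only baseline is unaffected by a-specific parameters
  # (p, variance, q, ...), so it is computed once per distinct wild-type
  # configuration rather than once per grid point
  baseline_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_along(spec$values), function(i) {
    cfg <- set_param(spec$config, spec$parameter, spec$values[[i]])
    cfg$rescue_threshold <- Inf
    out <- run_ensemble(cfg, spec$replicates, point_seed(spec$seed, i))
    s <- summarize_fates(out, cfg$max_time)
    base_cfg <- cfg
    base_cfg$q <- 0L
    base_cfg$mu <- 0
    key <- paste(base_cfg$phiA, base_cfg$N0, base_cfg$K,
                 base_cfg$density_dependent, base_cfg$max_time,
                 base_cfg$scenario,
                 if (!is.null(base_cfg$schedule))
                   paste(base_cfg$schedule$n, base_cfg$schedule$M,
                         base_cfg$schedule$initial) else "",
                 sep = "|")
    if (is.null(baseline_cache[[key]])) {
      nkeys <- length(ls(baseline_cache))
      base <- run_ensemble(base_cfg, spec$replicates,
                           point_seed(spec$seed + 1L, nkeys + 1L))
      baseline_cache[[key]] <- summarize_fates(base, cfg$max_time)
    }
    sb <- baseline_cache[[key]]
    s$baseline_mean_T_ext <- sb$mean_T_ext
    s$baseline_restricted_T <- sb$restricted_mean_T
    cbind(data.frame(parameter = spec$parameter,
                     value = spec$values[[i]]), s)
  })
  res <- do.call(rbind, rows)
  res$censoring_warning <- res$n_censored / res$n_rep > 0.05
  res
}

#' Epistasis between phenotypic variability and a resistance locus
#'
#' Paired comparison of the rescue probability of (i) a population fixed
#' for the invariant wild type with access only to the resistance mutation
#' (`mu = 0`), and (ii) the same population with recurrent mutation to the
#' phenotypically variable allele `a` as well. When `a` alone is
#' subcritical (`sa < 1`), any excess of (ii) over (i) is an epistatic
#' effect: `a` buys persistence time during which resistance can arise.
#' Both arms of each grid point use the same derived seed.
#'
#' @param config a [sim_config()] with `resistance = TRUE` and `mu > 0`.
#' @param p_values memory values to compare at.
#' @param replicates replicates per arm per point.
#' @param seed base seed.
#' @return A data.frame with per-point rescue estimates for both arms,
#'   their difference, and the standard error of the difference.
#' @export
epistasis_comparison <- function(config, p_values, replicates = 1000,
                                 seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$resistance)
    stop("epistasis comparison requires the resistance locus enabled")
  sa_max <- max(vapply(p_values, function(p)
    effective_birth_rate(config$phenotype, memory_model(p)), 0))
  if (sa_max > 1)
    warning("the a lineage is supercritical (sa > 1) at some p; the ",
            "comparison then confounds direct rescue by a with epistasis")
  rows <- lapply(seq_along(p_values), function(i) {
    cfg_full <- set_param(config, "p", p_values[[i]])
    cfg_Ronly <- set_param(set_param(cfg_full, "mu", 0), "q", 0)
    s <- point_seed(seed, i)
    full <- summarize_fates(run_ensemble(cfg_full, replicates, s),
                            cfg_full$max_time)
    ronly <- summarize_fates(run_ensemble(cfg_Ronly, replicates, s),
                             cfg_Ronly$max_time)
    data.frame(p = p_values[[i]], n_rep = replicates,
               p_hat_with_a = full$p_hat, se_with_a = full$se,
               p_hat_R_only = ronly$p_hat, se_R_only = ronly$se,
               diff = full$p_hat - ronly$p_hat,
               se_diff = sqrt(full$se^2 + ronly$se^2),
               n_censored_with_a = full$n_censored,
               n_censored_R_only = ronly$n_censored)
  })
  do.call(rbind, rows)
}
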