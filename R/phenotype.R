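#' Phenotype distribution on a finite support
#'
#' A discrete distribution of phenotypic values for the variable allele
#' \eqn{a}. Phenotype values are per-capita birth rates (time is measured in
#' units of the expected lifespan, i.e. the death rate is 1), so all support
#' values must be nonnegative. The object carries the mean \eqn{E(\Phi_a)},
#' variance \eqn{Var(\Phi_a)} and standard deviation \eqn{\sigma_{\Phi_a}};
#' for a two-point distribution the low and high atoms are the conventional
#' \eqn{\Phi_{a-} = E - \sigma} and \eqn{\Phi_{a+} = E + \sigma}.
#'
#' @param support numeric vector of phenotypic values (birth-rate scale).
#' @param weights probabilities, same length as `support`; must be
#'   nonnegative and sum to 1 (within `1e-8`).
#' @return An object of class `phenotype_dist` with elements `support`,
#'   `weights`, `mean`, `variance`, `sd`, and for two-point supports
#'   `phi_minus` / `phi_plus`.
#' @seealso [phenotype_two_point()], [phenotype_k_point()]
#' @export
phenotype_distribution <- function(support, weights) {
  support <- as.numeric(support)
  weights <- as.numeric(weights)
  if (length(support) < 1L || length(support) != length(weights))
    stop("'support' and 'weights' must be nonempty and of equal length")
  if (any(weights < 0))
    stop("'weights' must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must sum to 1")
  if (any(support < 0))
    stop("phenotype values are birth rates and must be nonnegative; got ",
         min(support))
  ord <- order(support)
  support <- support[ord]
  weights <- weights[ord]
  m <- sum(support * weights)
  v <- sum((support - m)^2 * weights)
  out <- list(support = support, weights = weights,
              mean = m, variance = v, sd = sqrt(v))
  if (length(support) == 2L) {
    out$phi_minus <- support[1L]
    out$phi_plus <- support[2L]
  }
  class(out) <- "phenotype_dist"
  out
}

#' Symmetric two-point phenotype distribution
#'
#' The analytically tractable case: the variable allele expresses one of two
#' phenotypes, \eqn{\Phi_{a-} = E - \sigma} or \eqn{\Phi_{a+} = E + \sigma},
#' each with probability 1/2, so that the mean and variance equal the
#' requested values exactly. With `variance = 0` the distribution collapses
#' to a single atom at `mean`.
#'
#' @param mean expected phenotype \eqn{E(\Phi_a)} (birth-rate scale).
#' @param variance phenotypic variance \eqn{Var(\Phi_a)}; must satisfy
#'   `mean - sqrt(variance) >= 0` so the lower birth rate is valid.
#' @return A `phenotype_dist`.
#' @examples
#' phenotype_two_point(0.95, 0.09)  # support {0.65, 1.25}
#' @export
phenotype_two_point <- function(mean, variance) {
  if (variance < 0) stop("'variance' must be nonnegative")
  s <- sqrt(variance)
  if (variance == 0)
    return(phenotype_distribution(mean, 1))
  if (mean - s < 0)
    stop("mean - sd = ", mean - s,
         " < 0: lower phenotype would be a negative birth rate")
  phenotype_distribution(c(mean - s, mean + s), c(0.5, 0.5))
}

#' Equally spaced k-point phenotype distribution
#'
#' Generalises the two-point case to `k` equally weighted, equally spaced
#' atoms symmetric about `mean`. Two calibrations are supported:
#' `"fixed_variance"` chooses the spacing so that the variance equals
#' `scale` regardless of `k`; `"fixed_range"` fixes the range
#' `max - min = scale`, in which case the variance shrinks as `k` grows
#' (by the factor \eqn{(k+1)/(3(k-1))} relative to the two-point case).
#'
#' @param mean expected phenotype.
#' @param k number of atoms, an even integer `>= 2`.
#' @param mode `"fixed_variance"` or `"fixed_range"`.
#' @param scale target variance (squared birth rate) or target range
#'   (birth rate), depending on `mode`; must be positive.
#' @return A `phenotype_dist` with `k` atoms of weight `1/k`.
#' @examples
#' phenotype_k_point(0.95, 4, "fixed_variance", 0.09)
#' @export
phenotype_k_point <- function(mean, k,
                              mode = c("fixed_variance", "fixed_range"),
                              scale) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 2L || k %% 2L != 0L) stop("'k' must be an even integer >= 2")
  if (scale <= 0) stop("'scale' must be positive")
  # atoms at mean + d * (i - (k + 1) / 2), i = 1..k; index variance (k^2-1)/12
  d <- switch(mode,
              fixed_variance = sqrt(12 * scale / (k^2 - 1)),
              fixed_range = scale / (k - 1))
  support <- mean + d * (seq_len(k) - (k + 1) / 2)
  if (support[1L] < 0)
    stop("requested spacing yields a negative phenotype (",
         signif(support[1L], 4), "); reduce 'scale' or increase 'mean'")
  phenotype_distribution(support, rep(1 / k, k))
}

#' @export
print.phenotype_dist <- function(x, ...) {
  cat("Phenotype distribution (", length(x$support), " atoms)\n", sep = "")
  cat("  support:", paste(signif(x$support, 6), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 6), collapse = ", "), "\n")
  cat(sprintf("  E = %g, Var = %g, sd = %g\n", x$mean, x$variance, x$sd))
  invisible(x)
}

#' Phenotypic memory model
#'
#' The probability `p` that an offspring of the variable allele inherits its
#' parent's expressed phenotype; with probability `1 - p` the offspring's
#' phenotype is redrawn independently from the phenotype distribution. For a
#' symmetric two-point distribution the implied per-birth phenotype
#' switching ("epimutation") rate is `u = (1 - p) / 2`.
#'
#' @param p phenotypic memory in `[0, 1]`.
#' @return An object of class `memory_model` with elements `p` and `u`.
#' @export
memory_model <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single number in [0, 1]")
  structure(list(p = p, u = (1 - p) / 2), class = "memory_model")
}

#' @export
print.memory_model <- function(x, ...) {
  cat(sprintf("Phenotypic memory p = %g (epimutation rate u = %g)\n",
              x$p, x$u))
  invisible(x)
}

#' Periodic environment schedule
#'
#' Two environments E1 and E2 alternate every `n` time units (period `2n`).
#' E1 maps phenotype to birth rate by the identity `f1(x) = x`; E2 applies
#' the reflection about the midpoint `M`, `f2(x) = 2M - x`. The reflection
#' preserves the variance of any phenotype distribution and maps its mean to
#' `2M - mean`, which is what keeps the two alleles' mean fitnesses equal
#' across environments when `phiA = 2M - E(phi_a)`.
#'
#' @param n epoch duration in expected lifespans (must be positive for a
#'   periodic schedule).
#' @param M reflection midpoint (average of the two alleles' mean birth
#'   rates).
#' @param initial initial environment: `"E1"`, `"E2"`, or `"random"`
#'   (chosen per replicate).
#' @return An object of class `environment_schedule`.
#' @export
environment_schedule <- function(n, M = 1, initial = c("random", "E1", "E2")) {
  initial <- match.arg(initial)
  if (!is.numeric(n) || n <= 0) stop("'n' must be a positive epoch length")
  structure(list(n = n, M = M, initial = initial),
            class = "environment_schedule")
}

#' Map a phenotype to a birth rate in a given environment
#'
#' @param x phenotype value(s).
#' @param env `"E1"` (identity) or `"E2"` (reflection `2M - x`).
#' @param M reflection midpoint.
#' @return Birth rate(s), clamped at 0 (a reflection can otherwise produce
#'   a negative rate for phenotypes beyond `2M`).
#' @export
env_map <- function(x, env = c("E1", "E2"), M = 1) {
  env <- match.arg(env)
  if (env == "E1") x else pmax(0, 2 * M - x)
}

#' Environment active at a given time
#'
#' The regime flips at the deterministic times `n, 2n, 3n, ...`; a one-shift
#' scenario (no schedule) is constant in time.
#'
#' @param t time(s) `>= 0`.
#' @param schedule an [environment_schedule()], or `NULL` for a one-shift
#'   (constant) scenario.
#' @param initial initial regime, `"E1"` or `"E2"`; overrides the
#'   schedule's `initial` field (required when that field is `"random"`).
#' @return Character vector of `"E1"` / `"E2"`.
#' @export
environment_at <- function(t, schedule = NULL, initial = NULL) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (is.null(schedule)) {
    init <- if (is.null(initial)) "E1" else initial
    return(rep(init, length(t)))
  }
  init <- if (!is.null(initial)) initial else schedule$initial
  if (init == "random")
    stop("initial environment is 'random'; pass 'initial' explicitly")
  flips <- floor(t / schedule$n) %% 2
  other <- if (init == "E1") "E2" else "E1"
  ifelse(flips == 0, init, other)
}

#' Per-capita birth rate of an individual
#'
#' Death rates are 1 for every genotype; this function gives the matching
#' birth rate: `f_env(phenotype)` for the A and a genotypes (for A the
#' phenotype is the fixed `phiA`), and `beta_R` for resistance carriers
#' (independent of both the A/a locus and the environment). With density
#' dependence the rate is multiplied by `max(0, 1 - N/K)`.
#'
#' @param genotype `"A"`, `"a"`, or `"R"`.
#' @param phenotype phenotype value (ignored for `"R"`).
#' @param env `"E1"` or `"E2"`.
#' @param M reflection midpoint of the schedule.
#' @param N current population size (used only with density dependence).
#' @param K carrying capacity.
#' @param density_dependent logical; apply the logistic factor to births?
#' @param beta_R birth rate of resistance carriers.
#' @return A nonnegative per-capita birth rate.
#' @export
birth_rate <- function(genotype, phenotype = NULL, env = "E1", M = 1,
                       N = 1, K = Inf, density_dependent = FALSE,
                       beta_R = NULL) {
  base <- switch(genotype,
                 A = ,
                 a = {
                   if (is.null(phenotype))
                     stop("'phenotype' required for genotype ", genotype)
                   env_map(phenotype, env, M)
                 },
                 R = {
                   if (is.null(beta_R)) stop("'beta_R' required for genotype R")
                   beta_R
                 },
                 stop("unknown genotype: ", genotype))
  if (density_dependent) base * max(0, 1 - N / K) else base
}
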