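#' Epimutation-selection balance within the variable lineage
#'
#' For a two-point phenotype distribution with atoms
#' \eqn{\Phi_{a-} < \Phi_{a+}} and per-birth switching rate
#' \eqn{u = (1-p)/2}, the frequency \eqn{x} of the high-fitness phenotype
#' inside the `a` lineage equilibrates at the root in `[0, 1]` of
#' \deqn{(\Phi_{a-} - \Phi_{a+})x^2 -
#'       (\Phi_{a-} - \Phi_{a+} + u(\Phi_{a-} + \Phi_{a+}))x +
#'       \Phi_{a-} u = 0,}
#' the standard mutation-selection balance quadratic. At `u = 0` selection
#' fixes the fitter phenotype (`fa+ = 1`); at `u = 1/2` every newborn
#' redraws, so `fa+ = 1/2`.
#'
#' @param dist a two-point [phenotype_distribution()] with positive sd.
#' @param mem a [memory_model()].
#' @return The equilibrium frequency of the high phenotype, in `[0, 1]`.
#' @export
equilibrium_fa_plus <- function(dist, mem) {
  check_two_point(dist)
  lo <- dist$phi_minus
  hi <- dist$phi_plus
  u <- mem$u
  num <- hi - lo - u * lo - u * hi
  disc <- 4 * lo * u * (hi - lo) + (lo - hi + u * hi + u * lo)^2
  f <- (num + sqrt(disc)) / (2 * (hi - lo))
  min(max(f, 0), 1)
}

check_two_point <- function(dist) {
  if (!inherits(dist, "phenotype_dist"))
    stop("'dist' must be a phenotype_dist")
  if (length(dist$support) != 2L || dist$sd <= 0)
    stop("the epimutation-selection balance requires a two-point ",
         "distribution with positive phenotypic variance")
  invisible(dist)
}

#' Effective birth rate of the variable lineage
#'
#' The birth rate of the `a` lineage averaged over its balance composition:
#' \eqn{s_a = \Phi_{a-}(1 - f_{a+}) + \Phi_{a+} f_{a+}}. Increasing
#' phenotypic memory concentrates the lineage on the high phenotype, so
#' `sa` rises monotonically from the plain mean `E(phi_a)` at `p = 0` to
#' `phi_a+` at `p = 1`.
#'
#' @inheritParams equilibrium_fa_plus
#' @return The effective per-capita birth rate, in
#'   `[phi_minus, phi_plus]`.
#' @export
effective_birth_rate <- function(dist, mem) {
  f <- equilibrium_fa_plus(dist, mem)
  dist$phi_minus * (1 - f) + dist$phi_plus * f
}

#' Establishment probability of a supercritical lineage
#'
#' Survival probability of a linear birth-death process with birth rate `b`
#' and death rate 1, started from one individual: `max(0, (b - 1)/b)`. This
#' is the time-homogeneous, infinite-`K` limit of the general expression
#' implemented in [establishment_prob_general()].
#'
#' @param b per-capita birth rate (`> 0`).
#' @return A probability; 0 for critical or subcritical rates.
#' @export
establishment_prob <- function(b) {
  if (any(b < 0)) stop("'b' must be nonnegative")
  pmax(0, (b - 1) / b)
}

#' Establishment probability against a declining resident background
#'
#' Evaluates, by adaptive quadrature, the establishment probability of a
#' lineage with intrinsic birth rate `b` (death rate 1) arising at time
#' `tau` while the resident wild-type population declines as
#' `N(t) = N0 exp(-r t)` and suppresses births through the logistic factor
#' `1 - N/K`:
#' \deqn{P(\tau) = 2 / \left(1 + \int_0^\infty (b(1 - N(t+\tau)/K) + 1)
#'   e^{-\int_0^t (b(1 - N(t'+\tau)/K) - 1) dt'} dt\right).}
#' The inner integral is available in closed form for exponential decline,
#' leaving a single outer quadrature. With `K = Inf` the result reduces to
#' `(b - 1)/b`.
#'
#' @param b intrinsic per-capita birth rate of the focal lineage.
#' @param tau arrival time of the lineage.
#' @param N0 resident population size at time 0.
#' @param decline_rate exponential decline rate `r` of the resident
#'   (`1 - (1 - mu) * phiA` for the wild type; see [wildtype_decline()]).
#' @param K carrying capacity (`Inf` for the density-independent limit).
#' @return A probability in `[0, 1]`.
#' @export
establishment_prob_general <- function(b, tau = 0, N0 = 0,
                                       decline_rate = NA, K = Inf) {
  if (b <= 1 && (is.infinite(K) || N0 == 0)) return(0)
  if (is.infinite(K) || N0 == 0) return(establishment_prob(b))
  if (!is.finite(decline_rate) || decline_rate <= 0)
    stop("'decline_rate' must be positive when K is finite")
  r <- decline_rate
  Ntau <- N0 * exp(-r * tau)
  inner <- function(t) (b - 1) * t - (b / K) * Ntau * (1 - exp(-r * t)) / r
  integrand <- function(t)
    (b * (1 - Ntau * exp(-r * t) / K) + 1) * exp(-inner(t))
  if (b <= 1) return(0)  # integral diverges: no establishment
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
  min(max(2 / (1 + val), 0), 1)
}

#' Deterministic wild-type decline
#'
#' After the environmental shift the wild type is subcritical and its
#' expected size follows `N(t) = N0 exp(-(1 - (1 - mu) phiA) t)`; the
#' `(1 - mu)` factor accounts for births lost to mutation away from `A`.
#'
#' @param t time(s) `>= 0`.
#' @param N0 initial population size.
#' @param phiA wild-type birth rate.
#' @param mu per-birth mutation probability away from `A`.
#' @return Expected wild-type population size(s).
#' @export
wildtype_decline <- function(t, N0, phiA, mu = 0) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  N0 * exp(-(1 - (1 - mu) * phiA) * t)
}

new_rescue_result <- function(p_establish, p_rescue, method, subcritical) {
  structure(list(p_establish = p_establish, p_rescue = p_rescue,
                 method = method, subcritical = subcritical),
            class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("P(establish) = %.6g, P(rescue) = %.6g  [%s%s]\n",
              x$p_establish, x$p_rescue, x$method,
              if (x$subcritical) "; subcritical lineage" else ""))
  invisible(x)
}

rescue_rate_check <- function(phiA, mu) {
  r <- 1 - (1 - mu) * phiA
  if (r <= 0)
    stop("the wild type is not declining (1 - (1 - mu) * phiA <= 0); ",
         "rescue is not the relevant question")
  r
}

#' Rescue probability when mutants enter with the beneficial phenotype
#'
#' Probability that at least one de novo `a` mutant, always arriving with
#' the high phenotype \eqn{\Phi_{a+}}, establishes before the wild type is
#' lost. Mutant arrivals form a time-inhomogeneous Poisson process with
#' intensity `mu N(t) phiA P_est`, giving
#' \deqn{P = 1 - \exp\left(-\frac{\mu N_0 \Phi_A (s_a - 1)}
#'   {(1 - (1-\mu)\Phi_A) s_a}\right)}
#' in closed form, with `P_est = (sa - 1)/sa` the establishment probability
#' of the lineage at its phenotypic balance. The `"quadrature"` method
#' integrates the Poisson intensity numerically instead of using the closed
#' form (a cross-check of the algebra).
#'
#' @param dist a two-point [phenotype_distribution()].
#' @param mem a [memory_model()].
#' @param N0 wild-type population size at the environmental shift.
#' @param mu per-birth mutation probability `A -> a`.
#' @param phiA wild-type birth rate (defaults to the equal-mean value
#'   `dist$mean`).
#' @param method `"closed_form"` or `"quadrature"`.
#' @return A `rescue_result` with `p_establish` (of one lineage) and
#'   `p_rescue` (at least one establishes); both 0, with the `subcritical`
#'   flag set, when the lineage's effective birth rate `sa <= 1`.
#' @export
rescue_prob_aplus <- function(dist, mem, N0, mu, phiA = dist$mean,
                              method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  if (mu == 0)
    return(new_rescue_result(establishment_prob(effective_birth_rate(dist, mem)),
                             0, method, FALSE))
  r <- rescue_rate_check(phiA, mu)
  sa <- effective_birth_rate(dist, mem)
  if (sa <= 1) return(new_rescue_result(0, 0, method, TRUE))
  pest <- (sa - 1) / sa
  if (method == "closed_form") {
    pr <- 1 - exp(-mu * N0 * phiA * pest / r)
  } else {
    intens <- function(t) mu * wildtype_decline(t, N0, phiA, mu) * phiA * pest
    I <- stats::integrate(intens, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
    pr <- 1 - exp(-I)
  }
  new_rescue_result(pest, pr, method, FALSE)
}

#' Rescue probability when mutants enter with the deleterious phenotype
#'
#' When every de novo `a` mutant arrives with the low phenotype
#' \eqn{\Phi_{a-}}, establishment requires an epimutation to the high
#' phenotype before the (subcritical) low-phenotype lineage is lost,
#' followed by establishment of the resulting balanced lineage. Viewing the
#' epimutations as a Poisson process along the declining lineage
#' `Na-(t) = exp(-(1 - (1-u) phi_a-) t)` gives
#' \deqn{P_{est,a-} = 1 - \exp\left(-\frac{u \Phi_{a-} (s_a - 1)}
#'   {(1 - (1-u)\Phi_{a-}) s_a}\right)}
#' and the rescue probability
#' \eqn{1 - \exp(-\mu N_0 \Phi_A P_{est,a-} / (1 - (1-\mu)\Phi_A))}.
#' The probability vanishes at both `p = 1` (`u = 0`: the lineage can never
#' escape the low phenotype) and wherever `sa <= 1`, and has an interior
#' maximum in `p` (see [optimal_memory_aminus()]).
#'
#' @inheritParams rescue_prob_aplus
#' @return A `rescue_result`; `p_establish` is the establishment
#'   probability of a single low-phenotype mutant.
#' @export
rescue_prob_aminus <- function(dist, mem, N0, mu, phiA = dist$mean,
                               method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  pest <- establishment_prob_aminus(dist, mem, method)
  if (mu == 0) return(new_rescue_result(pest, 0, method, pest == 0))
  r <- rescue_rate_check(phiA, mu)
  if (pest == 0) return(new_rescue_result(0, 0, method, TRUE))
  if (method == "closed_form") {
    pr <- 1 - exp(-mu * N0 * phiA * pest / r)
  } else {
    intens <- function(t) mu * wildtype_decline(t, N0, phiA, mu) * phiA * pest
    I <- stats::integrate(intens, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
    pr <- 1 - exp(-I)
  }
  new_rescue_result(pest, pr, method, FALSE)
}

#' Establishment probability of a single low-phenotype mutant
#'
#' @inheritParams rescue_prob_aplus
#' @return A probability (0 when `u = 0`, when the low phenotype is not
#'   declining-but-escapable, or when `sa <= 1`).
#' @export
establishment_prob_aminus <- function(dist, mem,
                                      method = c("closed_form",
                                                 "quadrature")) {
  method <- match.arg(method)
  check_two_point(dist)
  u <- mem$u
  lo <- dist$phi_minus
  if (u == 0) return(0)
  sa <- effective_birth_rate(dist, mem)
  if (sa <= 1) return(0)
  decay <- 1 - (1 - u) * lo
  if (decay <= 0)
    stop("the low-phenotype lineage is not declining (1 - (1-u) phi_a- <= 0)")
  pest_plus <- (sa - 1) / sa
  if (method == "closed_form") {
    1 - exp(-u * lo * pest_plus / decay)
  } else {
    intens <- function(t) u * lo * exp(-decay * t) * pest_plus
    I <- stats::integrate(intens, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
    1 - exp(-I)
  }
}

#' Rescue probability from standing variation
#'
#' `q` copies of the `a` allele are already present, at epimutation-
#' selection balance, when the environment shifts. High-phenotype copies
#' (a fraction `fa+`) establish with probability `(sa - 1)/sa`; low-
#' phenotype copies must first epimutate, with the same establishment
#' probability as a de novo low-phenotype mutant:
#' \deqn{P = 1 - \exp\left(-\left( f_{a+} q \frac{s_a - 1}{s_a} +
#'   (1 - f_{a+}) q \left(1 - e^{-\frac{u \Phi_{a-}(s_a-1)}
#'   {(1-(1-u)\Phi_{a-}) s_a}}\right)\right)\right).}
#'
#' @inheritParams rescue_prob_aplus
#' @param q number of standing `a` copies.
#' @return A `rescue_result`; `p_establish` is the per-copy establishment
#'   probability averaged over the balance composition.
#' @export
rescue_prob_standing <- function(dist, mem, q,
                                 method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  if (q < 0) stop("'q' must be nonnegative")
  sa <- effective_birth_rate(dist, mem)
  if (sa <= 1 || q == 0)
    return(new_rescue_result(0, 0, method, sa <= 1))
  f <- equilibrium_fa_plus(dist, mem)
  pest_plus <- (sa - 1) / sa
  pest_minus <- if (mem$u == 0) 0 else establishment_prob_aminus(dist, mem, method)
  expo <- f * q * pest_plus + (1 - f) * q * pest_minus
  new_rescue_result(f * pest_plus + (1 - f) * pest_minus,
                    1 - exp(-expo), method, FALSE)
}

#' Phenotypic memory maximising rescue through the deleterious entry route
#'
#' The rescue probability for low-phenotype entrants vanishes at both
#' extremes of memory (at `p` small the lineage is effectively subcritical;
#' at `p = 1` it can never leave the low phenotype) and is maximised at an
#' interior `p`. Located numerically.
#'
#' @inheritParams rescue_prob_aplus
#' @return A list with `p_star` and the rescue probability there.
#' @export
optimal_memory_aminus <- function(dist, N0, mu, phiA = dist$mean) {
  f <- function(p) rescue_prob_aminus(dist, memory_model(p), N0, mu,
                                      phiA)$p_rescue
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  list(p_star = opt$maximum, p_rescue = opt$objective)
}

#' Analytic summary table over a grid of memory values
#'
#' Tabulates the balance frequency, effective birth rate, and the three
#' analytic rescue probabilities (beneficial entry, deleterious entry, and
#' standing variation with the configuration's `q`) for each memory value.
#'
#' @param config a [sim_config()] (one-shift, two-point phenotype).
#' @param p_grid memory values to evaluate.
#' @param method `"closed_form"` or `"quadrature"`.
#' @return A data.frame with one row per `p`.
#' @export
analytic_rescue_table <- function(config, p_grid = seq(0, 1, by = 0.05),
                                  method = "closed_form") {
  stopifnot(inherits(config, "sim_config"))
  dist <- config$phenotype
  check_two_point(dist)
  rows <- lapply(p_grid, function(p) {
    mem <- memory_model(p)
    sa <- effective_birth_rate(dist, mem)
    ap <- rescue_prob_aplus(dist, mem, config$N0, config$mu, config$phiA,
                            method)
    am <- rescue_prob_aminus(dist, mem, config$N0, config$mu, config$phiA,
                             method)
    st <- rescue_prob_standing(dist, mem, config$q, method)
    data.frame(p = p, u = mem$u,
               fa_plus = equilibrium_fa_plus(dist, mem), sa = sa,
               p_est_aplus = ap$p_establish, p_rescue_aplus = ap$p_rescue,
               p_est_aminus = am$p_establish, p_rescue_aminus = am$p_rescue,
               p_rescue_standing = st$p_rescue,
               method = method)
  })
  do.call(rbind, rows)
}
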