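---
title: "Phenotypic memory, bet-hedging and evolutionary rescue: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic memory, bet-hedging and evolutionary rescue: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirescue)
```

## The model

`epirescue` implements a continuous-time birth–death model of a finite,
haploid population facing environmental deterioration. Each individual
carries one of two alleles at a focal locus. The wild type `A` expresses a
fixed phenotype, hence a fixed per-capita birth rate $\Phi_A$. The variable
allele `a` expresses a phenotype drawn from a finite distribution $\Phi_a$
(analytically, a symmetric two-point distribution with atoms
$\Phi_{a-} = E(\Phi_a) - \sigma$ and $\Phi_{a+} = E(\Phi_a) + \sigma$).
Phenotypes are birth rates: time is measured in units of the expected
lifespan, and every individual dies at rate 1.

Phenotypes are *partly heritable*. When an `a` individual reproduces, the
offspring keeps the parental phenotype with probability $p$ (the
*phenotypic memory*) and otherwise redraws independently from $\Phi_a$. For
a symmetric two-point distribution the redraw lands on the other atom half
the time, so the per-birth switching ("epimutation") rate is
$u = (1-p)/2$: $p = 1$ freezes the lineage's phenotype, $p = 0$ gives
memoryless resampling with $u = 1/2$.

Two environmental scenarios are supported.

* **One abrupt shift.** The shift has already happened at $t = 0$; the
  wild type is subcritical ($\Phi_A < 1$) and declines as
  $N(t) = N_0 e^{-(1-(1-\mu)\Phi_A)t}$, where $\mu$ is the per-birth
  mutation probability from `A` to `a`. Rescue means the population
  reaches the carrying capacity $K$ before hitting 0.
* **Periodic environments.** Two regimes alternate every $n$ lifespans.
  Regime E1 maps phenotype to birth rate by the identity $f_1(x) = x$;
  regime E2 applies the reflection $f_2(x) = 2M - x$ about the midpoint
  $M$. The reflection preserves the phenotypic variance and swaps which
  allele is favoured, and the equal-mean constraint
  $\Phi_A = 2M - E(\Phi_a)$ makes the two alleles exchange mean fitness
  across regimes, isolating the effect of variance and memory from any
  mean-fitness effect. Persistence is measured as time to extinction.

A linked resistance locus can be enabled: any `A` or `a` birth produces an
`R` offspring with probability $\mu_R$; `R` breeds true and confers a
birth rate $\beta_R$ independent of the A/a locus and of the environment.

## Analytic layer

For the one-shift scenario the package provides closed forms and matching
quadrature evaluations.

* **Balance composition.** The frequency of the high phenotype within the
  `a` lineage equilibrates at the root in $[0,1]$ of
  $(\Phi_{a-}-\Phi_{a+})x^2 - (\Phi_{a-}-\Phi_{a+}+u(\Phi_{a-}+\Phi_{a+}))x
  + \Phi_{a-}u = 0$ (`equilibrium_fa_plus()`), giving the lineage's
  effective birth rate $s_a = \Phi_{a-}(1-f_{a+}) + \Phi_{a+}f_{a+}$
  (`effective_birth_rate()`).
* **Establishment.** A lineage with birth rate $b$ escapes stochastic loss
  with probability $(b-1)/b$ ($b > 1$; 0 otherwise). The generalisation
  with a declining resident suppressing births through $1 - N/K$ is
  evaluated by quadrature in `establishment_prob_general()`.
* **Rescue.** Treating mutant arrivals as a time-inhomogeneous Poisson
  process with intensity $\mu N(t)\Phi_A$ yields closed forms for rescue
  when mutants enter with the beneficial phenotype
  (`rescue_prob_aplus()`), with the deleterious phenotype — requiring an
  epimutation before loss of the declining $\Phi_{a-}$ lineage
  (`rescue_prob_aminus()`) — and from $q$ standing copies at balance
  (`rescue_prob_standing()`).

Two structural properties are worth stating because the test-suite
certifies them: rescue with beneficial entry increases monotonically in
both $p$ and $Var(\Phi_a)$, while rescue with deleterious entry vanishes
at both extremes of memory and has an interior maximum
(`optimal_memory_aminus()`) — the lineage needs enough switching to find
the good phenotype but not so much that it immediately loses it.

```{r analytics}
d <- phenotype_two_point(0.95, 0.09)     # support {0.65, 1.25}
m <- memory_model(0.8)                   # u = 0.1
equilibrium_fa_plus(d, m)
effective_birth_rate(d, m)
rescue_prob_aplus(d, m, N0 = 1000, mu = 1e-5)
rescue_prob_aminus(d, m, N0 = 1000, mu = 1e-5)
```

## Simulator

`run_ensemble()` is an exact Gillespie simulation over aggregated classes
(one per genotype–phenotype combination; rates depend only on class, total
size and regime, so event choice is exchangeable within a class). Waiting
times are exponential at the total event rate; deterministic environment
switches truncate the pending waiting time, after which rates are
recomputed and the time redrawn — valid because the process is Markov.
Mutation is coupled to birth events, matching the $(1-\mu)\Phi_A$ factor
in the decline of $N(t)$; an independent-Poisson mutation process is
deliberately not implemented. The core is compiled (Rcpp) and uses R's own
RNG, so a `(config, seed)` pair reproduces every replicate bit-identically.
A plain-R reference implementation (`run_replicate_r()`) mirrors the loop
for small problems and doubles as an independent check of the compiled
core and of the rate bookkeeping.

## Tunable parameters

| Parameter | Meaning | Units | Typical defaults |
|---|---|---|---|
| $E(\Phi_a)$, $Var(\Phi_a)$ | mean / variance of the `a` phenotype | birth rate (per lifespan), squared | 0.95, 0.09 (one-shift); 1.5, 0.16 (periodic) |
| $p$ | phenotypic memory | probability | swept over $[0,1]$ |
| $\mu$, $q$ | mutation supply to `a`; standing copies | per birth; count | $N_0\mu = 0.01$; $q$ small |
| $N_0$, $K$ | initial size; carrying capacity / rescue threshold | individuals | 1000, 5000 (one-shift); 500, 10000 (periodic) |
| $n$, $M$ | epoch length; reflection midpoint | lifespans; birth rate | 13, 1 |
| $\beta_R$, $\mu_R$ | resistance birth rate; mutation to `R` | birth rate; per birth | 2, $10^{-6}$ |

The packaged YAML configurations under `inst/extdata/` encode the standard
study conditions for each scenario; `read_config()` loads them and
`set_param()` derives sweep points.

## Design choices

Several aspects of the model are genuinely open; the package resolves them
as follows.

* **Entry phenotype of de novo mutants** (`entry_mode`): `a_plus` and
  `a_minus` reproduce the two single-shift study designs in which mutation
  can only produce one epigenetic state; `random` (the default) draws from
  $\Phi_a$ and is used for the resistance and periodic scenarios, where
  the entry state is not pinned down by the study design. The epistasis
  comparison is qualitatively insensitive to this choice; the packaged
  configs make it explicit.
* **Density dependence** defaults off for one-shift runs (whose analytic
  comparisons are density-independent) and on for periodic runs, where a
  carrying capacity is part of the study design. It only multiplies birth
  rates by $\max(0, 1-N/K)$; death rates are density-independent.
* **Rescue threshold.** $N \ge K$, checked after every birth. In
  density-dependent mode holding exactly $K$ is a measure-zero excursion
  (births vanish there), so the threshold becomes $\lceil 0.99K \rceil$;
  persistence studies disable rescue detection entirely
  (`rescue_threshold = Inf`).
* **Multi-phenotype distributions** (`phenotype_k_point()`): equally
  weighted, equally spaced atoms symmetric about the mean — the simplest
  family supporting both a constant-variance and a constant-range
  calibration. With constant variance the rescue probability is
  statistically indistinguishable from the two-point case; with constant
  range the variance (and with it the rescue probability) falls as $k$
  grows.
* **Standing-variation initial condition**: each of the $q$ copies is
  assigned the high phenotype independently with the balance probability
  $f_{a+}$ (`init_phenotype = "balance"`), the composition assumed by the
  closed form; `"random"` draws from $\Phi_a$ instead (used for the
  single introduced copy in periodic runs). The number of standing copies
  has no canonical value; the packaged config uses $q = 5$.
* **Equal-mean constraints** are validated with a warning rather than an
  error, so off-constraint regimes remain explorable.
* **Per-capita rate table.** Birth rates are the phenotype values
  themselves (composed with the regime map and the optional logistic
  factor); the death rate is unity for every genotype in every scenario.
  All rate bookkeeping follows from this table.

## Numerical choices

* Quadrature uses `stats::integrate` with relative tolerance $10^{-10}$;
  all integrands decay exponentially, and inner integrals with an
  exponentially declining resident are evaluated in closed form, leaving
  one-dimensional outer integrals.
* The balance quadratic is evaluated via the explicit radical, clamped to
  $[0,1]$; tests compare it to an independent bisection root-finder at
  $10^{-10}$.
* Subcritical clamp: whenever $s_a \le 1$ the analytic rescue
  probabilities return 0 with a flag rather than a negative exponent (the
  closed forms implicitly assume $s_a > 1$).
* The compiled event loop maintains the total birth weight incrementally
  and resynchronises it from scratch every $2^{14}$ events, keeping
  floating-point drift far below the event-selection resolution.
* Reflected birth rates and logistic factors are clamped at 0, so rates
  are never negative even for phenotypes beyond $2M$ or $N > K$.

## Extinction-time reporting

Periodic-environment persistence is summarised by the *restricted* mean
time to extinction, $E[\min(T, \tau)]$ with horizon $\tau$ =
`max_time`, alongside the plain mean over extinct replicates and the
censoring count. The restricted mean remains well defined and comparable
across parameter values when some replicates outlive the horizon, which is
exactly the regime of interest (intermediate memory produces heavy-tailed
persistence); the plain mean over extinct replicates would be biased
downward most where persistence is best. The packaged study conditions use
a $10^4$-lifespan horizon; the test-suite and the acceptance script use a
300-lifespan horizon with 200–600 replicates per grid point, which already
separates the memory and variance effects by several standard errors.
Other deliberately reduced problem sizes in the tests: 2000 replicates per
point for the rescue-probability comparisons (the packaged configs default
to $10^4$), and 2000 paired replicates for the epistasis contrast, whose
effect size (about 0.06 in rescue probability) needs that many pairs for
a clear separation.

## What the ensembles do and do not show

The simulator *is* the data generator: every empirical number in the tests
and the acceptance report is an ensemble over replicate birth–death paths
under the packaged study conditions. Passing tests therefore certify the
internal consistency of the model — simulation agrees with the analytic
approximations in their regime of validity, and the qualitative effects
(monotone benefit of memory for beneficial entry, interior optimum for
deleterious entry and for persistence, variance benefit, epistatic boost
through a linked resistance locus) hold with certified separation. They do
not certify that any real population follows this model: real systems have
continuous phenotype spaces, environment-dependent switching rates,
age structure, and demographic covariates the model abstracts away.

## Known limitations

* The analytic layer covers two-point distributions and the one-shift
  scenario only; periodic environments and $k > 2$ are simulation-only.
* The rescue closed forms are branching/Poisson approximations: they
  treat lineages as independent and establishments as a Poisson count.
  The simulation comparisons are run in the regimes where those
  assumptions hold (mutation-limited supply, $K$ well above $N_0$); for
  standing variation the Poisson-in-$q$ form visibly undershoots the
  exact binomial survival once per-copy establishment approaches
  $(\Phi_{a+}-1)/\Phi_{a+}$ (memory near 1).
* Density-dependent closed forms are not provided (the simulator supports
  the density-dependent birth factor; the analytic layer's only density
  correction is `establishment_prob_general()`).
* The phenotypic memory $p$ is a fixed parameter, not an evolving trait;
  there is no modifier dynamics, no diploidy, no spatial structure, and
  epoch lengths are deterministic.
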