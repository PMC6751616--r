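---
title: "Sequential Bayesian safety monitoring with elicited margin distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential Bayesian safety monitoring with elicited margin distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safenim)
```

## The model and its assumptions

`safenim` monitors several rare dichotomous safety events during a
non-inferiority trial. For arm $i \in \{0, 1\}$ (control, experimental)
and event $j$, cumulative counts at interim analysis $l$ follow a
binomial likelihood $Y_{ij} \sim \mathrm{Bin}(n_i, \theta_{ij})$ with
independent beta priors per arm, hence closed-form beta posteriors. The
decision statistic is the posterior probability that the excess
$\theta_{1j} - \theta_{0j}$ exceeds a *margin distribution* $D_j$ — a
mixture of at most three beta densities fitted from expert elicitation —
integrated over $D_j$:
$$
P(\delta^l_j) \;=\; \int_0^1 P\!\left(\theta_{1j}-\theta_{0j} > x
\,\middle|\, \text{data}\right)\, dF_{D_j}(x).
$$
The trial is flagged at the first analysis where
$P(\delta^l_j) \ge \tau^l_j$ (closed comparison). The key assumptions:
counts accrue independently across analyses and arms at constant true
rates; events are monitored marginally (no multiplicity adjustment or
borrowing across events); and the margin distribution is a legitimate
summary of clinical opinion — in particular, a zero margin is not
admissible for non-inferiority, so elicited zero differences are clamped
(below).

Because the posterior is conjugate, the probability is evaluated by
direct Monte-Carlo sampling of the two beta posteriors and of the margin
(default $10^5$ draws, mandatory seed, binomial standard error always
reported). No MCMC is involved; correctness is checked in the test suite
against one- and two-level quadrature oracles.

## Fitting the margin from elicitation

Each expert states the maximal tolerable event rate $h_{j,e}$ in the
experimental arm given the reference control prevalence
$\tilde f_j$; the acceptable difference is
$d_{j,e} = h_{j,e} - \tilde f_j$. Three fitting methods compete:

1. **EM mixture** (`fit_mixture_em`): finite beta mixtures with
   $K = 1, \dots, 3$ components fitted by expectation–maximisation,
   $K$ chosen by the selection criterion.
2. **Manual dichotomisation** (`fit_manual_two_component`): every split
   of the sorted differences (from isolating the two smallest to the two
   largest values) is tried; a beta is fitted by maximum likelihood on
   each side and the sides are mixed over the 21-point weight grid
   $w_1 \in \{0, 0.05, \dots, 1\}$.
3. **Hybrid** (`fit_hybrid`): the left component and $w_1$ from method
   2, the right side refitted as a 2-component EM mixture with weights
   rescaled by $1 - w_1$.

`select_margin_fit` compares the three on one criterion and keeps the
winner; ties go to fewer components, then to method order.

### Numerical choices

- **Zero/boundary clamp**: differences are clamped into
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$ by default.
  Many experts state a zero tolerance, which is not an admissible
  margin; the clamp maps those answers to the smallest representable
  positive margin rather than discarding them. Configurable via
  `elicit_config(eps = )`.
- **Selection criterion**: log-likelihood, AIC, BIC and the
  Kolmogorov–Smirnov distance are implemented; the default is **BIC**
  because it penalises superfluous components, matching the preference
  for parsimonious mixtures. Parameters are counted as two shapes per
  active component plus $K - 1$ free weights (a boundary weight of 0 or
  1 de-activates a component).
- **EM specifics**: method-of-moments initialisation on a quantile
  partition, 10 seeded restarts (random quantile breakpoints), relative
  log-likelihood tolerance $10^{-6}$, at most 500 iterations, shape
  parameters bounded in $[10^{-3}, 10^4]$. The observed-data
  log-likelihood trace is returned and tested to be non-decreasing.
- **Degenerate sides**: a dichotomisation side with fewer than two
  distinct values gets a sharp spike fit (beta with the common mean and
  effective sample size 1000) with a warning, so the search never
  aborts on ties in the data.
- **Beta ML**: fits use the sufficient statistics
  $(n, \overline{\log x}, \overline{\log(1-x)})$ with the analytic
  gradient on the log-shape scale, which makes the cut search cost
  almost independent of the sample size per cut.

## Priors and the sensitivity grid

`build_prior_grid` constructs 13 prior pairs: prior 1 is the
non-informative $\mathrm{Beta}(1,1)$ in both arms; priors 2–13 cross
three locations for the prior mean difference
$E(\pi_1 - \pi_0) \in \{0, \mathrm{median}(d_{j,e}), \tilde f_j\}$ with
four precision levels $\{1, 1/3, 1/10, 1/20\}$. The exact
parameterisation behind the reference precision labels is not available,
so this package adopts a declared stand-in: precision $p$ scales a base
effective sample size $S_0$ (default 10) so that
$\alpha + \beta = p\,S_0$ per arm, the control prior mean equals
$\tilde f_j$ and the experimental prior mean is shifted by the location
(clamped inside $(0,1)$). Lower precision means a flatter, less
informative prior; $S_0$ is configurable.

## Threshold schedules

Four families define the per-analysis thresholds:
uniform ($\tau^l = \tau^L$ for all $l$), linear ($a l + b$),
exponential ($a e^l + b$) and logarithmic ($a \log l + b$). The
functional forms alone do not determine $(a, b)$; this package anchors
the non-uniform families through the two fixed points $(1, 0.95)$ and
$(L, \tau^L)$, a choice validated by exact reproduction of the full
reference 11-by-4 threshold table to three decimals (an acceptance
test). The uniform family deliberately ignores the first-analysis
anchor, per its literal definition. Raw (unrounded) thresholds are used
for every decision; three-decimal rounding is presentation only, and a
test demonstrates a case where the rounded threshold would flip the
decision.

## Calibration and rule selection

Five scenarios set the experimental prevalence to
$\{1, 2/3, 1.5, 2, 3\} \times \theta_{0j}$, rounded to two decimals and
capped at 1, with configurable truth labels (defaults: the two most
frequent events become truly "Unacceptable" from scenario C, the rarer
two from scenario D). One reference tie cell could not be reproduced by
any rounding rule ($1.5 \times 0.15 = 0.225$ is tabulated as 0.23 while
$1.5 \times 0.39 = 0.585$ is tabulated as 0.58); the package applies the
formula with standard rounding, documented in the tests.

Simulated trials draw binomial increments on the accrual grid (default:
equal increments $\lceil n_i\, l / L\rceil$; any custom vector can be
supplied), share count data across priors and schedules via seed
derivation (so the sensitivity analysis compares rules on the same
trials), and conclude "Unacceptable" for an event as soon as any
analysis flags it. Misclassification accounting distinguishes class-a
errors (false "Unacceptable", rate $A/(A+C)$, capped at 0.10) from
class-b errors (false "Acceptable", rate $B/(B+D)$, capped at
$0.1 + 0.5(100 - W_j)/100$ for median severity weight $W_j$); undefined
rates (zero denominators) are reported as `NA`, never as 0.

Rule selection applies the caps to the final-analysis calibration over a
threshold grid (step 0.01 on the stated interval $(0.5, 1)$, the step
being this package's choice). Choices the procedure leaves open are made
deterministic here: per event the *smallest* admissible final threshold
is retained (it minimises the class-b rate subject to the class-a cap —
the safety-first choice); among admissible priors the one minimising the
summed class-b rates is kept, then the lowest label (a selection that is
otherwise arbitrary among admissible priors). The schedule family is chosen
as the admissible one (sequential rates within caps) with the smallest
total misclassification. An empty admissible set returns an explicit
"no admissible rule" result with a nearest-miss report rather than a
silent fallback.

## The synthetic-data generators

`generate_expert_answers` emulates the salient feature of real margin
elicitations for severe events: a majority spike of near-zero tolerated
differences plus a diffuse minority cluster. Defaults: 43 experts,
spike weight 0.6 with $\mathrm{Beta}(1, 200)$ differences (mass below
one percentage point), diffuse cluster $\mathrm{Beta}(4, 36)$ (mean
0.1), severity scores normal around the event's central weight
(SD 10, truncated to $[0, 100]$, death pinned at 100). The spike weight
and cluster shapes are the package's own realism choices — the real
answer sets are not available — and are fully configurable.
`generate_trial_dataset` draws cumulative binomial increments on the
accrual grid; a test verifies the final count is exchangeable with a
single binomial draw.

What a green simulation test does **not** establish: the generators
assume constant rates, independent events, no dropout and no
covariate-driven expert opinion, so operating characteristics computed
here transfer to a real trial only to the extent those idealisations
hold. The reference overall misclassification rates depend on the
retained margin mixture parameters, which are not available, and are therefore not
reproduction targets; the suite instead verifies the properties that
must hold for any margin (oracle equivalence, monotonicities, EM
recovery, exchangeability).

## Known limitations

- Margins are univariate per event; no multiplicity control or
  hierarchical borrowing across events or subgroups.
- The precision labels of the prior grid use the declared
  effective-sample-size stand-in described above.
- Monte-Carlo evaluation makes flag decisions near the threshold
  stochastic at the $\mathrm{SE} \approx 0.0016$ level (at $10^5$
  draws); raise `n_samples` for production monitoring reports.
- Simulation defaults (1000 trials per scenario) are reduced in the
  test suite (typically 40–200 trials) with tolerances widened to
  binomial standard errors accordingly.
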