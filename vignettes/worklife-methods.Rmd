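---
title: "Estimating worklife expectancy from multi-state event histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating worklife expectancy from multi-state event histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worklife)
```

## The problem

Late-career labor-market affiliation is not a single survival outcome. An
employee in their late fifties moves between work, long-term sickness
absence and unemployment, and may leave the labor market for good through
disability pensioning or a voluntary early-retirement pension. Worklife
expectancy (WLE) summarizes this process in one number: the expected total
time spent in the work, sickness-absence and unemployment states from a
given age until pension age. Because recurrent moves between the
transdurable states are the norm, WLE has to be computed from a multi-state
model rather than from a single time-to-event analysis.

`worklife` implements two estimation routes over the same pipeline:

* **MSLT** (multi-state life table): nonparametric occurrence/exposure
  intensities at observed event ages,
  $\hat\alpha_{hj}(t) = d_{hj}(t) / n_h(t)$, where $d_{hj}(t)$ counts
  transitions from state $h$ to $j$ at age $t$ and $n_h(t)$ counts subjects
  at risk in $h$ just before $t$.
* **Cox-MSLT**: one proportional-hazards model per transition,
  $\lambda_{hj}(t) = \lambda_{hj,0}(t)\exp(\beta^\top Z)$, whose Breslow
  baseline increments are multiplied by $\exp(\beta^\top Z)$ for a chosen
  covariate profile $Z$ to produce profile-specific intensities. This buys
  stable estimates for small subgroups at the price of the proportionality
  assumption.

Either route yields a time-indexed intensity matrix series $\hat A(t)$
(row sums zero, absorbing rows zero). Occupation probabilities follow from
the Aalen–Johansen product integral

$$\hat P(s, t) = \prod_{u \in (s,t]} \left( I + \hat A(u) \right),$$

and the expected duration in state $h$ starting from state $W$ at age $s$
is the area under the occupation curve,
$E(h) = \int_s^{t_p} \hat P_{W h}(s, u)\, du$, up to the pension age
$t_p$. WLE is the sum of $E(h)$ over the states that count as labor-market
affiliation (by default W, S and U).

## State space and data format

The default state space (`danish_labor_market()`) has five primary states —
work (W), sickness absence (S), unemployment (U), disability pension (D)
and early-retirement pension (E) — with eight transitions: the six
recurrent moves among W, S, U and two *combined-origin* transitions
$\{W,S,U\} \to D$ and $\{W,S,U\} \to E$ whose hazards are estimated on the
pooled risk set because exits to pensions are too sparse to estimate per
origin state. D and E are absorbing; pension age is 65. An absorbing
`Death` state and a transdurable `TO` (temporary out) state can be switched
on; both are excluded from WLE.

Data enter in counting-process (long) format: one row per subject-episode
with a half-open age interval $[\mathrm{entry}, \mathrm{exit})$, origin
state, destination state or the reserved `CENSORED` marker, episode-constant
covariates and an optional weight. An event happens at the exit age;
tied event ages are aggregated (Breslow convention downstream). Validation
enforces per-subject chaining (each episode starts in the state the
previous one ended in), non-overlap, and no starts in absorbing states, and
truncates episodes at pension age, where everyone is administratively
censored. Time-varying covariates are represented purely by episode
splitting: a dynamic indicator that flips no→yes does so at an episode
boundary and is carried forward.

## Combined transitions

The printed form of the intensity matrix places the *same* pooled value
$d_c(t)/n_c(t)$ in each origin row of a combined transition; this is
`combined_mode = "equal"` and the default. The alternative reading —
redistributing the pooled intensity over origin rows in proportion to the
crude whole-follow-up shares $f_h$ of origin-specific events — is
implemented as `combined_mode = "crude_frequency"`, where row $h$ receives
$\lambda_c(t)\, f_h\, n_c(t) / n_h(t)$. This choice preserves the total
expected event flow at every age, $\sum_h n_h(t) \cdot
\mathrm{entry}_h(t) = d_c(t)$, which is the property that makes a
redistribution coherent. The crude shares are aggregate (whole-follow-up)
rather than per-age because per-age shares are 0/1 for single events and
would defeat the purpose of pooling. With a single origin, or when no
origin events exist (the latter falls back to `equal` with a warning), the
two modes coincide.

## Confidence limits

Pointwise variances for every entry of $\hat P(s,t)$ come from the
recursive covariance update of the product integral: at each event age the
running covariance of $\operatorname{vec} \hat P$ is propagated through the
factor $(I + \Delta \hat A)$ and incremented by the multinomial
(Greenwood-type) covariance of the intensity increments estimated from the
risk sets. In the pure-survival special case this reproduces the classical
Greenwood Kaplan–Meier variance exactly, which the test suite checks in
closed form; in a three-state illness-death cohort the recursion is checked
against a nonparametric bootstrap.

Two deliberate simplifications, both documented limits of the estimator:

* Only the variability of the (baseline) hazard increments is carried. The
  sampling variability of Cox coefficients $\hat\beta$ is **not**
  propagated into profile-adjusted curves, so Cox-MSLT limits are
  conditional on $\hat\beta$.
* With combined transitions, the entries placed in different origin rows
  share one pooled increment. The recursion treats rows as independent (as
  the standard formulation does) and uses each entry's own effective
  denominator — the pooled $n_c(t)$ for combined entries, $n_h(t)$ for
  ordinary ones — for its variance, and the origin-state $n_h(t)$ for
  within-row cross terms. When all entries of a row share one denominator
  this is exactly the multinomial covariance.

Interval construction is plain-scale Wald, $\hat P \pm z\,\mathrm{SE}$,
clipped to $[0,1]$; no log-log transform is applied, which keeps the
limits directly integrable. Bounds on expected durations are the areas
under the pointwise lower and upper limits, computed with the same
quadrature as the point estimate. Because pointwise limits are dependent
across ages and states, these areas are approximate bounds and are labeled
as such.

## Quadrature

The Aalen–Johansen curve is a right-continuous step function, so the
primary quadrature is its exact step integral — no discretization error
beyond the estimator itself. A trapezium rule with half-weighted endpoints
on a whole-age grid is available (`quadrature = "trapezium"`) as the
conventional approximation; on the default grid the two agree to within the
curvature of the occupation curve over one year.

## Inverse-propensity weighting

To interpret a health exposure predictively rather than conditionally, the
Cox engine accepts per-record weights, and `stabilized_weights()` computes
them: the stabilized exposure component $p_0 / p(Z)$ (marginal over
conditional probability of the observed exposure level, both by logistic
regression) multiplied by the analogous stabilized probability of remaining
uncensored. One weight is computed per record because covariates are
episode-constant snapshots of time-dependent quantities. Administrative
censoring at pension age or end of follow-up is covariate-independent by
design and is not modeled. Weight truncation (winsorizing at configurable
percentiles) is available but off by default; under correct specification
the mean stabilized weight is close to 1 and truncation is unnecessary.

## The cohort simulator and its oracles

`sim_config()`/`simulate_cohort()` generate register-style cohorts from
known piecewise-constant baseline intensities with multiplicative
covariate effects, optional covariate dependence (for confounding
scenarios), dynamic no→yes covariate flips (e.g. a long-term
sickness-absence indicator that switches on after a sickness episode longer
than four weeks), optional shared gamma frailty, and exponential
non-administrative censoring. Sojourns are drawn by exact inversion of the
piecewise-constant cumulative exit hazard and destinations from the
relative intensities at the event age, so the simulated law is exactly the
configured Markov process — which keeps the oracles honest.

For fixed-profile, no-frailty, no-dynamic-rule configs the process is a
time-inhomogeneous Markov chain, and `true_occupation()` /` true_wle()`
return exact answers via matrix exponentials over the constant pieces
(expected durations through the augmented-matrix exponential). Both
functions refuse frailty or dynamic-rule configs rather than returning a
wrong "truth".

The shipped `default_scenario()` is *illustrative*: rates (per year, ages
55–65) are shaped to reproduce the qualitative orderings of late-career
cohorts — a dominant work state with frequent short sickness episodes
(W→S 0.12, S→W 2.0), moderate unemployment flows (W→U 0.10, U→W 0.80),
rare disability exits (0.005 combined), an early-retirement hazard that
switches on at age 60 (0.35) for scheme members, poor self-rated health
(10% prevalence) raising sickness, unemployment, disability and
early-retirement hazards and slowing recovery, and male gender raising the
unemployment hazard. It is not calibrated to any register data, which are
not publicly available; agreement of its outputs with published cohort
numbers should not be over-read.

## Numerical choices

* Cox fits use Breslow ties, convergence at relative partial-log-likelihood
  change below 1e-11 (tightened so that the stacked-stratified and
  per-transition routes agree to 1e-8 on coefficients, as they should
  analytically), at most 100 Newton iterations; non-convergence and
  suspected complete separation (|β| > 15) are errors naming the
  transition. Covariates without variation in a transition's risk set are
  reported absent and absorbed into that baseline.
* Shared gamma frailty (one multiplicative random effect per subject across
  all transitions) is fitted by penalized partial likelihood on the stacked
  data; it is off by default so the headline pipeline stays deterministic,
  and the frailty variance may be fixed (`frailty_theta`) instead of
  estimated.
* A product factor $(I + \hat A(u))$ with a negative entry (an adjusted
  off-diagonal increment exceeding 1, possible for extreme profiles on thin
  risk sets) is a hard error rather than a silent clamp.
* The intensity series is sparse in time (event ages only): the product
  integral only changes there.
* Months are years × 12 rounded half-up — the convention that maps 0.60
  years to 7 months and 1.15 years to 14.

## Problem sizes used in the test suite

Consistency and recovery checks run at the sizes where their tolerances
are comfortably identifiable: occupation probabilities within 0.01
entrywise of the matrix-exponential truth at 20 000 simulated subjects;
expected durations of the WLE states within 2% at 10 000; configured
hazard ratios within 3 standard errors at 5 000; the IPW contrast at
5 000; the Greenwood recursion against a 200-replicate bootstrap at 500.
The expectancy examples and method comparisons use cohorts of a few
hundred to two thousand subjects, matching the scale of the survey cohort
this kind of analysis is designed for.

## Known limitations

* Dynamic carried-forward covariates (prior long-term sickness or
  unemployment) violate the Markov assumption of the occupation-probability
  step; this is inherent to the design it mirrors, and the simulator can
  generate exactly this violation for sensitivity checks.
* Cox-MSLT validity rests on proportional hazards;
  `proportionality_diagnostics()` provides the stratified
  cumulative-hazard curves and log-ratio tables to inspect it, but no
  automatic test.
* Confidence bounds on expectancies are areas under dependent pointwise
  limits — approximate by construction.
* No smoothing of intensities, no Efron/exact tie handling, no
  time-varying coefficients, and no propagation of $\hat\beta$ variance.
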