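---
title: "Prioritizing decision-model parameters for updating and adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing decision-model parameters for updating and adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voirank)
```

## The problem

A cost-effectiveness model that already exists can be *updated* (its
parameter values refreshed with newer evidence) or *adapted* (converted to
estimate outcomes separately for equity-relevant subgroups). Both exercises
require identifying evidence per parameter, which is costly, so the analyst
needs an ex-ante ranking — computable from the model alone, before any
searching — of which parameters matter most. The two tasks need different
notions of "matters":

* For **updating**, what matters is decision uncertainty: the value of
  learning a parameter's true value. That is exactly what the expected
  value of partial perfect information (EVPPI) measures.
* For **adaptation**, what matters is leverage: how much a *change in the
  expected value* of a parameter moves the result, irrespective of how
  uncertain it is. A one-way sensitivity (semielasticity) measures that.
  EVPPI is the wrong tool here — a parameter can be influential but
  precisely known, or uncertain but inconsequential.

Everything operates on per-draw incremental net benefit in health units,
`INB = ΔQALYs − ΔCosts / k`, intervention minus comparator, where `k`
(GBP/QALY) is the rate at which spending displaces health elsewhere.
Working in QALY units rather than monetary units keeps value-of-information
quantities directly interpretable as health; `compute_inb(monetary = TRUE)`
attaches the monetary-scale vector for presentation. Exactly two strategies
are supported; the one-way machinery for more than two arms is an open
research question and the package refuses rather than guesses.

## Value-of-information estimators

With two strategies,

* `EVPI = E[max(0, INB)] − max(0, E[INB])`, estimated by plugging in the
  PSA draws. Its standard error uses the delta method: when
  `mean(INB) > 0` the estimator is the mean of `max(0, INB_i) − INB_i`,
  otherwise of `max(0, INB_i)`, and the SE is the SD of those terms over
  `sqrt(n)`.
* `EVPPI(S) = E[max(0, E[INB | θ_S])] − max(0, E[INB])`. The inner
  conditional expectation is a regression function, estimated with
  penalized splines (`mgcv`):
  * one parameter: a thin-plate spline `s(x, k)` with basis dimension
    `k = 4⌈n^0.2⌉` capped at 30 and by the number of distinct values — a
    slow-growing rule so flexibility rises with information but fitting
    stays cheap;
  * two parameters: a low-rank tensor product `te(x1, x2, k = c(5, 5))`,
    which captures interactions between the pair;
  * three or more: an additive spline basis, one smooth per parameter.
    Interactions among three or more parameters are therefore *not*
    modelled — a documented limitation, acceptable because higher-order
    interaction EVPPI components are rarely dominant and full
    multivariate smoothing at these dimensions is unreliable.

  Above 20,000 draws the fit switches to `mgcv::bam(discrete = TRUE)` for
  speed. Smoothing parameters use `mgcv` defaults (GCV/fREML).

Numerical conventions: a raw EVPPI estimate below zero is pure estimation
noise and is clipped to zero in `per_person`, with the raw value retained
in the estimate's `raw` field — estimates are never silently altered. The
EVPPI standard error is a 200-replicate nonparametric bootstrap over
`(fitted, INB)` pairs; the smoother is *not* refitted per replicate, so the
SE reflects Monte-Carlo error in the plug-in functional but not
smoothing-parameter uncertainty. This keeps the greedy ranking (dozens of
fits) tractable; the omitted component is second-order at the draw counts
the estimators require (`n ≥ 100` is enforced). Regression EVPPI carries a
known upward bias, which is why cumulative rankings can exceed the EVPI and
update metrics can exceed 100%; the package flags, and never truncates,
such values.

Constant (deterministic) columns requested in a subset produce a warning
and contribute nothing; a fully constant subset returns EVPPI 0. Subsets
larger than 5 parameters are refused unless `max_subset` is raised
explicitly — the cap surfaces, rather than hides, the unreliability of
high-dimensional smoothing.

## Greedy conditional-EVPPI ranking and the update metric

Independent EVPPIs do not sum to the set's EVPPI, so ranking by independent
EVPPI alone misstates priorities. `conditional_evppi_ranking()` performs
forward selection: rank 1 is the arg-max of independent EVPPI; at step *k*
each remaining candidate is evaluated jointly with the already-ranked set
and the arg-max is appended. Design choices:

* **Stopping rule.** "Marginal gain has gone to zero" is unattainable
  verbatim under Monte-Carlo noise, so the default tolerance is
  `max(2 × SE(EVPI), 0.1% × EVPI)`: a gain smaller than twice the noise in
  the reference quantity, or smaller than a thousandth of it, is treated
  as zero. `tol = 0` forces ranking until gains turn non-positive;
  `max_steps` caps the table length.
* **Determinism.** Greedy comparisons use unclipped estimates (so noise
  does not get rectified into spurious gains), ties break by larger
  independent EVPPI then lexicographic name, and candidates are processed
  in sorted-name order — the result is invariant to input order and, with
  a fixed RNG seed, bitwise reproducible.
* **Correlated groups.** Parameters sampled jointly (the adverse-event
  probabilities in the bundled simulator) are offered as a single grouped
  candidate by default, because learning one member implies learning about
  the others; pass `candidates` explicitly to rank them individually.
* **One PSA.** Every step reuses the same fixed PSA sample. The method is
  post hoc by design; no re-simulation occurs.

The update metric is `100 × cumulative EVPPI / EVPI`, computed from
unrounded values. A published table computed from rounded intermediate
values can disagree in the last digit; the package always reports from
unrounded quantities and leaves presentation rounding to the report layer
(CSV at full precision, Markdown rounded: EVPPI 2 d.p., metrics 1 d.p.,
semielasticities 4 d.p.).

## Semielasticity metamodel and the adaptation metric

`fit_semielasticity_metamodel()` rescales each usable parameter column to
`z = 100 (x − x̄)/x̄` and fits OLS of INB on all rescaled columns plus an
intercept; coefficients are ΔINB per +1% of the input. Rows are ranked by
absolute coefficient (ties lexicographic); normalized proportions
`|b_j| / Σ|b_j|` sum to one, and the adaptation metric is their cumulative
sum × 100, reaching exactly 100% at the full set.

Degenerate inputs are surfaced, not papered over: constant columns are
excluded (they are deterministic inputs; OLS cannot use them — this also
matches presenting only probabilistic inputs in results tables); columns
whose sample mean is statistically indistinguishable from zero
(`|x̄| < 2.5 sd/√n`) are excluded with a warning because percent-of-mean
rescaling is undefined/sign-unstable there; exact collinearity raises an
error naming the offending columns; constant INB yields an all-zero table
with `r_squared = NA` and a warning. The metamodel's R² is reported and a
warning is emitted below 0.8 (configurable): the OLS semielasticity is a
*linear* summary, and on strongly nonlinear models both its value and the
ranking derived from it degrade — the direct perturbation route
(`manual_owsa()`, which changes one input by 1% at expected values and
re-runs the model) is exact on linear models and available as a
cross-check on any model.

## The bundled case-study simulator

`markov_config()` + `sample_psa()` emulate a two-arm oncology evaluation: a
4-state Markov cohort (well, local recurrence, metastasis, dead), annual
cycles over 45 years from age 55, exponential transitions converted by the
competing-risks formula (exit probability `1 − exp(−Σr·Δt)` apportioned
proportionally to rates), background mortality as an additive log-linear
age-indexed rate from all alive states, a first-year local-recurrence cost
tunnel, one-off intervention and adverse-event costs/disutilities at cycle
0, both discount rates 3.5%/year with cycle 0 undiscounted, and no
half-cycle correction — the simplest defensible cohort conventions, stated
rather than hidden. Arm B's two relative effects (treatment intensity;
new modality) multiply the local-recurrence hazard jointly for the effect
duration (10 years); the duration truncates *both* effects, the simpler of
the two readings of a time-limited effect.

The 21 probabilistic inputs use standard health-economics families with
correct support: gamma for rates and costs (CV 0.2), beta for utilities
(effective sample size 150), lognormal for the relative effects
(log-scale SD 0.12). The adverse-event class probabilities (classes 0, 2a,
2b, 3 under each arm) are the only correlated inputs: each arm's classes
are a Dirichlet draw (concentration 150) including a small unclassified
remainder — so the named classes sum to slightly under one and are not
exactly collinear in the OLS design — and the two arms share the
underlying uniform draws (a comonotone coupling), inducing strong positive
cross-arm correlation. Arm A's class-0 probability is the simplex
complement rather than a separate input, giving 21 sampled columns.

Default values are plausible for an adjuvant breast-cancer setting and
were chosen once so that the qualitative published pattern holds —
treatment B dominates (more QALYs, lower costs), the probability of
cost-effectiveness is ≈0.97 at k = £13,000/QALY, decision uncertainty is
concentrated in the two relative-effect parameters — and then frozen. They
are *not* the original study's appendix inputs, which are not reproduced in
the paper's main text; every value is overridable, so an analyst holding
the original inputs can reproduce the published tables. Consequently a
green simulator test establishes that the machinery behaves correctly on a
model *of this structure*, not that the package reproduces the published
numbers: reported EVPPIs and semielasticities from the bundled defaults
differ from the published case study in magnitude (and can differ in sign —
e.g. the baseline recurrence-rate semielasticity is positive here because a
higher baseline hazard gives the effective treatment more events to
prevent).

What the generator does not emulate: patient-level heterogeneity,
non-exponential (time-varying) hazards, half-cycle or life-table
corrections, parameter correlation beyond the adverse-event group, and
structural uncertainty.

## Validation strategy

The estimators are validated against a linear-Gaussian toy
(`linear_gaussian_toy()`): INB is a sum of independent normals, so EVPI and
every subset EVPPI have the closed form
`σ_S φ(μ/σ_S) − μ Φ(−μ/σ_S)` (for `μ ≥ 0`) with
`σ_S² = Σ_{j∈S} sd_j²` — an oracle independent of the regression path. The
test suite checks the estimators against these closed forms at 3 Monte-
Carlo SEs, the greedy ranking against the sd-ordering the oracle implies,
OLS recovery of known coefficients within 3 SEs, cohort conservation to
1e-12 with pencil-and-paper traces, and bit-exact CSV round trips.

## Known limitations

* EVPPI interactions of order ≥ 3 are not modelled (additive basis).
* Bootstrap SEs omit smoother-refit uncertainty (see above).
* Semielasticities are linear summaries; nonlinear models get a warning,
  not a nonlinear extension.
* Two strategies only; no acceptability curves over a threshold grid; no
  expected value of sample information; metamodel uncertainty is not
  propagated into rank intervals.
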