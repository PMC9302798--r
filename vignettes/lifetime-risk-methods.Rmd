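---
title: "Methods: lifetime risk of diabetes from surveillance records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime risk of diabetes from surveillance records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liferisk)
```

## The model

`liferisk` works with a discrete-time illness–death chain on four mutually
exclusive states — normoglycemia (N), prediabetes (P), diabetes (D), death —
with a cycle length of one year and age as the clock, on ages 0 to 110.
Severity is ordered N < P < D; D is absorbing among the living states,
death absorbs everything, and no reversion is allowed (a person classified
prediabetic stays at least prediabetic). The allowed one-year moves are
N→{N,P,D,death}, P→{P,D,death}, D→{D,death}.

The quantity of interest is the remaining lifetime risk at an index age
\(x\): the probability that a person alive and diabetes-free in state
\(s \in \{N, P\}\) at \(x\) develops diabetes before dying, together with
the expected number of remaining years lived without and with diabetes and
the mean per-individual fraction of remaining life spent with diabetes.
Lifetime risk differs from any fixed-horizon risk because death competes
with diabetes over the whole remaining life span: raising mortality lowers
lifetime risk even when the diabetes hazard is unchanged.

The pipeline has four estimation layers, each usable on its own:

1. **Classification.** Raw records are classified with the ADA thresholds
   (FPG 5.6 / 7.0 mmol/L, HbA1c 39 / 48 mmol/mol, 2-h OGTT 7.8 / 11.1
   mmol/L; diagnosis codes, non-insulin glucose-lowering drugs, and insulin
   episodes of at least 28 continuous days also identify diabetes).
   Diabetes onset is the earliest age at which any criterion holds;
   prediabetes onset is the earliest qualifying measurement strictly before
   that (a tie at the same age resolves to the more severe state). Random
   plasma glucose is ingested but never classifies, and a person whose only
   records are random glucose never enters the cohort: cohort entry is the
   first fasting-glucose, HbA1c or OGTT measurement. FPG measured during a
   hospital admission and any glycemic measurement taken in gestational
   weeks 24–40 are excluded before classification.
2. **Transition estimation.** Age- and sex-specific one-year transition
   probabilities are estimated by occurrence/exposure counting (below).
3. **Cohort simulation.** `simulate_cohort()` draws annual multinomial
   moves for each simulated person from the estimated table; lifetime risk
   and life years are empirical means over the conditioning set.
4. **Cross-validation.** A modified Kaplan–Meier estimator on the age
   timescale, an Aalen–Johansen cumulative incidence function, a Sullivan
   life table, and age–period–cohort spline models provide independent
   routes to the same quantities.

## Observation processes and the at-risk rule

Opportunistic registries observe the glycemic state only when a qualifying
measurement happens, while deaths are registered continuously. These two
processes end at different times for the same person, and conflating them
biases the estimates in ways that are easy to reproduce with the synthetic
generator. The estimator therefore uses *cause-specific exposure windows*:

* **Progression** (N→P, N→D, P→D). A person is at risk at age \(a\) only if
  a qualifying measurement exists at or after age \(a+1\), so that the
  destination state is actually observable; the estimate is the conditional
  progression probability given survival. Onsets are dated at the first
  qualifying evidence (right-endpoint convention) and carried forward, so
  states between measurements are deducible from the no-reversion rule.
* **Death.** A person is at risk at age \(a\) only if vital-status coverage
  extends through \(a+1\) — the administrative end of surveillance when
  `resolve_histories(..., study_end = )` is given, the last record
  otherwise (for a deceased person without a study end, the death record
  itself certifies coverage through the death year). Within the vital risk
  set, onsets and registry entry are *ceiling-dated*: a state detected
  mid-year is attributed to the origin state for that whole year, and the
  partial entry year is dropped. Detection and entry happen conditional on
  being alive at that moment; crediting the switch year to the new state
  would give it survivor-only person-time and push its deaths onto the
  origin state (in synthetic runs this halves the onset-year death count of
  the diabetes row).

The row at \((a, s)\) is assembled as \(P(s\to\text{death}) = \hat q\),
\(P(s \to s') = (1-\hat q)\,\hat p'_{s'}\) for living destinations, and the
diagonal as the remainder; rows are exactly stochastic by construction.
Ages with no at-risk person borrow the nearest populated age's row within
the stratum (recorded in the `borrowed` slot) so the chain is defined on
the whole 0–110 range; person-time before entry never contributes.

Two residual biases of the observation process are inherent rather than
fixable by the estimator, and are visible when the generator uses its
realistic opportunistic schedule: onsets are detected with a delay of the
order of the inter-test gap, shifting progression events slightly to older
ages, and a person lost to follow-up whose death goes unregistered
contributes alive person-time until the administrative end. Both are small
at the default testing intensity and loss rate; the
`testing_schedule = "annual"` generator option removes interval censoring
entirely and is what the estimator-recovery tests use, so that they test
the estimator and not the observation process.

## The synthetic registry generator

The generator first simulates each person's latent annual trajectory from a
known ground-truth transition table, then overlays the observation process.
Its defaults describe the kind of surveillance registry the package
targets:

* entry age uniform on [0, 90] (populates every estimation age), entry
  calendar year uniform over 2001–2019, administrative censoring at the end
  of 2019;
* 21.2% of persons have exactly one glycemic measurement; the others test
  at a mean of 1.5 tests per observed year (`tests_per_year`), a rate
  chosen so the median inter-test gap is well under a year;
* measurement mix 60% FPG, 35% HbA1c, 1.4% 2-h OGTT, 3.6% random glucose
  (the OGTT share mirrors how rarely that test is ordered in practice);
* 5% of FPG records are inpatient and 2% of measurements of women aged
  15–45 carry a gestational week, exercising the exclusion rules;
* loss to follow-up at 0.005/year, the order of magnitude of net migration
  in a territory-wide registry;
* measurement values are drawn uniformly *within the ADA band of the latent
  state*, so classification recovers the latent state exactly and
  estimator tests are isolated from misclassification noise;
* latent diabetes additionally generates diagnosis-code, drug and long
  insulin episodes after onset, plus rare short (< 28-day) insulin episodes
  anywhere that must not trigger a diabetes call.

The default ground truth (`default_truth_transitions()`) uses
age-increasing incidence (N→P: 0.002 + 0.00055·age per year; P→D: 0.035 +
0.0003·age; a small direct N→D term) and Gompertz-type mortality
(2·10⁻⁵·e^{0.1·age}, male multiplier 1.6, state multipliers 1.15 for P and
1.8 for D), with certain death in the final cycle. These values were chosen
once to give adult P→D crude incidence of a few percent per year, lifetime
risks of the magnitude seen in East-Asian surveillance populations, and
realistic survivorship; they are deliberately *not* tuned to reproduce any
published table. What the generator does **not** emulate: state-dependent
testing intensity is off by default (a multiplier hook exists),
measurement error across band boundaries, reversion from prediabetes,
seasonal or provider effects, and any covariates beyond age and sex.
Passing tests on this registry therefore show that the estimators recover
the truth *under the stated observation model*, not that real registries
are free of the selection effects the generator omits.

## Simulation quantities and conventions

* Everyone starts in N at age 0 by default; for the adults-only sensitivity
  analysis, `simulate_cohort(start_age = 20)` starts everyone normoglycemic
  at 20.
* Trajectories are stored as first-occupancy ages; survivors at 110 are
  truncated there for year accounting (very few people survive past that
  age under any realistic table).
* A recorded death age \(D\) means the person was alive at ages up to
  \(D-1\); alive years from index \(x\) are \(\min(D, 110) - x\) and split
  exactly into years without and with diabetes.
* The fraction of remaining life with diabetes is the mean over individuals
  of the per-person fraction, zeros included. This is *not* the ratio of
  the two mean year totals — the two can differ by several points — and
  the per-individual convention is the one consistent with the ordering of
  published tables of this kind.
* Reported confidence intervals on simulated quantities reflect Monte Carlo
  noise (binomial/normal approximation). Estimation uncertainty of the
  transition table can be propagated with `bootstrap_lifetime_ci()`, a
  parametric bootstrap that resamples the observed transition counts
  per row (default B = 200 replicates of a 100,000-person cohort); it
  propagates sampling noise of the counts, not model misspecification.

## Modified Kaplan–Meier and cumulative incidence

The competing-risk machinery works on one-year intervals with ties
processed as simultaneous (events and competing deaths share the at-risk
count; censorings leave afterwards). Pointwise variances use the standard
competing-risks estimator with log(−log) confidence bounds, which is stable
near 0 and 1. Exits are certified per cause: a progression event by its
detecting measurement (an event dated only by a clinical flag after the
last measurement has no matching person-time and is censored instead), a
competing death by full-interval vital coverage, a censored person at the
last age where both processes were observable.

The modified Kaplan–Meier lifetime risk accumulates the annual diabetes
hazard among persons in the origin state with death absorbing probability
mass; persons enter the risk set at the later of the index age and their
entry into the origin state. On complete trajectories this reproduces the
chain's absorption probability exactly (an identity the tests assert). Two
limitations on registry data are worth knowing:

* from a **normoglycemic** origin with delayed entry, prevalent-prediabetes
  entrants are excluded from the risk set, so the DM-free composition
  understates progression and the estimate is attenuated — the prediabetes
  origin, whose risk set is well defined, is the one to cross-validate
  with;
* detection lags make the recorded process slightly non-Markov, so at old
  index ages the pooled-hazard estimate and the chain-conditional estimate
  can drift apart by a few hundredths even on data generated by a Markov
  chain.

## Sullivan life table

`build_life_table()` uses the standard recursion \(l(x+1) = l(x)(1-q(x))\),
\(L(x) = l(x) - d(x)/2\) (deaths mid-interval, all ages including infancy —
an adult-disease application does not warrant an infant separation factor),
\(e(x) = \sum_{y \ge x} L(y)/l(x)\), and partitions person-years by
age-specific diabetes prevalence. The table is closed at the final age by
assuming all survivors die there with half-year exposure. Missing
prevalence at sparse old ages is forward-filled from the last observed age.
Because the cohort's own year accounting counts whole years while Sullivan
subtracts half the deaths, the two agree to within half of the
prevalence-weighted death share — a few tenths of a year on realistic
tables — which is why the cross-method tests use a 0.5-year band.

## Age–period–cohort extrapolation

Rates on age × period cells are modelled as Poisson with an exposure offset
and natural cubic spline effects of age, period and cohort
(`cohort = period − age`). The exact linear collinearity of the three
timescales is resolved by constraining the period effect to curvature only:
each period basis column is residualised on a linear function of period, so
any linear drift is carried by the age and cohort effects, whose slopes are
then identified. This allocation suits the model's purpose — predicting
cohort-indexed rates at unobserved ages — and a user who prefers drift on
the period axis can refit with the roles swapped. Interior knots default to
three per dimension, evenly spaced (a reproducible stand-in for placing
knots at visually identified inflection points; a custom knot list restores
that workflow). Natural splines extrapolate linearly beyond the boundary
knots, which is exactly the behaviour the birth-cohort extrapolation needs.
Rates convert to annual probabilities via \(p = 1 - e^{-r}\), which keeps
probabilities in [0, 1] for any rate, and cohort lifetime risks use the
same modified Kaplan–Meier sum as the registry estimator. When testing
recovery of a known log-linear age effect, cell exposures are sized so
that three standard errors of the extrapolated log-rate at the farthest
evaluated age fit inside the stated 2% tolerance; otherwise the check
measures Poisson noise rather than the model.

## Numerical choices and degenerate inputs

* Row-stochasticity is validated at 10⁻⁹; structurally forbidden cells must
  be exactly zero.
* `substitute_mortality()` redistributes surviving mass proportionally to
  the original conditional shares; a row that previously had no surviving
  mass sends the new surviving mass to its own diagonal.
* Zero at-risk rows borrow the nearest populated age (logged in
  `borrowed`); a state never observed at all gets an inert diagonal row.
* Empty conditioning sets (e.g. prediabetes at very young index ages) yield
  `NA` estimates flagged `unstable` with a warning, never an error.
* If the off-diagonal hazards handed to `transition_table_from_rates()`
  exceed one in total they are rescaled proportionally.
* Determinism: every stochastic entry point takes a seed
  (`generator_config(seed=)`, `simulate_cohort(seed=)`,
  `run_config(seed=)`); identical configuration and seed give
  byte-identical outputs.

## Problem sizes

The test suite runs registries of 4,000–100,000 persons and simulated
cohorts up to 100,000; the acceptance script uses a 50,000-person registry
and a 200,000-person cohort, sizes at which the Monte Carlo error of the
reported quantities is a fraction of a percentage point while a full run
stays under a minute. The simulation scales linearly in cohort size, so the
three-million-person cohorts appropriate for production analyses use the
same code path via `run_config(n_sim = 3e6)`.

## Known limitations

* The estimators inherit the registry's selection: people appear only when
  tested, and the package cannot correct for testing that depends on
  unrecorded risk factors.
* Diabetes type is not differentiated; impaired glucose tolerance is not a
  separate state.
* The bootstrap propagates count noise only; the APC identifiability
  constraint is a modelling choice that cannot be tested from data; and the
  no-reversion convention makes all prevalence and risk estimates
  conditional on that operational definition.
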