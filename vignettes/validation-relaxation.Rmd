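---
title: "Validation relaxation: monitoring error rates in electronic data collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation relaxation: monitoring error rates in electronic data collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(validrelax)
```

## The problem: masking

Electronic data collection platforms (ODK and its relatives) prevent many
errors outright: skip logic guarantees the right questions are asked, and
field constraints refuse out-of-range or mistyped entries. The side effect is
*masking* — an enumerator who misunderstands the instrument, or fabricates
answers, produces data that still satisfies every constraint and therefore
*looks* clean. Unlike paper surveys, there is no hard copy against which such
errors could later be discovered.

*Validation relaxation* turns this around: for a small, purposive subset of
questions the validation rules are deliberately removed, so that errors on
those questions become committable — and therefore detectable, countable and
monitorable. The detectable error rate then serves as a proxy for the
undetectable one, and its breakdown by enumerator and time drives targeted
supervision.

This package implements the full method: the instrument model, the
eight-class taxonomy of detectable errors, opportunity-denominated error
rates, monitoring reports, trend regressions, and a synthetic survey
generator so the entire pipeline is testable without field data.

## Opportunities, errors, and rates

Every monitored (relaxed) rule is evaluated per record. The denominator of a
rate is the number of *opportunities*: the number of records whose routing
actually reached the rule's requisite questions. A respondent who never
entered the birth section cannot commit a birth-section error, and must not
appear in that denominator. The error rate for rule $i$ is

$$ r_i = E_i / N_i $$

with $E_i$ errors among $N_i$ opportunities; $0/0$ is reported as missing,
never as a zero rate.

Eight classes of detectable error are supported (`relaxed_rule()`): removal
of a required-question constraint, illogical combinations across multiple
questions, illogical combinations within one multi-select question,
intentional redundancy (the same question asked in two sections), manual
skip logic, removed minimum/maximum constraints, manual calculation, and
invalid data types. For value-comparing classes an opportunity additionally
requires the compared questions to be *answered*: a missing answer yields no
opportunity rather than an error, so a single skip is never double-counted
as both a skip error and a mismatch error.

Values that cannot be typed as a rule requires (for example a non-numeric
answer reaching a range rule) are excluded from that rule's opportunities and
routed to a diagnostics channel: a typing failure is not evidence of a range
violation, and the invalid-type class exists to count typing failures where
they are the monitored error.

### Relevance semantics

Skip logic is evaluated with three-valued (Kleene) logic: a predicate over
an unanswered question is *unknown*, `and`/`or`/`not` combine as usual, and
an unknown result at the top level means *not shown*. The obvious
alternative — forcing every leaf over a missing answer to `FALSE` — breaks
monotonicity under negation: removing an answer could then *reveal*
questions, which no branching UI does. Under Kleene semantics the reached
set can only shrink when answers are removed, a property the test suite
checks directly. The reached set itself is computed by sequential replay of
the form: each question's relevance is evaluated over the effective answers
accumulated so far, and answers attached to unreached questions (stray data)
are ignored downstream.

A caveat inherent to the method: the app does not log which questions were
displayed, so reach is *reconstructed* from relevance. If an enumerator
backtracked and changed a gating answer, the reconstruction may differ from
what was actually shown.

### Tick distance

Date questions are entered on scroll widgets, so a natural diagnostic for a
date mismatch is how many "ticks" separate the two entries:

$$ \tau = |\Delta \text{day}| + |\Delta \text{month}| + |\Delta \text{year}| $$

on raw calendar components, without normalisation. "One tick off" and "two
ticks off" are $\tau = 1$ and $\tau = 2$; the component-sum covers both one
component off by two and two components off by one, which a scroll overshoot
can produce equally well. Any $\tau > 0$ counts as a redundancy error; the
distance is retained as a diagnostic, not a threshold.

## Monitoring statistics

`rate_table()` aggregates outcomes by rule, enumerator, day, period window
(default 0–14, 15–29, 30–45 days), or enumerator × period. Raw cells get
Wilson score intervals — small counts such as 1/436 make the Wald interval
degenerate, and the Wilson interval is exact at the 0 and $N$ boundaries.

Between-enumerator comparison uses a one-way ANOVA on the binary error
indicators, computed directly from the cell counts: with $p_i = E_i/N_i$ and
pooled $\bar p$,

$$ SSB = \sum_i N_i (p_i - \bar p)^2, \quad
   SSW = \sum_i N_i p_i (1 - p_i), \quad
   F = \frac{SSB/(k-1)}{SSW/(N-k)}. $$

This is algebraically identical to expanding each cell into $N_i$ zeros and
ones and running a textbook ANOVA, which the test suite verifies to
$10^{-10}$. An alternative reading — ANOVA on enumerator-day aggregated
rates — is available by aggregating first (`aggregate_daily()`) and passing
those cells; the binary-observation reading is the default because the
monitoring table's cells are themselves binary-count summaries.

## Trend models

The primary trend model is a no-covariate logistic regression of the binary
error indicator on survey day $t$:

$$ \operatorname{logit} P(\text{error}) = \beta_0 + \beta_1 t, \qquad
   \text{OR per day} = e^{\beta_1}. $$

The observation unit defaults to one observation per (record × reached
rule) — i.e. per opportunity, matching the rate denominator — and is
configurable to one per record, because the unit is genuinely a modelling
choice. Day 0 defaults to the earliest survey date in the dataset, with a
configurable origin.

The fit is maximum likelihood (IRLS via `stats::glm`, deviance tolerance
$10^{-10}$, at most 100 iterations); coefficients beyond $|\beta| > 30$ or a
non-converged fit raise an explicit separation error rather than returning
garbage. Variance is the clustered sandwich

$$ V = A^{-1} B A^{-1}, \qquad
   B = \frac{G}{G-1} \sum_{g=1}^{G} s_g s_g^\top, $$

where $A$ is the observed information, $s_g$ the within-cluster score sum,
and $G/(G-1)$ the standard small-sample factor. The cluster variable
defaults to the enumerator and is configurable (the underlying survey design
clusters on communities). With a single cluster the fit falls back to the
independence (heteroskedasticity-robust) sandwich with a warning; with
singleton clusters the estimator collapses to the HC sandwich times
$n/(n-1)$, which the tests check against an independent implementation.

Predicted rates $p(t) = \operatorname{invlogit}(\beta_0 + \beta_1 t)$ carry
delta-method intervals on the logit scale, transformed back. The same
extrapolation is available in closed form from any reported pair
$(p_0, \text{OR})$ via `extrapolate_rate()`, and the two agree identically
at the fitted coefficients.

Two sensitivity views mirror common practice: `fit_linear_aggregated()`
runs OLS of enumerator-day (or day) aggregated rates on day, and
`daily_sd_trend()` tracks the between-enumerator standard deviation of
daily rates over time, excluding days with fewer than two enumerators.

## The synthetic generator

Field data from the reference deployment is not redistributable, so the
package ships a generator with two regimes.

**The deterministic fixture** (`build_fixture()` with
`reference_fixture_spec()`) reproduces the reference survey's reported summary
exactly: 972 respondents over a 46-day window starting 2016-04-12, routed so
the five opportunity pools are 961 (consent), 618 (birth section), 895
(health-knowledge section), 325 and 202 (child-treatment branches), with
planted per-rule error counts totalling 125 over 7817 opportunities, a
25/14/45 split of date-mismatch tick distances, and per-(enumerator ×
period) opportunity and error totals matching the reported monitoring
table. The 961-vs-972 gap is modelled as 11 consent refusals, which is the
simplest routing that produces a maximum denominator below the respondent
count.

Matching the enumerator table is a small combinatorial problem: each record
contributes a *bundle* of opportunities determined by its routing (a
birth+health record contributes 9, a health-only record 6, a consent-only
record 1, and each treatment branch adds 1), and the 18 enumerator-period
cells must hit their totals exactly. The builder apportions record profiles
across cells by largest-remainder apportionment with a bounded repair pass,
then distributes each rule's errors across cells by a capacity-capped greedy
transportation; both steps assert exactness and fail loudly on infeasible
specifications. Error placement among a cell's eligible records uses a
seeded shuffle, so the dataset is byte-identical for identical (spec, seed)
and error positions are not pathologically clustered. Child birth dates are
generated with day ≤ 24 and month ≤ 10 so that planted tick offsets never
cross a component boundary.

**The stochastic simulator** (`simulate_survey()`, `simulate_trend_obs()`)
draws routing gates as Bernoulli variables with the reference pool
proportions and commits each reached opportunity's error with probability
$\operatorname{invlogit}(\beta_0 + \beta_1 t + u_e)$, defaulting to
$\beta_0 = \operatorname{logit}(0.023)$ and $\beta_1 = \ln 0.969$.
`simulate_trend_obs()` generates the bare (error, day, cluster) triples for
estimator studies; its cluster set defaults to 86 community ids, mirroring
the reference design's sampled communities.

What the generator does *not* emulate: respondent recall error (fixture
mismatches are mechanical plants, not a cognitive model), enumerator
heterogeneity beyond the optional intercept shifts, household/community
covariates and sampling weights, backtracking or partially saved forms, and
any dependence between different rules' errors within a record. Passing
tests therefore demonstrate that the rule engine, accounting and estimators
are correct — not that real field data behaves this way.

## Numerical and design notes

* Percent formatting in reports follows the monitoring convention: one
  decimal for per-rule and per-enumerator cells, two decimals for the
  overall rate; zero-opportunity cells render as an em dash.
* Apportionment ties break deterministically by index order; the error
  transportation processes cells in decreasing error-count order.
* `with_seed()` scopes all generator randomness so library calls never
  disturb the caller's RNG state.
* Answers are kept as raw strings at ingestion; typing is enforced only at
  rule evaluation, which is what makes the invalid-type class expressible.
* `select_multiple` answers use space-separated option tokens, the common
  CSV export convention for ODK-family tools.

Problem sizes in the test suite are chosen for exactness, not scale: the
fixture is the full 972-record dataset; estimator recovery uses 200
replicates of 9527 simulated opportunities, at which size the fitted
per-day OR distribution centres on the generating value and its 95%
interval covers it at close to nominal rate.

## Known limitations

* With very few clusters (e.g. 6 enumerators) the normal-quantile
  cluster-robust interval undercovers noticeably; this is the standard
  few-clusters phenomenon, not a defect of the implementation. Cluster on a
  finer variable, or treat the interval as approximate, when $G$ is small.
* The between-enumerator ANOVA is offered in two constructions (binary
  observations vs aggregated rates) because the reference analysis is
  ambiguous on this point; their P values differ in general.
* Reach is reconstructed from relevance rather than logged by the app (see
  above).
* The generator's defaults encode one specific deployment; other instruments
  need their own form template and fixture specification.
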