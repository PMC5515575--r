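---
title: "Analysing rodent longevity cohorts with lifespanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing rodent longevity cohorts with lifespanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanr)
```

## The data and the questions

lifespanr works on per-animal lifespan tables from factorial rodent
longevity experiments: each row is one animal with its age at death in
days, its genotype (`dwarf` or `control`), treatment (`GH` or `saline`),
sex, and an event flag. The motivating design is a 2 x 2 x 2 study of
early-life growth-hormone exposure in long-lived Ames dwarf mice and
their normal littermates, where every animal is followed until natural
death, so the data carry no censoring (censoring is nonetheless supported
throughout for generality, except where a method is only defined for
complete data).

Three distinct questions are asked of such data, and they need three
different tools:

1. **Does treatment shift overall survival?** Kaplan-Meier curves,
   median lifespans, the log-rank test and Cox proportional-hazards
   models; with complete data, ordinary linear models on the ages at
   death give a complementary, easily adjusted analysis.
2. **Does treatment change maximum lifespan?** A shift confined to the
   long-lived tail can leave the median and much of the survival curve
   untouched. The quantile-threshold test scores every animal alive or
   dead at the age at which only an upper fraction (25% or 10%) of the
   pooled population remains alive, and tests the resulting 2 x 2 table
   exactly.
3. **Does treatment change the rate of aging?** The interval
   occurrence/exposure estimator measures how fast age-specific
   mortality rises with age, without committing to a parametric hazard.

## Survival statistics

`km_estimate()` implements the product-limit estimator
$\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ over distinct death times.
With no censoring it coincides with the empirical survival function. The
median lifespan convention is the smallest death time with
$\hat S \le 0.5$; published longevity papers rarely state their
convention, and this is the standard Kaplan-Meier choice. A tolerance of
1e-9 absorbs floating-point representation of exact halves.

`logrank_test()` accumulates, at each distinct death time, observed
group-A deaths, their conditional (hypergeometric) expectation
$d\,n_a/n$ and variance $d (n_a/n)(1-n_a/n)(n-d)/(n-1)$; the variance
term is defined as zero when only one animal remains at risk, where the
$(n-1)$ denominator degenerates. When the total variance is zero the
test is reported as degenerate with $p = 1$ and a warning rather than an
error, so batch analyses do not abort on pathological subgroups. Only
two-group comparisons are provided: the motivating analyses compare
treatment arms within genotype, and multi-arm contrasts belong in the
Cox model. P-values are reported unadjusted; no multiplicity correction
is applied anywhere in the package.

`cox_ph_fit()` maximises the partial likelihood by Newton-Raphson with
step-halving. Efron's tie correction is the default - day-resolution
lifespan records are tie-rich and Efron is markedly less biased than
Breslow there - with Breslow available for cross-checking against other
software. Numerical choices: iterations stop when the score sup-norm
falls below 1e-8 or after 50 iterations; a step is accepted if it does
not decrease the log-likelihood beyond floating-point resolution
(near the optimum the true gain per step is below representable
precision, and demanding strict increase can stall one step short of
convergence); a coefficient escaping beyond |beta| > 20 is diagnosed as
a monotone likelihood (perfect separation of the death order) and
reported as non-converged with a warning. The score test at beta = 0
(`cox_score_test()`) equals the log-rank chi-square exactly on tie-free
data, which the test suite asserts to 1e-8.

`lifespan_linear_model()` fits `age_days ~ treatment (+ sex)` by
ordinary least squares - valid here because lifespans are complete -
and reports sex-adjusted mean lifespans per treatment by averaging model
predictions over the cohort's observed sex distribution. In a saturated
one-factor model these reduce exactly to the sample group means.
Rank-deficient designs are refused with the collinear columns named.

`percent_change()` encodes the arithmetic used to report lifespan
shortening: day difference and percent of the reference median, with
printing (not storage) rounded to whole days and percent.

## The maximum-lifespan quantile test

`wang_allison_test()` pools the two compared groups (only those two -
the comparisons of interest are within genotype), finds the
$\lceil n(1 - q)\rceil$-th pooled order statistic for alive fraction
$q$, and classifies each animal as alive at that age only if its
lifespan strictly exceeds the threshold. Ties at the threshold count as
dead: the threshold animal itself has died by that age, and the rule
stays deterministic when ages are rounded to whole days. The 2 x 2
group-by-status table goes to `fisher_exact()`, a two-sided Fisher test
by hypergeometric enumeration under the "probability mass at most
observed" rule. A relative slack of 1e-7 decides probability ties; the
slack is part of the rule's definition (descriptions of the method in
print rarely state their tie handling) and is configurable. The sample
odds ratio $ad/bc$ is reported, with `Inf` and `NaN` conventions for
empty cells; a table with a zero margin is uninformative and yields
$p = 1$.

The point of carrying this test alongside the log-rank test is power
against tail-only alternatives. The validation suite constructs a pair
of mortality laws with identical medians in which one group trades its
Gompertz term for a Makeham background - more early-life deaths, far
fewer late-life deaths - so that the log-rank drift largely cancels
while the long-lived tails diverge; there the quantile test rejects more
often than log-rank at the same nominal level. Under the null it is
conservative (discrete tables), which the suite also checks.

## Interval mortality and aging rates

`interval_mortality_rates()` bins age into half-open 200-day intervals
anchored at day 0 (no origin is canonical; day-0 anchoring is
deterministic and matches axes that start near zero) and estimates the
interval mortality rate as deaths per mouse-day of exposure. Exposure
accounting is exact: person-time sums to the total of all death ages and
deaths sum to the cohort size, both asserted in tests. If exactly one
animal dies in the last interval holding any death, that interval is
flagged excluded - a single terminal death gives an unstable terminal
rate - and skipped downstream; interior intervals with no exposure are
dropped rather than treated as zero.

`aging_rates_from_mortality()` differences the mortality rates of
consecutive usable intervals and divides by the distance between
interval midpoints, a finite-difference estimate of the hazard slope,
reported as deaths per 10,000 mice per day and located at the centre
between the two midpoints (the shared boundary, for adjacent
intervals). The default takes absolute differences, matching the
convention of the motivating analysis; `signed = TRUE` is provided
because falls in mortality are otherwise indistinguishable from rises,
and discussions of "rates increasing to a lower level" implicitly use
sign information. Both modes are exposed; the default is documented
rather than guessed from ambiguous usage.

No left truncation is modelled: every animal contributes exposure from
birth, which is correct for lifespan studies that follow animals from
birth to death.

## The synthetic-cohort generator

Raw per-animal records for the motivating study are not published, so
the package ships a Gompertz-Makeham simulator
(`simulate_gompertz_makeham()`) and a design layer
(`study_design()`, `build_study_cohort()`) that every analysis stage is
tested against. The hazard is $h(t) = a e^{bt} + c$; sampling inverts
the cumulative hazard at exponential deviates - in closed form when
$c = 0$ or $b = 0$, otherwise by a monotone Newton iteration started
from the exponential-envelope bound (the cumulative hazard is convex, so
the iterates decrease monotonically to the root; convergence is
bit-stable under a fixed seed). Each design cell draws from a substream
seeded by a hash of the master seed and the cell key, so adding a cell
never perturbs the others. Sub-day resolution is kept by default to
avoid artificial ties in rank-based tests; `round_days = TRUE` emulates
day-resolution records.

Treatment, genotype and sex effects enter as per-cell parameters rather
than as a single proportional-hazards multiplier, so crossing-hazard
scenarios - required to exercise the maximum-lifespan test where the
log-rank test is blind - remain expressible; `scale_hazard()` covers the
proportional special case.

`paper_like_design()` is the package's reference scenario: group sizes
41/41/31/36 (week-1 protocol) and 36/26/32/29 (week-2), split evenly by
sex with the remainder to males, pure Gompertz hazards with slope
$b = 0.008$/day (a typical laboratory-mouse value), and intercepts
calibrated through `gompertz_from_median()` so the cell medians mimic
the printed study medians (week 1: dwarf 1004 vs 839 days under saline
vs GH, controls 830 with no treatment effect; week 2: dwarf 1019 vs 821,
controls 830 vs 725, the 12.6% printed drop). The study reports only
medians and group sizes, so this scenario is a calibration device for
validating the pipeline, not an estimate of the real cohorts: real
lifespan data can depart from Gompertz mortality (late-life hazard
deceleration, cohort heterogeneity, seasonal husbandry effects), and a
passing test suite demonstrates correctness of the estimators under the
stated law, not fidelity of that law to any particular mouse colony.

## Assay transforms

Three small formula-defined transforms round out the pipeline.
`ddct_fold_change()` computes qRT-PCR relative expression; note the
sign-convention trap documented on its help page: the formula
$2^{\Delta\Delta Ct}$ as sometimes printed in methods sections yields
fold < 1 for up-regulated genes, the reciprocal of the common Livak
$2^{-\Delta\Delta Ct}$. Both conventions are implemented and are exact
reciprocals; neither is silently corrected into the other.
`respiratory_quotient()` is VCO2/VO2, dimensionless, ~1.0 for
carbohydrate and ~0.7 for fat oxidation. `itt_percent_baseline()`
expresses an insulin-tolerance glucose series as percent of its
baseline point and is invariant under unit rescaling.

## Validation strategy and problem sizes

The test suite pairs every estimator with an independent oracle:

- Fisher exact p-values against exact integer enumeration (a Pascal
  triangle; all numerators for table totals <= 40 are below 2^53, so
  double arithmetic is exact) for every 2 x 2 table with total <= 40.
- Log-rank p-values against the exhaustive permutation distribution of
  the statistic on small two-sample problems (3-6 animals per group).
- Cox estimates against a grid-search maximiser of the hand-written
  partial likelihood, against `survival::coxph` under both tie methods,
  and by parameter recovery (200 cohorts of 500, true hazard ratio 2,
  checking mean log-HR and 95% Wald coverage).
- The simulator against its closed-form survival law
  (Kolmogorov-Smirnov over 100 seeds at n = 10^4) and closed-form
  medians with bootstrap error bars.
- Interval mortality against the analytic interval-average hazard
  $(S(t_1) - S(t_2)) / \int_{t_1}^{t_2} S$ on a simulated cohort of
  10^5 (200-day bins, intervals with >= 100 deaths, 5% band).
- Aging rates against the analytic slope $a b e^{bt}$ at interval
  boundaries. This check uses 50-day bins and intervals with >= 2000
  deaths: the estimator is a finite difference, and at 200-day bins its
  discretisation bias against the pointwise slope is itself ~20% for
  $b = 0.008$ (the factor $((e^{bw}-1)/bw)^2 e^{-bw}$), while at 50-day
  bins it is ~1%; the death-count floor keeps the sampling error of the
  difference quotient several standard errors inside the 15% band.
- The maximum-lifespan test's null level (2000 simulated pairs of 30)
  and its power against the tail-only alternative described above,
  versus log-rank on the same replicates.

These problem sizes were chosen so the whole suite runs in about a
minute while leaving each stochastic assertion multiple standard errors
of headroom; none of the checks is tight to its tolerance.

## Known limitations

- No stratified, time-varying or frailty Cox models; no interval
  censoring.
- Log-rank is two-sample only by design.
- The quantile test's exact Fisher inference is conservative at small
  group sizes; it trades level for exactness.
- The aging-rate estimator inherits the bias of any finite difference:
  with wide bins on a convex hazard it overstates the slope early and
  understates it where survivorship collapses. Bin width is the user's
  bias-variance dial.
- The simulator draws i.i.d. lifespans within cells; it does not model
  litter effects, shared-cage correlation or heterogeneous frailty.
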