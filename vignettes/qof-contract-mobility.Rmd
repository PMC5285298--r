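---
title: "Pay-for-performance, contract choice and GP mobility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pay-for-performance, contract choice and GP mobility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qofmobility)
```

This vignette is the package's account of its science: the market model
and its assumptions, the payment engine, what the synthetic panel
generator does and does not emulate, the estimators and their numerical
choices, and the design decisions taken where the design was genuinely
open. No empirical number is stated here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The market model

Two practices, each run by a profit-oriented manager and each needing one
doctor, are located a relocation cost `t` apart. Doctors are efficient
(`v`) or inefficient (`nv`), with quadratic effort cost
`gamma * e^2 / 2`, `0 < gamma_v <= gamma_nv = 1`; a doctor hired fresh
from the market is efficient with probability `pi`, while the doctor
living next to each practice has known type. Patients experience quality
`Q = q + e`, the sum of the practice's investment and the doctor's
medical effort, and doctors are altruistic: `Q` enters their utility
directly. Practice revenue is a capitation payment `m` plus `p * Q`, the
pay-for-performance component. Timing: contracts are chosen first (a new
salaried hire at the outside-option wage, a partnership for a local
doctor, or — in the asymmetric type configuration — a contested
partnership after outbidding the rival); then investment and effort are
chosen simultaneously; then care is delivered.

Key equilibrium facts, all unit-tested against a numeric best-response
oracle:

* salaried effort `1/gamma` is price-inelastic; partner effort
  `(2 + p)/(2 gamma)` rises with `p` because a partner keeps half the
  surplus;
* `q = p` under every contract: without the scheme there is no
  investment, and the expected new-hire profit reduces to `m`;
* partnerships pay only inside a region `S` of the primitives (price
  high enough, capitation below a threshold `m_bar`), never for the
  inefficient type; on the sub-region `S_hat` the rival's best bid
  `w_bar_2` and the retention wage `w_bar_1 = w_bar_2 - 2(b1 - b2)`
  leave the home practice a profit advantage of exactly `b1 - b2 + t`.

Two typesetting-level ambiguities in the printed closed forms were
resolved algebraically, not by choice: the squared-price term in the
new-hire profit is `p^2 / 2` (substituting the stage-2 solutions into the
profit function leaves no other reading), and the contested profit is
computed as the manager's profit at the retention wage, which makes the
`b1 - b2 + t` advantage an algebraic identity that the tests verify to
1e-10 rather than an assumption. The region thresholds are evaluated as
printed; because membership is governed by `0 <= m < m_bar`, the
`p_bar` inequality is redundant at non-negative capitation, and a
brute-force profit-comparison oracle confirms the region flags on
thousands of random draws.

### Numerical choices

* **Oracle.** Best-response iteration with golden-section/parabolic
  search (`stats::optimize`) on `e, q in [0, 50]`; equilibria are
  interior for the ranges used (`p <= 10`, `gamma >= 0.1`), except
  `q = 0` at `p = 0`, which is snapped to the bound. Inner searches are
  solved to 1e-10; the fixed-point loop stops at 2e-6, above the
  floating-point jitter of repeated searches on flat objectives, and the
  resulting equilibrium accuracy (tested) is a few 1e-7.
* **Comparative statics.** Central differences with step
  `h = 1e-5 * max(1, |x|)`, scale-robust; a perturbation that leaves the
  parameter domain or the region of definition yields a boundary warning
  and `NA` rather than a sign.
* **Ties.** Exact profit ties in the stage-1 choice resolve to the
  status quo (a new salaried hire), making the choice deterministic and
  conservative.
* **Wages.** The outside option is fixed at zero, so equilibrium
  salaried and uncontested partner wages are zero; profit sharing is
  exactly one half.

## 2. The payment engine

An indicator earns nothing at or below its lower achievement threshold,
its full points at or above the upper threshold, and a continuous linear
ramp in between — a piecewise-linear schedule with exactly two kinks,
tested for monotonicity and linearity on a fine grid. Points convert to
money at the year's price per point. The default synthetic registry has
146 indicators, a 40% lower threshold everywhere, deterministic upper
thresholds cycling over 0.70/0.80/0.90, and prices 76 (2004) and 125
(2005 on); four indicators form a cardiovascular-disease control subset
whose upper thresholds rise to 0.85 in the 2006 registry. The price
shock is the counterfactual: revenue the base-year achievement would earn
under the next year's thresholds, minus what it actually earned, holding
the price per point at the base-year level so the threshold change is
isolated. It is reported in money and as a percentage of the practice's
total base-year revenue — the regressor form — and is non-positive by
construction under a threshold-only tightening. Achievement is stored as
a fraction internally and rendered as a percentage at the interfaces;
records with a zero denominator are undefined and must be dropped
upstream. Whether real points are awarded continuously or in integer
steps is not documented in the scheme descriptions the package follows;
the continuous ramp is implemented.

## 3. The synthetic panel generator

`generate_population()` and `simulate_panel()` produce a census-style
doctor-by-practice panel (default 500 practices, 5 doctors each,
2003–2007, with one internal burn-in year so every emitted year has
lagged covariates). The generator emulates the structure a census-based
study needs — practices with locations, deprivation (LISI), list size,
age–sex population mix and opening year; doctors with age, gender,
income band, latent type and latent intercept; yearly exit, mobility,
partnership, FTE, practice QOF performance, entry, and the 2005→2006
price shock — with marginals centred on census-like values (mean age 45,
42% female, LISI mean 11, list size mean 8.8 thousand). It does **not**
emulate real UK geography or postcodes, survey weighting, practice
births and closures, or any behaviour outside the structural model, so
passing tests demonstrate internal consistency of model and estimator,
not external validity on real data.

The structural defaults were chosen once: `m = 0.5`, `gamma_v = 0.3`,
`pi = 0.2`, and the price path 0 / 0.76 / 1.25 / 1.25 / 1.25 across
2003–2007, mirroring the £76 → £125 price-per-point step at a 1/100
scale. At these values the positive-price years lie inside `S` (so
partnership offers switch on in 2004) and the relocation-cost draws
(exponential, mean 0.6) make the rival's bid feasible for most efficient
doctors — the mobility channel.

Mechanisms, per year:

1. **Exit**: a latent index rising as retirement approaches plus a
   standard-normal error; statutory retirement at 65 for three quarters
   of doctors and 60 for the rest (pension-section heterogeneity), which
   is what makes years-to-retirement vary across same-aged doctors and
   gives the selection model's exclusion restriction real first-stage
   variation.
2. **Mobility** (conditional on staying): triggered when the rival
   feasibility condition of the model holds for the doctor's type at the
   year's price, with an error correlated `rho` (default 0.3) with the
   exit error — the correlation that activates the Heckman correction.
   Movers relocate to one of their practice's ten nearest neighbours and
   stay at least a year.
3. **Partnership**: gated by the stage-1 profit comparison (efficient
   type, parameters in `S`), with a logistic taste shock deciding timing
   among the eligible; inefficient doctors are never promoted, and a
   zero price path yields a panel with no partners at all.
4. **FTE**: `clip(100 * e / e_max + a_i + noise, 11, 100)` with `e_max`
   set so a full-time salaried inefficient doctor at `p = 0` maps near
   91, the census-like mean; the transform preserves monotonicity in
   structural effort.
5. **Practice QOF share**: a bounded affine transform of investment plus
   mean doctor effort plus a practice effect, clipped to [0, 100].
6. **Entry**: market exits vacate slots (a mover merely swaps
   practices); vacancies are filled with probability declining in the
   price — partnership lock-in — which is the mechanism behind the
   falling new-entrant rate after 2005.
7. **Price shock**: per-practice achievement records around the 2005
   QOF share are pushed through the payment engine under the 2005 and
   2006 registries, and the percentage shock is attached to 2006 rows.

Covariates are dated `t - 1` for outcome year `t`, except for newly
entered doctors, whose covariates are contemporaneous because no earlier
observation exists. Ages are September-census integers. All randomness
flows from one seed; the same configuration reproduces the panel
byte-for-byte.

### Geography and derived covariates

Distances are Vincenty inverse geodesics on WGS-84, in miles
(`metres / 1609.344`), with a great-circle fallback and warning in the
non-convergent near-antipodal case. The distance-to-best-practice
covariate takes, among a practice's ten nearest neighbours, the distance
to the one with the highest QOF share, ties to the nearer practice; the
alternative reading "the furthest of the ten nearest" is available
behind `rule = "furthest_of_10"` rather than silently merged, because
the two definitions are genuinely different quantities. Neighbour
candidates are pre-ranked by fast spherical distance and the exact
Vincenty distance is computed on the candidate set; at within-region
scales the rankings are indistinguishable. Survey income bands map to
interval midpoints; only the scale's endpoints (under £25,000, over
£150,000) are published, so the interior edges are a package decision:
band 1 is [0, 25k), band 7 is [125k, 150k), bands 2–6 split [25k, 125k)
evenly, and the open top band extrapolates the last closed band's width,
giving £162,500.

## 4. The estimation suite

* `ols_fit()` — pooled least squares; for binary outcomes this is the
  linear probability model, whose fitted values are deliberately not
  clipped: the out-of-range share is reported instead. Conventional
  standard errors by default, practice-clustered (`sandwich::vcovCL`) by
  option; the default is conventional because the source design does not
  document a clustering treatment. Rank deficiency is an error naming
  the offending columns.
* `probit_fit()` — ML probit via `stats::glm`; one-class outcomes and
  (quasi-)complete separation are errors, never silent divergence.
* `inverse_mills()` — `dnorm/pnorm` computed on the log scale
  (`exp(log phi - log Phi)`), accurate far into the left tail where the
  naive ratio underflows; tested against an adaptive-quadrature oracle
  on moderate indices and a continued-fraction oracle in the tail, to
  1e-10.
* `random_intercept_fit()` — two-level linear model by ML (`lme4`),
  one random intercept at the practice (default) or doctor level. The
  grouping ambiguity — an individual intercept in the model statement,
  practice-level group counts in reporting — is preserved as a flag, not
  resolved. Age enters models quadratically wherever the design uses it.
* `heckman_selection_fit()` — per-year probits of staying in the
  market (exclusion variable: years to statutory retirement), inverse
  Mills ratios stacked into one time-varying series and joined to the
  rows at risk the following year (the doctors who stayed), then the
  random-intercept outcome model with the IMR as covariate. A year with
  a single-class stay outcome is flagged and skipped with a warning.
* `first_difference_fit()` — within-doctor differences across two
  consecutive years, price shock in levels; covariates constant after
  differencing (gender; age, whose yearly increment is common to all
  incumbents) are dropped with a warning. The quintile split fits the
  bottom/top quintile of 2004 practice performance separately, ties to
  the lower quintile, retaining an IMR column in levels when present.
* `exclusion_restriction_check()` — refits mobility with the exclusion
  variable included and reports its coefficient; under the maintained
  restriction it should be quiet, and the generator's `mob_retirement`
  knob deliberately violates it for power checks.
* No multiple-testing adjustment is applied anywhere, matching the
  table conventions the suite mirrors (stars at 10/5/1%).

## 5. Study sizes and what the checks show

The test suite and `scripts/acceptance.R` use problem sizes chosen as a
balance between Monte-Carlo resolution and a single-CPU run: a
1,000-point parameter grid for oracle agreement; 1,000 draws inside
`S_hat` for the profit identity; 50 seeded panels at the default
500-practice scale for the three structural implications (the
partnership gap is structural and holds in every seed; the mobility and
entry contrasts are a few tenths of a percentage point and are therefore
evaluated as means across seeds, with single seeds expected to be noisy);
100 replications of the 500 x 8 random-intercept recovery; 200
replications each for the Heckman bias reduction at `rho = 0.5` and the
`rho = 0` placebo — where "IMR not significant in at least 90% of
replications" is simply the nominal-size property of a 5% test — and 100
replications of the first-difference study. Green results establish that
the implementation computes what the model says and that the estimators
recover what the generator encodes; they say nothing about confidential
census data the package never touches.

## 6. Known limitations

The theory is strictly two practices, two types and one period; the
generator's practice covariates are static apart from size and
performance, so differenced practice characteristics identify only off
movers; FTE saturates at the upper bound for efficient partners, as a
bounded transform of an unbounded effort must; and the structural price
scale (1/100 of the per-point price) is a modelling convenience, not an
estimate.
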