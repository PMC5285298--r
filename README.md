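# qofmobility

Contract choice and GP mobility under practice-level pay-for-performance.

The UK Quality and Outcomes Framework (QOF), introduced in April 2004,
pays general practices per quality "point" earned on clinical indicators:
an indicator with achievement *A* (the share of eligible patients meeting
its target) earns nothing at or below a lower threshold, its full points
at or above an upper threshold, and a linear ramp in between; points
convert to money at a price per point (£76 in 2004, £125 from 2005).
Because the scheme rewards the *practice*, not the individual doctor, it
changes what contracts practices want to offer: a salaried doctor's effort
does not respond to the price, while a profit-sharing partner's does. This
package implements a two-practice contract-theory model of that mechanism
and the empirical machinery to test its implications on synthetic
census-style panel data.

## The model

Two practices, each needing one doctor, sit a relocation cost *t* apart.
Doctors are efficient (*v*) or inefficient (*nv*), with effort-cost
parameter γ\_v ≤ γ\_nv = 1; a new hire is efficient with probability π.
Quality is *Q = q + e* (practice investment plus medical effort), doctors
are altruistic (*Q* enters utility), and practices earn capitation *m*
plus *pQ* under the P4P scheme. In the stage-2 equilibrium:

- a salaried doctor exerts `e = 1/γ` (unresponsive to *p*), a partner on
  half profit shares exerts `e = (2 + p)/(2γ)`;
- the practice invests `q = p` under either contract, so `p > 0` is
  necessary for any investment;
- a partnership beats a new salaried hire (`Π^M > max(0, Π^N)`) only on a
  parameter region `S` requiring `p` large and `m` below a threshold
  `m̄(p, γ, π)` — never for an inefficient doctor, and never when `p = 0`
  (where `Π^M = m/2 < m = Π^N`);
- on the sub-region `Ŝ` (relocation cost small enough) the rival bids
  `w̄₂` for the efficient doctor, the home practice retains them at
  `w̄₁ = w̄₂ − 2(b₁ − b₂)`, and its profit advantage over a new hire is
  exactly `b₁ − b₂ + t`.

Three testable implications follow: efficient doctors are more likely to
be offered partnerships; introducing the scheme (p: 0 → positive) creates
mobility; strengthening it (the 2005 price rise) raises quality and
reduces the entry of new salaried doctors.

Every closed form is verified against a numeric best-response oracle
(golden-section search to a fixed point), and the empirical side mirrors
the design used on the real GMS census: pooled OLS / linear probability
models, two-level random-intercept models (doctors nested in practices),
year-stratified probits of staying in the market whose stacked inverse
Mills ratios correct the mobility equation for selection (exclusion
restriction: years to statutory retirement), and first-difference models
using the exogenous 2005→2006 CVD threshold-change price shock.

## Worked example

```r
library(qofmobility)

pars <- model_params(m = 0.5, p = 1.25, pi = 0.2, gamma_v = 0.3, t = 0.4)
equilibrium_outcomes(pars, "local_partnership", "v")
#> Contract outcome [local_partnership, type v]:
#>   effort e = 5.4167, investment q = 1.2500, quality Q = 6.6667
#>   wage w = 0.0000, doctor utility U = 6.2917, profit = 4.0260
region_membership(pars)
#> Region membership: S1 = FALSE, S2 = TRUE, S = TRUE, S_hat = TRUE
#>   thresholds: m_bar = 2.3229, p_bar = -3.0857, pi_cutoff = 0.2857
stage1_contract_choice(pars, c("v", "nv"))
#> Stage-1 choices:
#>   practice 1: contested_partnership (type v)
#>   practice 2: new_salaried (type unknown)
```

The partner's effort `(2 + 1.25)/(2 × 0.3) = 5.42` exceeds the salaried
effort `1/0.3 = 3.33`; the parameters lie in `S` (partnerships are
profitable) and in `Ŝ` (the rival can feasibly bid), so practice 1
retains its efficient doctor as a contested partner while practice 2
hires a new salaried doctor.

One full synthetic study — generate a 500-practice, five-year doctor
census whose outcomes follow the model, then fit the whole estimation
suite:

```r
suite <- run_empirical_suite(dgp_config(seed = 42))
suite$implications
#>                                        implication    statistic  pass
#> 1     efficient doctors more likely to be partners 0.6055449777  TRUE
#> 2    mobility higher once the price turns positive 0.0024310658  TRUE
#> 3 new-doctor entry lower after the 2005 price rise 0.0005128814 FALSE
coef_table(suite$fits$partnership_ri)["efficient", ]
#> estimate       se        z        p
#>   0.6055   0.0057 105.4543   0.0000
```

The random-intercept partnership model puts the efficient-type effect at
61 percentage points. The two mobility/entry implications are year-mean
contrasts of a few tenths of a percentage point, so a single seed is
noisy — here the entry contrast lands on the wrong side — which is why
the reproduction script below aggregates them over 50 seeded
replications, where all three hold with room to spare.

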