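# pharmequity

Needs-based equity analysis of pharmaceutical-assistance transfers with
multiple data envelopment analysis (MDEA).

## The problem

Public pharmaceutical-assistance budgets are supposed to follow need:
locations with more chronic disease, more elderly residents and less income
should receive more support, not less. `pharmequity` measures whether they
do. It was built around the 2013 allocation of two Brazilian federal
programs across the 26 states and the Federal District — the Popular
Pharmacy Program (BPPP), which subsidises drugs through accredited private
pharmacies, and the Basic Component of Pharmaceutical Assistance (BCPA),
which funds dispensing through public-system pharmacies — but the machinery
applies to any set of decision-making units (DMUs) with a needs vector and
a services vector.

## The model

Each unit *o* has needs **x**ₒ ≥ 0 (inputs: hypertension, diabetes and
asthma prevalence, elderly population, a negative-income index) and
services **y**ₒ ≥ 0 (outputs: transfer values per program). The
output-oriented, variable-returns-to-scale DEA envelopment program finds
the largest radial expansion φₒ of the unit's services achievable by a
convex combination of observed peers with no greater needs:

    max φ   s.t.   Σⱼ λⱼ xⱼ ≤ xₒ ,   Σⱼ λⱼ yⱼ ≥ φ yₒ ,   Σⱼ λⱼ = 1 ,   λ ≥ 0

The **equity index** is EI = 1/φ ∈ (0, 1]: 1 on the equity frontier, below
1 for units whose service coverage falls short of what comparable-need
peers obtain. A second LP phase maximises the remaining slacks, so the peer
target φ·yₒ + s⁺ is the Pareto-optimal "projected" transfer value.

With 27 units and 5 + 2 variables, plain DEA calls too many units
efficient. **MDEA** solves the DEA for *every* non-empty subset pair of
needs and services — (2⁵−1)(2²−1) = 93 submodels — and summarises each
unit's EI distribution by its mean, standard error and normal 95%
confidence interval.

On top of the index the package computes capture percentages
(100·effective/projected), aggregate required increases
(100·(projected−effective)/projected), and two budget-constrained
reallocation schemes that redistribute existing budgets in proportion to
projected values: **complementary** (each program keeps its own budget) and
**substitution** (both budgets pooled). A small OLS helper regresses the
coverage deficit 1−EI on the accredited-pharmacy share.

The envelopment LPs are solved by a built-in two-phase primal simplex with
Bland's anti-cycling rule, designed for the heavy degeneracy typical of DEA
programs, and verified in the test suite against an exhaustive grid-search
oracle over the peer-weight simplex.

## Worked example

```r
library(pharmequity)

# synthetic states with a planted frontier and known inefficiencies
sim <- simulate_states(n_dmus = 8, n_frontier = 3,
                       inefficiency_range = c(0.5, 0.95), seed = 7)
fit <- mdea(sim$dataset)
fit
#> MDEA fit: 8 units x 93 submodels (5 needs, 2 services)
#>   equity index (ensemble mean): 0.5687 to 1.0000; 3 unit(s) on the full-model frontier

round(cbind(recovered = fitted(fit), planted = sim$truth$true_u), 3)
#>     recovered planted
#> S01     1.000   1.000
#> S02     1.000   1.000
#> S03     1.000   1.000
#> S04     0.809   0.806
#> S05     0.620   0.619
#> S06     0.585   0.584
#> S07     0.586   0.583
#> S08     0.673   0.671
```

`fitted()` returns the full-model EI, which recovers each planted
inefficiency to within the 1% needs jitter; `summary(fit)` adds the
ensemble mean, SE and 95% CI per unit, and `coef(fit)` the mean indices.

On the bundled 2013 tables:

```r
tr <- brazil_transfers_2013()
required_increase(sum(tr$effective_bppp), sum(tr$projected_bppp))
#> 22.70728   # percent increase in BPPP transfers needed to reach the frontier

head(as.data.frame(reallocate(brazil_projection_2013(), "substitution",
                              pooled_effective = 2850.00)), 2)
#>   dmu_id program coefficient allocated
#> 1     TO    BCPA 0.005845210 16.658850
#> 2     TO    BPPP 0.004319155 12.309593
```

So under a pooled budget of R$ 2,850.00 million, Tocantins' equity-based
share of the BPPP would be about R$ 12.31 million.

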