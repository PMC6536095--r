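---
title: "Methods: the MDEA equity index and budget reallocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MDEA equity index and budget reallocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmequity)
```

## The model and its assumptions

`pharmequity` treats equity as a frontier problem. Units with similar
*needs* — chronic-disease prevalence, elderly population, low income —
should receive similar *service* levels; units receiving less than the best
observed practice for their needs profile carry a relative coverage
deficit. The output-oriented, variable-returns-to-scale (VRS) DEA
envelopment program formalises "best observed practice" as the convex hull
of the observed units: for unit $o$,

$$\max_{\varphi,\lambda}\ \varphi \quad\text{s.t.}\quad
X^\top\lambda \le x_o,\qquad Y^\top\lambda \ge \varphi\, y_o,\qquad
\mathbf{1}^\top\lambda = 1,\qquad \lambda \ge 0,$$

and the equity index is $EI = 1/\varphi$. The method is nonparametric and
relative: it assumes only free disposability and convexity of the
needs–services technology, and VRS (the convexity constraint on $\lambda$)
acknowledges that federative units differ enormously in scale. Output
orientation is the substantive choice — needs are fixed epidemiology;
transfers are the policy lever to be expanded.

Two conventions the algebra does not force, chosen and fixed here:

* **EI as the reciprocal of the expansion factor.** Any normalised
  distance to the frontier would do; $1/\varphi$ is adopted because it is
  the standard output-oriented efficiency score, lies in $(0,1]$ with the
  frontier at exactly 1, and reads directly as "share of the optimal
  service level actually delivered" — the published per-state capture
  percentages are consistent with this reading.
* **Slack treatment.** $\varphi$ alone measures radial expansion; a second
  LP phase maximises total slack at fixed $\varphi$, and the projected
  ("optimal") transfer is $\varphi y_o + s^+$, the Pareto-optimal peer
  target. Pure radial projection demonstrably understates the published
  projected values for strongly unbalanced units, so the peer target is
  the package's projection rule. Peer weights at the optimum need not be
  unique; only $\varphi$, $EI$ and the projected vector are contractual.

## The MDEA ensemble

With 27 units and 7 variables a single DEA model saturates: many units are
efficient by default. MDEA runs the DEA over **all** $(2^m-1)(2^s-1)$
non-empty subset pairs of needs and services (93 models for $5\times 2$)
and treats each unit's indices across submodels as a distribution. The
package reports its arithmetic mean, a standard error, and a normal 95%
interval $\bar{EI} \pm 1.96\,se$.

The SE definition is not derivable from the published table — both the
ensemble SD and SD$/\sqrt{n}$ satisfy the printed CI relation — so the
package defaults to the standard error of the mean (`se_mode =
"sd_over_sqrt_n"`) and exposes the alternative (`"sd"`). The interval is
deliberately **not** truncated at 1 (published upper bounds exceed 1), and
$z$ is fixed at 1.96 by default. Because submodels are enumerated, never
sampled, the fit is deterministic and bit-reproducible; dimension
monotonicity (adding variables never lowers an index) guarantees the
ensemble mean never exceeds the full-model index, which the tests assert.

A submodel whose selected services are all zero for a unit has no defined
radial expansion; such solves contribute $EI = 0$, are flagged, and are
counted per unit (`degenerate_count`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `se_mode` | `sd_over_sqrt_n` | ensemble SE definition (see above) |
| `z` | 1.96 | CI critical value |
| `epsilon` (income transform) | 0.01 | positive floor for the richest unit's need value |
| `pooled_effective` | exact sum | substitution-budget override for published rounded totals |
| `inefficiency_range` | (0.6, 1) | planted-inefficiency spread in the generator |
| `jitter` | 0.01 | upward needs perturbation of copied units |

The negative-income need is $(\max_j \text{inc}_j - \text{inc}_i)/s +
\varepsilon$ with $s$ the sample SD of income: strictly positive,
decreasing in income, unit-free. Any transform with those properties is
acceptable; this one is the default because DEA requires strictly positive
inputs with "larger = needier".

## Numerical choices

* **LP solver.** The envelopment LPs are tiny (about $n + 1 + m + s$
  variables, $m + s + 1$ rows) but heavily degenerate — feasible regions
  can collapse to a single point. The package ships a two-phase primal
  simplex with Bland's anti-cycling rule (lowest-index entering/leaving
  candidates) and an explicit $10^{-9}$ tolerance on every comparison,
  which is immune to the 0/0 ratio tests that break steepest-descent
  pivoting on such instances. The test suite validates it against an
  exhaustive grid search over the peer-weight simplex (coarse step 1/20,
  locally refined; the objective is concave, so refinement converges).
* **Frontier classification.** $\varphi$ within $10^{-9}$ of 1 snaps to 1;
  a unit is `on_frontier` when $\varphi \le 1 + 10^{-6}$ and all slacks
  are $\le 10^{-6}$.
* **Phase-2 feasibility.** Fixing $\varphi^\*$ exactly can be infeasible at
  solver tolerance; phase 2 retries with $\varphi^\*(1-10^{-10})$ and
  $\varphi^\*(1-10^{-8})$, then falls back to phase-1 residual slacks.
* **Degenerate targets.** All-zero selected services give $EI = 0$,
  flagged, excluded from the frontier; projection falls back to the
  effective value.
* **Rounding.** Full precision is kept internally; printed-precision
  rounding (coefficients to 3 decimals, values to 2) happens only in
  display methods and reports.

## Projections and reallocation

The reallocation formulas are not stated alongside the published tables;
they were reverse-engineered from the printed coefficients (e.g. $0.168 =
397.22/2360.30$) and adopted as the package's rule:

* **complementary**: $c_i^p = \hat{y}_i^p / \sum_j \hat{y}_j^p$,
  allocation $c_i^p \sum_j y_j^p$ — each program's own budget is conserved;
* **substitution**: $c_i^p = \hat{y}_i^p / \sum_{j,q} \hat{y}_j^q$,
  allocation $c_i^p \cdot B$ with $B$ the pooled budget — the pool is
  conserved,

where $y$ is effective, $\hat{y}$ projected. When run from the bundled
2013 tables the pooled budget uses the published total of 2,850.00 million
(the table's own column totals sum to 2,850.34 — a rounding artefact of
the source); from raw data the exact sum is used. Verified against the
published table, 106 of 108 state-level value cells reproduce within
±0.05 million; the two exceptions (Minas Gerais complementary BCPA, Rio
Grande do Sul complementary BPPP) are inconsistent with the published
table's own proportional rule and are documented as misprints in the test
suite rather than targeted.

## What the synthetic generator emulates — and what it does not

`simulate_states()` plants a known frontier: frontier units draw five
log-normal needs (location/spread matching the bundled descriptive table
in order of magnitude, with heavy right skew on the prevalence counts) and
receive two services as a concave increasing function of a normalised
aggregate need; every other unit copies a frontier anchor's needs,
jittered multiplicatively upward by at most 1%, with services on the
frontier curve at its own needs scaled by a planted $u \in (0,1]$. Upward
jitter keeps the anchor a feasible peer, so the full-model index recovers
$u$ up to a term of order the jitter (exactly at zero jitter), and a unit
with $u = 1$ lies exactly on the frontier. Defaults (27 units, 5 frontier,
$u \in (0.6, 1)$) mirror the observed setting: 27 federative units and
published index spread of roughly 0.62–1.

Randomness comes from one `set.seed(seed)` with a fixed draw order
(needs, then inefficiencies, then jitter), which makes every output
deterministic in the seed; R offers no counter-based stream, so
reproducibility is by draw-order convention rather than per-variable
substreams.

Deliberately **not** emulated: the real inter-state correlation structure
of needs, spatial autocorrelation, measurement error in survey prevalence,
and any dependence of services on politics or history. Passing recovery
tests therefore shows the estimator is correct on data satisfying the DEA
axioms with a planted truth — not that the 2013 indices themselves are
externally valid.

## Problem sizes and test design

The suites run the solver on randomized instances of up to 6 units and
3+2 variables against the grid oracle (20 seeds), full MDEA ensembles on
8–12 synthetic units (93 submodels each), and 20-seed recovery studies at
12 units — sizes chosen so the whole battery, about six thousand LP
solves, completes in well under a minute while exercising every code
path; the 27-unit default is used where only full-model solves are needed.
The published-table reproductions are pure arithmetic and run in
milliseconds.

## Known limitations

* The published 2013 equity indices cannot be recomputed from raw data
  (the per-state needs inputs were never released); the package reproduces
  every quantity derivable from the published tables and validates the
  estimator on synthetic truth instead.
* DEA measures *relative* equity against observed practice; if every unit
  under-serves, the frontier is too low and the indices are optimistic.
* The ensemble SE describes submodel dispersion, not sampling error; it is
  not a bootstrap of the frontier, and no smoothed-DEA inference is
  attempted.
* The deficit regression is a descriptive OLS on 27 points; with a noisy
  covariate its slope is attenuated toward zero, and no causal reading is
  intended.
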