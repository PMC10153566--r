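---
title: "Models, numerics and design choices in healtheff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in healtheff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healtheff)
```

# The two-stage efficiency workflow

The package implements the workflow commonly applied to regional health
systems: a panel of decision-making units (DMUs; city-years) converting
inputs (health technicians, beds, total expenditure) into outputs (visits,
discharges) is scored against an empirical best-practice frontier, the
scores are decomposed over time, and a second-stage regression relates them
to contextual covariates (income, population density, education, per-capita
GDP, urbanization). Nothing in the machinery is specific to health data;
the built-in schema and generator defaults are.

## Non-oriented SBM and its linearization

For DMU $k$ in a cross-section with input matrix $X$ ($n \times m$) and
output matrix $Y$ ($n \times s$), the slacks-based measure is

$$\rho_k = \min_{\lambda, s^-, s^+}
  \frac{1 - \frac1m \sum_a s_a^-/x_{ak}}
       {1 + \frac1s \sum_c s_c^+/y_{ck}}
  \quad \text{s.t.} \quad
  X^\top\lambda + s^- = x_k,\;
  Y^\top\lambda - s^+ = y_k,\;
  \lambda, s^-, s^+ \ge 0,$$

with $\sum_b \lambda_b = 1$ added under variable returns to scale (VRS).
The measure is non-oriented — input excess and output shortfall are
penalized symmetrically — which is why it is preferred over radial models
whose slacks are an afterthought. The linear-fractional program is
linearized by the Charnes–Cooper device: multiply all variables by a scalar
$t > 0$ chosen so the denominator equals one, which yields a single LP in
$(t, \Lambda, S^-, S^+)$; the reported slacks and weights are de-scaled by
$t$ afterwards. $\rho \in (0, 1]$ and $\rho = 1$ exactly when a zero-slack
solution exists.

Frontier DMUs ($\rho = 1$) are re-scored by the super-efficiency SBM: the
DMU leaves the reference set and the program finds the cheapest projection
point $\bar x \ge x_k$, $0 < \bar y \le y_k$ that the *remaining* hull
dominates, scored as $\delta = \frac{\frac1m\sum \bar x_a / x_{ak}}
{\frac1s\sum \bar y_c / y_{ck}} \ge 1$. `combined_score()` routes each DMU
to $\rho$ or $\delta$ with threshold $\rho \ge 1 - 10^{-6}$, producing the
mixed score column practitioners tabulate. A degenerate reading of the
published program (a bare ratio of slack means, 0/0 at zero slack) was
rejected in favour of this standard projection-ratio form — it is the model
the DEA-SOLVER "Super-SBM-V non-oriented" option computes, which is the
software the motivating study names.

Under VRS with the stated constraint set, the non-oriented super-efficiency
program is feasible whenever at least one other DMU exists (any simplex
$\lambda$ admits $\bar y = \min(Y^\top\lambda, y_k) > 0$); `status =
"infeasible"` is still reported honestly where it can occur (a lone DMU,
`n = 1`), and `score_matrix()` lets the caller choose between flag-and-omit
(default) and clamping such cells to 1.

## Malmquist decomposition

Adjacent-period productivity change uses the Fare et al. construction from
six radial LPs per DMU-pair. With $E_r(a)$ the Farrell efficiency of the
period-$a$ observation against the period-$r$ CRS frontier and $V_a(a)$ its
within-period VRS efficiency,

$$\mathrm{EFFCH} = \frac{E_{t+1}(t+1)}{E_t(t)}, \qquad
  \mathrm{TECHCH} = \sqrt{\frac{E_t(t+1)}{E_{t+1}(t+1)}\cdot
                          \frac{E_t(t)}{E_{t+1}(t)}},$$
$$\mathrm{PECH} = \frac{V_{t+1}(t+1)}{V_t(t)}, \qquad
  \mathrm{SECH} = \mathrm{EFFCH}/\mathrm{PECH}, \qquad
  \mathrm{TFPCH} = \mathrm{EFFCH}\times\mathrm{TECHCH}.$$

TFPCH and SECH are *defined* as the products/ratios, so the decomposition
identities hold to machine precision by construction; the LPs only have to
deliver the four CRS and two VRS efficiencies. Only CRS distances cross
periods (cross-period VRS programs can be infeasible, and the standard
decomposition never needs them). Orientation defaults to output — health
services are the maximand — and is configurable; under CRS the
TFPCH/TECHCH parts are orientation-robust.

Summary tables aggregate by **geometric** means per period pair, per DMU
and overall. The packaged published index table settles the convention:
the geometric mean of its eight printed TFPCH values reproduces the printed
Mean row (0.950) while the arithmetic mean does not (0.951). Geometric
averaging also preserves the product identities in every summary row.
Printed-table identity checks tolerate the propagation of two 3-decimal
roundings, a bound of about $1.6\times10^{-3}$ for values near 1.

## Tobit second stage

Scores are regressed on covariates by maximum-likelihood censored
regression: interior observations contribute normal log-densities,
censored ones tail log-probabilities. The optimizer is BFGS with an
analytic gradient in $(\beta, \log\sigma)$, started at the OLS solution
(with ML variance $\mathrm{RSS}/n$), so the uncensored special case
converges immediately to OLS exactly. Standard errors come from the inverse
observed information (numerical Hessian in $(\beta, \sigma)$ at the
optimum), inference uses the standard-normal reference (Stata-style
z-ratios and CIs), and an LR $\chi^2$ compares against the intercept-only
censored fit.

Censoring defaults are left limit 0, no upper limit. The classic DEA-Tobit
folklore censors on $(0, 1]$, but a *super*-efficiency dependent variable
exceeds 1 by design, so that cannot be what a published super-efficiency
Tobit ran; left-censoring at zero is the weakest faithful default, and both
limits are configurable. Covariate standardization is available but off by
default (the fit is invariant; only interpretation changes). The pooled
fit over all DMU-periods ignores within-DMU correlation — a known
limitation shared with the practice it reproduces, not a bug; see
Limitations.

## The synthetic world

`generate_panel()` draws the study conditions rather than arbitrary data:
19 DMUs over 9 consecutive years by default, with

* inputs log-normal across DMUs around published first-period means
  (16 157 technicians, 15 093 beds, 303 932 [10k yuan] expenditure), a
  common size factor with log-sd 0.9 producing the heavy right skew of
  one-metropolis provinces, and deterministic per-input growth (7.1%,
  8.9%, 17.1% per year) matching the published 2010→2018 trajectories;
* a Cobb–Douglas frontier $y_c = w_c A_t \prod_a x_a^{\alpha_a}$ with
  $\alpha = (0.45, 0.30, 0.25)$ (constant returns at the default sum of 1;
  the surface is concave and increasing, so its points are SBM-efficient
  under VRS), output share weights $w_c$ calibrated so first-period mean
  outputs land near the published 18.2M visits and 0.53M discharges, and
  Hicks-neutral technology level $A_t = (1 + g)^{t-1}$ with default
  $g = -0.05$, consistent with the published TFP decline (mean TFPCH
  0.950);
* inefficiency $u = \mathrm{softplus}(\mathrm{location} + \gamma^\top z +
  \nu)$ entering outputs as $e^{-u}$, with standardized covariates $z$
  correlated (0.6) with the size factor, persistent DMU noise $\nu$, and a
  45% frontier fraction ($u = 0$) matching the published share of
  DEA-effective cities. The softplus keeps the covariate→inefficiency link
  smooth and nonnegative; exact-recovery testing of the Tobit stage
  therefore uses `generate_tobit_data()` (a literal censored linear model)
  rather than scores from this link.

**The disaster-year shock.** A uniform rescaling of an output column is
absorbed by DEA's unit invariance, so a shock that multiplies *every*
DMU's visits by a common factor changes no score. The published
disaster-year column also shows the opposite of a uniform shock: the
metropolitan frontier's service volume surged while peripheral systems
collapsed to a fifth of their usual score. The generator therefore applies
the shock only to non-frontier DMUs, with DMU-specific severity drawn
uniformly in `[shock_factor, 1]` and `shock_factor = 0.25` by default,
which reproduces a period mean that is the panel minimum, as in the
published 2013 column.

What the generator does **not** emulate: spatial structure, within-DMU
serial correlation of the covariate noise, measurement error in inputs,
and any attempt to reconstruct actual city values. Passing tests on this
world therefore demonstrate solver correctness and calibration of the
estimators, not that real yearbook data would yield any particular score.

## Numerical choices

* **LP solver.** All envelopment programs are solved by a dense two-phase
  primal simplex (Bland's anti-cycling rule, pivot tolerance $10^{-9}$)
  written in the package; the programs have tens of variables, far below
  where sparse or interior-point machinery would matter. It is validated
  against hand-solved LPs, a vertex-enumeration oracle on random
  2-variable programs, and a simplex-grid SBM oracle.
* **Scaling.** Yearbook magnitudes (up to $10^8$) are hostile to fixed
  pivot tolerances, so every model first normalizes each measure column by
  the evaluated DMU's own value — a pure unit change under which all
  scores are invariant — and de-scales slacks and projections afterwards.
  Unit-invariance tests pin this at $10^{-7}$.
* **Tolerances.** Efficiency threshold for super-routing $10^{-6}$;
  feasibility identities at the SBM optimum checked to $10^{-7}$;
  decomposition identities $10^{-12}$ (exact by construction); Tobit
  convergence via BFGS `reltol` $10^{-14}$ with a guard against
  line-search overflow of $e^{\log\sigma}$.
* **Ties and degeneracy.** Any optimal $\lambda$ is acceptable; only
  optimal values feed downstream indices. Duplicated DMUs score 1 (a twin
  is a zero-slack reference; its super-efficiency is 1).
* **Rounding.** Full precision internally; 3-decimal scores and indices
  and 2-decimal percentages only in rendered CSV reports, matching the
  published table layouts.
* **Reproducibility.** One root seed; fixed per-component offsets derive
  substreams (inputs, covariates, inefficiency, shock) so adding a
  component never shifts existing draws; panel CSVs serialize at full
  precision so write→read is the identity.

## Problem sizes in the test and acceptance suites

The suites run the full 19×9 default world where the claim concerns it
(determinism, the disaster-year dip, calibration of 2018-analogue means)
and smaller worlds where the claim is solver-level: 8–12 DMUs over 2–3
periods for invariance, frontier-recovery and growth-recovery properties;
200 random instances with $n \le 3$, $m, s \le 2$ for the grid-oracle
comparison (the oracle's $10^{-3}$ simplex grid is only tractable at that
size); and 200 replicates of $n = 500$ for the Tobit recovery experiment
(~30% censoring, coefficient bias within 3 Monte-Carlo SEs, 95% CI
coverage within [0.91, 0.98]).

## Known limitations and recorded discrepancies

* The pooled Tobit ignores within-city correlation across years, and no
  Simar–Wilson-style bootstrap corrects the second stage for the
  first-stage estimation noise; both match common practice and the
  motivating study's design, not best econometric theory.
* No undesirable outputs, no window analysis or fixed-base Malmquist, no
  oriented SBM variants.
* The published tables the fixtures transcribe contain internal
  discrepancies which are preserved, not resolved: the study's abstract
  states a mean TFP of 0.930 while its index table and discussion give
  0.950 (the fixture reproduces 0.950); its text calls one city's 0.80 the
  2018 minimum while the table's 2018 column contains 0.801 < 0.861; and
  its conclusion says 20 cities where its methods (and the tables) have
  19.
* Whether the original DEA software clamped or dropped infeasible
  super-efficiency cells is not stated in the source; both policies are
  exposed.
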