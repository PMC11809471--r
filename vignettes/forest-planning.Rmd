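---
title: "Multi-objective forest planning with forestmop: models and methods"
author: "forestmop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective forest planning with forestmop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestmop)
```

## The planning problem

Forest simulators project, for every stand (or sample plot) and every
candidate management regime, a time series of indicators: harvested volume,
standing biomass, deadwood, structural and recreational indices.  The
planning question is which regime — or which fractional mix of regimes — to
assign to each stand so that the landscape as a whole balances several
competing objectives: steady timber flow, biodiversity retention, recreation.

The decision model is the classic stand-by-regime allocation ("Model I")
linear program.  For each simulated pair (stand $s$, regime $r$) there is a
share variable $x_{sr} \in [0,1]$ with $\sum_r x_{sr} = 1$ per stand.  A
missing (stand, regime) combination simply means the simulator did not run
that regime there, and no variable is created.  Fractional shares are the
default — the exported plan says how much of each stand is managed under
each regime — and a binary mode declares the same variables integral for
whole-stand assignments (a MILP).

Indicator values are treated as per-stand absolute quantities by default;
with `per_hectare = TRUE` they are interpreted as per-hectare rates and
multiplied by stand area during aggregation.  The yearly landscape aggregate
of indicator $d$ is the linear form

$$V_t(x) = \sum_s \sum_r x_{sr}\, w_s\, d_{srt},$$

with $w_s$ the area weight; `areaWeightedMean` divides by total area.

## Objectives

An objective declaration names an indicator, a sense (`max`/`min`), a
temporal operator, a spatial mode and, where needed, a parameter.  The
twelve temporal operators cover the recurring shapes of forest policy
targets; each is linearized with at most one auxiliary variable $m$ and one
inequality row per period:

| operator | value at a fixed allocation | LP form |
|---|---|---|
| `min` | $\min_t V_t$ (even-flow maximin) | $m \le V_t\ \forall t$, maximize $m$ |
| `average` | $\frac1T \sum_t V_t$ | linear |
| `firstYear`, `lastYear`, `targetYear` | $V_{t^*}$ | linear |
| `sum` | $\sum_t V_t$ | linear |
| `targetYearWithSlope` | $\min_{t \ge t^*} V_t / (1 + \text{slope}\,(t - t^*))$ | $m (1 + \text{slope}\,k) \le V_t$ |
| `periodicTargets` | $\min_t V_t/\tau_t$ (worst relative fulfilment) | $m\,\tau_t \le V_t$ |
| `maxYearlyIncrease` | $\min_k (V_{t_{k+1}} - V_{t_k})$ | $m \le V_{t_{k+1}} - V_{t_k}$ |
| `minYearlyIncrease` | $-\max_k (V_{t_{k+1}} - V_{t_k})$ | $M \ge V_{t_{k+1}} - V_{t_k}$, maximize $-M$ |
| `maxIncreaseDuringNPeriods` | $\min_k (V_{t_{k+N}} - V_{t_k})$ | window analogue |
| `minDecreaseDuringNPeriods` | $-\max_k (V_{t_k} - V_{t_{k+N}})$ | window analogue |

Three interpretation choices were genuinely open and are resolved as
follows:

* **"Yearly" means consecutive data periods.**  Simulators emit annual or
  5-year periods; differences are taken between consecutive available
  labels, never calendar-interpolated.
* **`minYearlyIncrease` / `minDecreaseDuringNPeriods` are smooth-flow
  (minimax) operators**: "minimize the yearly increase" is read as
  minimizing the *largest* per-period change, expressed as a negated
  maximum to stay in canonical maximization form.  This is the only reading
  that stays linear.
* **`targetYearWithSlope`** is read as "reach a level by the target year and
  sustain it, growing at a relative per-period rate `slope` afterwards";
  pre-target years are unconstrained and `slope` defaults to 0.

Everything is kept in canonical **maximization** form.  A `sense = "min"`
objective negates the yearly aggregates *before* the temporal operator is
applied, so `min` + `min` means "minimize the peak".  (Negating the finished
expression instead would make the auxiliary-variable operators unbounded.)
For the purely linear operators both readings coincide and the compiled
expressions of a min/max pair are exact negations.  `periodicTargets` keeps
its positive targets in either sense; with `sense = "min"` the ratio rows
flip to $V_t \le m\,\tau_t$ and the worst relative *exceedance* is
minimized.

## Structural constraints

Two families cover the common non-optimized requirements:

* **`allowed_regimes`** — on stands carrying a boolean flag (e.g. `PEAT`),
  only a listed set of regimes may be used.  Implemented by fixing the
  disallowed $x_{sr}$ to 0; a flagged stand with no allowed regime simulated
  triggers an explicit infeasibility warning naming the stand.
* **`indicator_threshold`** — a no-decline rule: $V_t \ge \alpha V_{t_1}$
  for all later years, with both sides linear in $x$, so the baseline is the
  plan's *own* first-year aggregate rather than a pre-computed constant.
  $\alpha = 1$ forbids any decline; $\alpha$ is configurable per constraint.

Epsilon-constraints bound individual objectives from below
($F_i(x) \ge \varepsilon_i$ in canonical max form), turning a preference
into a hard feasibility requirement.

## Payoff table and the reference-point solve

With $n$ objectives, $n$ single-objective maximizations over the feasible
set (structural constraints included, preferences excluded — a deliberate
choice, since the preference sliders derive their ranges from this table)
give the payoff matrix: row $i$ holds every objective's value at the
solution maximizing objective $i$.  The diagonal is the ideal vector
$z^{ideal}$; the column minima estimate the nadir $z^{nadir}$.  For more
than two objectives the column-minimum nadir is a known, accepted
approximation that can be too optimistic.

Preferences enter as a reference point $z^{ref}$ of aspiration levels.  The
solver maximizes the augmented Chebyshev achievement scalarizing function

$$\max_{x \in S}\ \min_{1 \le i \le n}
  \frac{F_i(x) - z^{ref}_i}{z^{ideal}_i - z^{nadir}_i}
  \;+\; \rho \sum_{i=1}^n \frac{F_i(x)}{z^{ideal}_i - z^{nadir}_i},$$

subject to the epsilon rows.  The min-max term is linearized with a single
scalar $\alpha \le (F_i - z^{ref}_i)/r_i$; the augmentation term with small
$\rho > 0$ guarantees that the optimum is Pareto optimal rather than merely
weakly so.  Normalization by the ranges $r_i$ makes the solve invariant
under rescaling an indicator (and its aspiration) by any constant.

Parameter choices:

* `rho = 1e-6` by default.  Any small positive value works in exact
  arithmetic; the value is exposed because the right magnitude depends on
  the solver's tolerances (see below).  A warning fires above `1e-3`, where
  the augmentation visibly distorts the compromise.
* `range_floor = 1e-9`: an objective whose ideal-nadir range collapses
  (constant over the feasible set) is normalized by 1 instead, with a
  warning, rather than dividing by ~0.
* Aspiration levels outside $[z^{nadir}, z^{ideal}]$ are clamped into the
  box, with a warning — the same semantics as preference sliders bounded by
  the payoff table.  Objectives without an aspiration default to their
  ideal.

Infeasibility is reported with a diagnosis rather than an irreducible
infeasible set: solver status plus any $\varepsilon_i$ exceeding its payoff
ideal, which is the usual culprit in interactive use.

## Numerical choices

* **Solver backend.**  Model construction, evaluation and verification are
  pure R; the LP/MILP solves are delegated to HiGHS through
  `scipy.optimize` in a `python` subprocess, behind a minimal
  rows-in/values-out interface that any LP backend could implement.
  Several objective vectors sharing one constraint matrix are solved per
  subprocess call, which is exactly what the payoff table needs.
* **Tolerances.**  Continuous solves run with primal/dual feasibility
  tolerances of `1e-9`.  This matters: with the default dual tolerance
  (`1e-7`) the $\rho = 10^{-6}$ augmentation term can be smaller than the
  solver's optimality slack, and a weakly-optimal (dominated) vertex can be
  returned.
* **Verification, not trust.**  Every reported objective value is
  recomputed from the shares and the raw indicator table by plain
  arithmetic; `verify_solution()` re-evaluates every constraint row at the
  returned point.  Tests compare objective values, never vertex identity,
  because degenerate optima are legitimately solver-dependent.
* **Determinism.**  For a fixed solver backend the pipeline is
  deterministic; exports are written with 6 significant digits so repeated
  runs are byte-identical, and the data writer uses 17 significant digits
  so a load-write-load round trip is bit-exact.

## The synthetic landscape generator

Testing an optimizer needs data with the right *structure*, not
silvicultural realism.  The generator draws per-stand latent state (site
quality, initial stock, deciduous propensity, phase) and rolls each regime
forward with simple parametric rules: logistic stock growth, clear-cut
pulses under rotation regimes, lighter/rarer cuts under extensive regimes,
periodic partial harvest under continuous-cover regimes, and zero harvest
with strictly accumulating deadwood under set-aside.  Multiplicative
lognormal noise (default sd 0.1) roughens the trajectories; a fifth of the
stands get a `PEAT` flag; areas are drawn from 0.5–5 ha.  Defaults (5
regimes, 2016 start, 5-year periods, 21 periods) mirror the shape of
national-scale simulator exports.

What this emulates: divergent indicator trajectories across regimes on a
shared year grid — the feature the optimizer actually consumes.  What it
does not: growth-model fidelity, climate response, inter-stand spatial
structure, price dynamics.  Passing tests therefore demonstrate correctness
of the *optimization machinery* on structurally realistic inputs, not
ecological validity of any particular plan.

## What the tests establish, and at what sizes

* On small seeded landscapes (2–4 stands, 2–3 regimes, 3 periods) the
  whole-stand problem is solved twice: by the package and by exhaustive
  enumeration of all regime assignments with plain-loop arithmetic.  The
  scalarization optimum matches enumeration to $10^{-6}$; the continuous
  optimum is never dominated by any enumerated assignment; achievable
  reference points (inside the payoff box) are met in every coordinate.
  Twenty such instances are used — small enough to enumerate, large enough
  to hit all operator/indicator combinations.
* A worked 1-stand, 2-regime, single-year problem has closed-form optima
  and a $10^4$-point grid-search oracle over the single share.
* The twelve temporal operators are checked against hand arithmetic on
  fixed sequences, both via the direct evaluator and via the LP
  linearization with the allocation frozen.
* A representative national-scale instance — 1,000 stands × 7 regimes × 21
  periods, four objectives, three no-decline constraints — builds and
  solves continuously in well under a minute on one CPU, and the no-decline
  rows hold on independent re-evaluation.  The bundled acceptance script
  runs a 300-stand version of the same scenario as a compact reproducible
  summary.

## Known limitations

* No spatial adjacency or green-up constraints, and no NPV/discounted
  economics: objectives are linear in the yearly aggregates.
* The nadir estimate can be optimistic for $n > 2$ objectives; achievements
  near 0 should be read with that in mind.
* Reference-point interaction is the only preference mechanism (no NIMBUS
  classification, no Pareto-front sampling).
* Fractional shares assume stands are divisible; use binary mode when they
  are not, at MILP cost.
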