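# forestmop — multi-objective optimization for forest planning

`forestmop` builds and solves multi-objective forest-planning problems from
long-format forest-simulator output.  It is written for forest planners and
policy analysts who have per-stand, per-regime indicator projections
(harvested volume, deadwood, recreation indices, ...) and need a management
portfolio — which regime, or which mix of regimes, on each stand — that
balances competing objectives such as even timber flow, biodiversity
retention and recreation.

## The model

Each simulated (stand *s*, regime *r*) pair gets a share variable
*x*<sub>*sr*</sub> ∈ [0, 1] with Σ<sub>*r*</sub> *x*<sub>*sr*</sub> = 1 per
stand (the classic Model I harvest-scheduling LP; a binary mode forces
whole-stand assignments).  Objectives are declared as descriptors — an
indicator, a sense, one of twelve temporal operators (even-flow maximin,
average, target year with sustained growth, yearly-change smoothing, ...)
and a spatial aggregation — and compiled into linear expressions.  From *n*
single-objective optima the package assembles the payoff table, whose
diagonal is the ideal vector *z*<sup>ideal</sup> and whose column minima
estimate the nadir *z*<sup>nadir</sup>.  Preferences enter as a reference
point *z*<sup>ref</sup> of aspiration levels, and the solver maximizes the
augmented Chebyshev achievement scalarizing function

```
max over x in S of   min_i (F_i(x) − z_i^ref) / (z_i^ideal − z_i^nadir)
                     + ρ Σ_i F_i(x) / (z_i^ideal − z_i^nadir)
subject to           F_i(x) ≥ ε_i  for every epsilon-constraint
```

whose optimum is a Pareto optimal plan (ρ > 0 small, default 1e-6).
Structural constraints restrict regimes on flagged stands (e.g. only
continuous-cover or set-aside on peatland) or forbid an indicator's
landscape aggregate from declining below a fraction of its own first-year
value.  The methods vignette (`vignettes/forest-planning.Rmd`) derives all
of this in detail.

LP/MILP solving is delegated to HiGHS via `scipy.optimize` in a `python`
subprocess; everything else — compilation, evaluation, verification — is R.

## Worked example

One stand, two regimes, one year: regime A yields 10 units of harvest and
no deadwood, regime B no harvest and 8 units of deadwood.

```r
library(forestmop)

fd <- forest_data(data.frame(
  stand = "S1", regime = c("A", "B"), year = 2020,
  harvest = c(10, 0), deadwood = c(0, 8)
))
objectives <- list(
  objective_spec("harvest",  "harvest",  temporal = "firstYear"),
  objective_spec("deadwood", "deadwood", temporal = "firstYear")
)
problem <- build_problem(fd, objectives)
payoff  <- compute_payoff(problem)
payoff
#> Payoff table (row i = solution maximizing objective i):
#>          harvest deadwood
#> harvest       10        0
#> deadwood       0        8
#> ideal: harvest=10  deadwood=8
#> nadir: harvest=0  deadwood=0

solve_scalarized(problem, payoff, ref = payoff$ideal)
#> <forest_solution: optimal>
#>   ASF value: -0.5 (worst normalized deviation -0.5)
#>   harvest: 5 (achievement 0.5)
#>   deadwood: 4 (achievement 0.5)
```

Aspiring to both ideals at once, the Chebyshev compromise splits the stand
50/50: each objective reaches half its range (harvest 5 of 10, deadwood 4
of 8), and the worst normalized deviation from the reference point is 0.5.
Adding `eps = list(harvest = 8)` forces harvest to at least 8 and the
solution moves to (8, 1.6) — the best attainable deadwood once 80% of the
stand must be managed under regime A.

For realistic runs, scenarios live in one YAML file (data path and schema,
objective and constraint descriptors, reference point, epsilons) and
execute end to end with `run_scenario("scenario.yaml")`, which writes
`stand_solution.csv` (per-stand regime shares), `aggregate_solution.csv`
(yearly landscape indicator totals under the plan), `payoff.csv`,
`achievement.csv` and summary figures.  A command-line front end wraps the
same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/forestmop.R", package="forestmop"))') \
    solve --config scenario.yaml --out results/
```

with subcommands `synth` (seeded synthetic landscapes), `validate`,
`payoff`, `solve` and `interactive` (a REPL preference loop: move an
aspiration, re-solve, compare).

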