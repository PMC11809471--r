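Package: forestmop
Title: Interactive Multi-Objective Optimization for Forest Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves multi-objective forest-planning problems from
    long-format forest-simulator output. Stand-by-regime indicator
    trajectories are compiled into linear programs; objectives are declared
    with one of twelve temporal operators (even-flow maximin, averages,
    target years, yearly-change smoothing) and a spatial aggregation mode;
    structural constraints restrict management regimes on flagged stands or
    forbid indicator declines. Ideal and nadir values are estimated from a
    payoff table of single-objective optima, and Pareto optimal management
    portfolios are found by maximizing an augmented Chebyshev achievement
    scalarizing function around a user-supplied reference point, subject to
    epsilon-constraints. Includes a seeded generator of simulator-like
    synthetic landscapes, scenario configuration files, solution export, and
    summary plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
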