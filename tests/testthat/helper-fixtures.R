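# Fixtures built in code: everything is generated at test time.

# One stand, two regimes, one year: harvest favors A, deadwood favors B.
toy_fd <- function() {
  forest_data(data.frame(
    stand = "S1", regime = c("A", "B"), year = 2020,
    harvest = c(10, 0), deadwood = c(0, 8),
    stringsAsFactors = FALSE
  ))
}

toy_objectives <- function() {
  list(
    objective_spec("harvest", "harvest", temporal = "firstYear"),
    objective_spec("deadwood", "deadwood", temporal = "firstYear")
  )
}

toy_problem <- function(binary = FALSE) {
  build_problem(toy_fd(), toy_objectives(), binary = binary)
}

# One stand, one regime, a fixed aggregate sequence V over three years: the
# only feasible allocation realizes exactly V, so temporal operators can be
# checked against hand arithmetic.
seq_fd <- function(V = c(3, 5, 4), years = c(2020, 2025, 2030)) {
  forest_data(data.frame(
    stand = "S1", regime = "A", year = years, ind = V,
    stringsAsFactors = FALSE
  ))
}

# Specs exercising all 12 temporal operators on seq_fd years.
all_operator_specs <- function(years = c(2020, 2025, 2030), slope = 0) {
  tau <- stats::setNames(rep(2, length(years)), years)
  list(
    objective_spec("t_min", "ind", temporal = "min"),
    objective_spec("t_average", "ind", temporal = "average"),
    objective_spec("t_firstYear", "ind", temporal = "firstYear"),
    objective_spec("t_sum", "ind", temporal = "sum"),
    objective_spec("t_targetYear", "ind", temporal = "targetYear",
                   param = years[2]),
    objective_spec("t_targetYearWithSlope", "ind",
                   temporal = "targetYearWithSlope", param = years[2],
                   slope = slope),
    objective_spec("t_lastYear", "ind", temporal = "lastYear"),
    objective_spec("t_periodicTargets", "ind", temporal = "periodicTargets",
                   param = tau),
    objective_spec("t_minYearlyIncrease", "ind", temporal = "minYearlyIncrease"),
    objective_spec("t_maxYearlyIncrease", "ind", temporal = "maxYearlyIncrease"),
    objective_spec("t_minDecreaseDuringNPeriods", "ind",
                   temporal = "minDecreaseDuringNPeriods", param = 1),
    objective_spec("t_maxIncreaseDuringNPeriods", "ind",
                   temporal = "maxIncreaseDuringNPeriods", param = 1)
  )
}

# Value of a compiled objective at a fixed allocation, obtained by fixing the
# allocation variables and letting the solver tighten the auxiliary; several
# keys are evaluated in one solver call.
compiled_values_at <- function(problem, x) {
  lp <- forestmop:::lp_clone(problem$lp)
  for (j in seq_len(problem$n_alloc)) forestmop:::lp_fix_var(lp, j, x[j])
  objs <- lapply(problem$compiled, function(co) {
    forestmop:::linform_dense(co$expr, lp$n_var)
  })
  sols <- forestmop:::lp_solve(lp, unname(objs))
  vapply(seq_along(objs), function(i) {
    sols[[i]]$objective + problem$compiled[[i]]$expr$const
  }, numeric(1)) |> stats::setNames(names(problem$compiled))
}

# Small seeded problem instances for the enumeration-oracle checks:
# 2-4 stands, 2-3 regimes, 3 periods, 2-3 objectives from a fixed operator
# pool.
make_instance <- function(seed) {
  set.seed(seed)
  n_stands <- sample(2:4, 1)
  regimes <- list(
    c(BAU = "rotation", SA = "set_aside"),
    c(BAU = "rotation", CCF = "ccf", SA = "set_aside"),
    c(EXT = "extensive", CCF = "ccf", SA = "set_aside")
  )[[sample(3, 1)]]
  fd <- generate_forest(synth_config(
    n_stands = n_stands, regimes = regimes, n_periods = 3,
    seed = seed + 1000L, noise_sd = 0.15
  ))
  ops <- c("min", "average", "sum", "targetYear", "maxYearlyIncrease")
  inds <- c("harvested_volume", "biomass", "deadwood_volume",
            "deciduous_share", "large_trees", "recreation_index")
  n_obj <- sample(2:3, 1)
  specs <- lapply(seq_len(n_obj), function(i) {
    op <- sample(ops, 1)
    objective_spec(
      paste0("obj", i), sample(inds, 1), temporal = op,
      param = if (op == "targetYear") sample(fd$years, 1) else NULL
    )
  })
  list(fd = fd, specs = specs, seed = seed)
}
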