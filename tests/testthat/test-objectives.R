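test_that("objective descriptors are validated field by field", {
  expect_error(objective_spec("k", "v", sense = "up", temporal = "min"), "sense")
  expect_error(objective_spec("k", "v", temporal = "median"), "temporal")
  expect_error(objective_spec("k", "v", temporal = "min", spatial = "mode"),
               "spatial")
  # param present exactly when the operator requires it
  expect_error(objective_spec("k", "v", temporal = "targetYear"), "requires a param")
  expect_error(objective_spec("k", "v", temporal = "min", param = 3), "no param")
  expect_error(objective_spec("k", "v", temporal = "periodicTargets",
                              param = c(1, 2)), "named")
  expect_error(objective_spec("k", "v", temporal = "periodicTargets",
                              param = c("2020" = -1)), "positive")
  expect_error(objective_spec("k", "v", temporal = "sum", slope = 0.1), "slope")
  expect_s3_class(objective_spec("k", "v", temporal = "targetYear", param = 2020),
                  "objective_spec")
})

test_that("per-year aggregation produces the defining linear forms", {
  pr <- toy_problem()
  forms <- aggregate_per_year(pr, "harvest", "sum")
  expect_length(forms, 1)
  f <- forms[[1]]
  # 7 x_A + 3 x_B shape: here 10 x_A + 0 x_B, zero coefficients dropped
  jA <- pr$vars$var[pr$vars$regime == "A"]
  expect_equal(f$j, jA)
  expect_equal(f$a, 10)
  expect_error(aggregate_per_year(pr, "nope"), "unknown indicator")
  expect_error(aggregate_per_year(pr, "harvest", "fancy"), "spatial")
})

test_that("area-weighted mean divides the area-weighted sum by total area", {
  d <- data.frame(stand = c("s1", "s2"), regime = "A", year = 2020,
                  v = c(10, 20), stringsAsFactors = FALSE)
  info <- data.frame(stand = c("s1", "s2"), area = c(2, 3))
  pr <- build_problem(forest_data(d, info),
                      list(objective_spec("m", "v", temporal = "firstYear",
                                          spatial = "areaWeightedMean")),
                      per_hectare = TRUE)
  f <- aggregate_per_year(pr, "v", "areaWeightedMean")[[1]]
  expect_equal(forestmop:::linform_eval(f, rep(1, pr$n_alloc)), (2 * 10 + 3 * 20) / 5)
})

test_that("all 12 temporal operators match direct arithmetic on V = [3,5,4]", {
  fd <- seq_fd(c(3, 5, 4))
  specs <- all_operator_specs()
  pr <- build_problem(fd, specs)
  expected <- c(
    t_min = 3, t_average = 4, t_firstYear = 3, t_sum = 12,
    t_targetYear = 5, t_targetYearWithSlope = 4, t_lastYear = 4,
    t_periodicTargets = 1.5,           # min(3,5,4)/2
    t_minYearlyIncrease = -2,          # -max(+2, -1)
    t_maxYearlyIncrease = -1,          # min(+2, -1)
    t_minDecreaseDuringNPeriods = -1,  # -max(-2, +1)
    t_maxIncreaseDuringNPeriods = -1   # min(+2, -1)
  )
  # direct arithmetic evaluator
  direct <- vapply(specs, evaluate_objective, numeric(1),
                   V = c(3, 5, 4), years = fd$years)
  names(direct) <- names(expected)
  expect_equal(direct, expected)
  # independent plain-loop oracle agrees
  oracle <- vapply(specs, function(sp) {
    oracle_objective(fd, c(S1 = "A"), sp)
  }, numeric(1))
  expect_equal(unname(oracle), unname(expected))
  # the LP linearization, solved with the allocation fixed, agrees
  compiled <- compiled_values_at(pr, rep(1, pr$n_alloc))
  expect_equal(compiled, expected, tolerance = 1e-9)
})

test_that("targetYearWithSlope discounts post-target years by the slope", {
  fd <- seq_fd(c(3, 5, 4))
  sp <- objective_spec("s", "ind", temporal = "targetYearWithSlope",
                       param = 2020, slope = 0.5)
  # min(3/1, 5/1.5, 4/2) = 2
  expect_equal(evaluate_objective(sp, c(3, 5, 4), fd$years), 2)
  pr <- build_problem(fd, list(sp))
  expect_equal(unname(compiled_values_at(pr, rep(1, pr$n_alloc))), 2,
               tolerance = 1e-9)
})

test_that("compiled and direct values agree for random fractional allocations", {
  fd <- generate_forest(synth_config(n_stands = 3, n_periods = 4, seed = 21))
  tau <- stats::setNames(rep(50, 4), fd$years)
  specs <- list(
    objective_spec("a", "biomass", temporal = "min"),
    objective_spec("b", "deadwood_volume", temporal = "average"),
    objective_spec("c", "harvested_volume", temporal = "maxYearlyIncrease"),
    objective_spec("d", "large_trees", temporal = "minDecreaseDuringNPeriods",
                   param = 2),
    objective_spec("e", "deadwood_volume", temporal = "periodicTargets",
                   param = tau),
    objective_spec("f", "biomass", temporal = "targetYearWithSlope",
                   param = fd$years[2], slope = 0.2)
  )
  pr <- build_problem(fd, specs)
  set.seed(99)
  for (rep_i in 1:3) {
    # random point on each stand's simplex
    x <- numeric(pr$n_alloc)
    for (s in unique(pr$vars$stand)) {
      j <- pr$vars$var[pr$vars$stand == s]
      w <- stats::runif(length(j))
      x[j] <- w / sum(w)
    }
    direct <- forestmop:::evaluate_all_objectives(pr, x)
    compiled <- compiled_values_at(pr, x)
    expect_equal(compiled, direct, tolerance = 1e-7)
  }
})

test_that("compilation adds at most one auxiliary variable and T rows", {
  fd <- seq_fd(c(3, 5, 4))
  T_ <- length(fd$years)
  for (sp in all_operator_specs()) {
    pr <- build_problem(fd, list(sp))
    co <- pr$compiled[[1]]
    expect_lte(length(co$aux), 1)
    expect_lte(length(co$aux_rows), T_)
  }
})

test_that("min- and max-sense expressions are exact negations for linear operators", {
  fd <- seq_fd(c(3, 5, 4))
  for (op in c("average", "sum", "firstYear", "lastYear", "targetYear")) {
    param <- if (op == "targetYear") fd$years[2] else NULL
    up <- objective_spec("up", "ind", sense = "max", temporal = op, param = param)
    dn <- objective_spec("dn", "ind", sense = "min", temporal = op, param = param)
    pr <- build_problem(fd, list(up, dn))
    eu <- pr$compiled$up$expr
    ed <- pr$compiled$dn$expr
    expect_equal(ed$j, eu$j)
    expect_equal(ed$a, -eu$a)
    v <- c(3, 5, 4)
    expect_equal(evaluate_objective(dn, v, fd$years),
                 -evaluate_objective(up, v, fd$years))
  }
  # min-sense flips the aggregates before envelope operators: "min the peak"
  dn_min <- objective_spec("d", "ind", sense = "min", temporal = "min")
  expect_equal(evaluate_objective(dn_min, c(3, 5, 4), fd$years), -5)
})

test_that("operator parameter errors name the problem", {
  fd <- seq_fd(c(3, 5, 4))
  bad_year <- objective_spec("k", "ind", temporal = "targetYear", param = 1999)
  expect_error(build_problem(fd, list(bad_year)), "1999")
  wide <- objective_spec("k", "ind", temporal = "maxIncreaseDuringNPeriods",
                         param = 3)
  expect_error(build_problem(fd, list(wide)), "smaller than the number of periods")
  partial <- objective_spec("k", "ind", temporal = "periodicTargets",
                            param = c("2020" = 1))
  expect_error(build_problem(fd, list(partial)), "every year")
})
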