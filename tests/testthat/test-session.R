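write_toy_scenario <- function(dir) {
  csv <- file.path(dir, "toy.csv")
  writeLines(c(
    "standid,regime,year,harvest,deadwood",
    "S1,A,2020,10,0",
    "S1,B,2020,0,8"
  ), csv)
  yml <- file.path(dir, "scenario.yaml")
  writeLines(c(
    "data:",
    "  path: toy.csv",
    "objectives:",
    "  - key: harvest",
    "    label: harvested volume first year",
    "    indicator: harvest",
    "    sense: max",
    "    temporal: firstYear",
    "    spatial: sum",
    "  - key: deadwood",
    "    label: deadwood first year",
    "    indicator: deadwood",
    "    sense: max",
    "    temporal: firstYear",
    "    spatial: sum",
    "reference_point:",
    "  harvest: 10",
    "  deadwood: 8",
    "params:",
    "  rho: 1.0e-6"
  ), yml)
  yml
}

test_that("a YAML scenario runs end to end and reproduces the toy optimum", {
  dir <- withr::local_tempdir()
  yml <- write_toy_scenario(dir)
  config <- read_scenario(yml)
  expect_s3_class(config, "scenario_config")
  out <- file.path(dir, "out")
  res <- run_scenario(config, out_dir = out)
  expect_equal(res$solution$status, "optimal")
  expect_equal(unname(res$solution$objective_values), c(5, 4), tolerance = 1e-6)
  expect_equal(unname(res$solution$achievements), c(0.5, 0.5), tolerance = 1e-6)

  st <- res$export$stand_table
  expect_equal(nrow(st), 2)
  expect_equal(st$share, c(0.5, 0.5), tolerance = 1e-6)
  expect_true(all(file.exists(file.path(out, c(
    "stand_solution.csv", "aggregate_solution.csv", "payoff.csv",
    "achievement.csv"
  )))))
})

test_that("scenario validation rejects bad configurations", {
  expect_error(scenario_config(objectives = list()), "no objectives")
  o <- list(key = "a", indicator = "v", temporal = "sum")
  expect_error(scenario_config(objectives = list(o, o)), "duplicate objective")
  expect_error(
    scenario_config(objectives = list(o), epsilon = list(zzz = 1)),
    "undeclared"
  )
  expect_error(
    scenario_config(objectives = list(o), reference_point = list(zzz = 1)),
    "undeclared"
  )
})

test_that("preference updates reuse the payoff table; toggles recompute it", {
  fd <- generate_forest(synth_config(n_stands = 4, n_periods = 3, seed = 41))
  config <- scenario_config(
    objectives = list(
      objective_spec("flow", "harvested_volume", temporal = "average"),
      objective_spec("dw", "deadwood_volume", temporal = "lastYear")
    ),
    constraints = list(
      constraint_spec("nd", "indicator_threshold", indicator = "biomass",
                      enabled = FALSE)
    )
  )
  ses <- forest_session(config, fd = fd)
  po_before <- ses$payoff
  pr_before <- ses$problem
  s1 <- update_preferences(ses)
  s2 <- update_preferences(ses, ref = c(flow = mean(c(po_before$ideal["flow"],
                                                      po_before$nadir["flow"]))))
  # cached across preference changes: same problem environment, same payoff
  expect_true(identical(ses$problem, pr_before))
  expect_identical(ses$payoff, po_before)

  # identical preferences give identical objective vectors
  s3 <- update_preferences(ses)
  expect_equal(s3$objective_values, s2$objective_values, tolerance = 1e-9)

  # enabling a structural constraint recompiles the problem and payoff
  s4 <- update_preferences(ses, enable = "nd")
  expect_false(identical(ses$problem, pr_before))
  expect_true(all(ses$payoff$ideal <= po_before$ideal + 1e-6))

  # relaxation: disabling it again never worsens the optimum
  s5 <- update_preferences(ses, disable = "nd")
  expect_gte(s5$scalar_value, s4$scalar_value - 1e-6)

  expect_error(update_preferences(ses, enable = "nope"), "unknown constraint")
})

test_that("an infeasible preference set keeps the previous solution", {
  pr_cfg <- scenario_config(objectives = toy_objectives())
  ses <- forest_session(pr_cfg, fd = toy_fd())
  good <- update_preferences(ses)
  expect_equal(good$status, "optimal")
  expect_message(
    kept <- update_preferences(ses, eps = c(harvest = 11)),
    "infeasible"
  )
  expect_identical(kept$objective_values, good$objective_values)
  expect_identical(ses$solution$status, "optimal")
  # history keeps both attempts
  expect_length(ses$history, 2)
  expect_equal(ses$history[[2]]$status, "infeasible")
})

test_that("exports are independently recomputable and byte-identical across runs", {
  dir <- withr::local_tempdir()
  fd <- generate_forest(synth_config(n_stands = 5, n_periods = 4, seed = 51))
  config <- scenario_config(
    objectives = list(
      objective_spec("flow", "harvested_volume", temporal = "min"),
      objective_spec("rec", "recreation_index", temporal = "average")
    )
  )
  out1 <- file.path(dir, "a"); out2 <- file.path(dir, "b")
  r1 <- run_scenario(config, fd = fd, out_dir = out1, plots = FALSE)
  r2 <- run_scenario(config, fd = fd, out_dir = out2, plots = FALSE)
  for (f in c("stand_solution.csv", "aggregate_solution.csv", "payoff.csv",
              "achievement.csv")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }

  # shares sum to one per stand
  st <- r1$export$stand_table
  sums <- tapply(st$share, st$stand, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # aggregates equal a plain-arithmetic recomputation from shares and raw data
  pr <- r1$session$problem
  agg <- r1$export$aggregate_table
  expect_equal(nrow(agg), length(fd$years) * length(fd$indicators))
  share_of <- stats::setNames(numeric(pr$n_alloc), paste(pr$vars$stand,
                                                         pr$vars$regime))
  share_of[paste(st$stand, st$regime)] <- st$share
  for (k in sample(nrow(agg), 10)) {
    y <- agg$year[k]; ind <- agg$indicator[k]
    sel <- fd$data$year == y
    manual <- sum(fd$data[[ind]][sel] *
                    share_of[paste(fd$data$stand[sel], fd$data$regime[sel])])
    expect_equal(agg$value[k], manual, tolerance = 1e-6)
  }
})

test_that("binary-mode exports contain only whole-stand assignments", {
  fd <- generate_forest(synth_config(n_stands = 4, n_periods = 3, seed = 61))
  config <- scenario_config(
    objectives = list(
      objective_spec("flow", "harvested_volume", temporal = "min"),
      objective_spec("dw", "deadwood_volume", temporal = "lastYear")
    ),
    binary = TRUE
  )
  res <- run_scenario(config, fd = fd, out_dir = NULL, plots = FALSE)
  expect_true(all(abs(res$export$stand_table$share - 1) < 1e-6))
  expect_equal(nrow(res$export$stand_table), 4)
})

test_that("plots are written when ggplot2 is available and never abort", {
  skip_if_not_installed("ggplot2")
  dir <- withr::local_tempdir()
  yml <- write_toy_scenario(dir)
  res <- run_scenario(read_scenario(yml), out_dir = file.path(dir, "out"))
  figs <- list.files(file.path(dir, "out", "figures"), pattern = "\\.png$")
  expect_setequal(figs, c("management_portfolio.png", "achievement.png",
                          "indicators.png"))
})
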