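# Scenario orchestration.
#
# A scenario is one declarative YAML file: where the simulator data lives,
# the objectives and structural constraints, and the current preferences
# (reference point, epsilon bounds, constraint toggles).  A session keeps
# the compiled problem and payoff table alive between preference updates, so
# the interactive loop (GUI-style "move a slider, re-solve") only re-runs
# the cheap scalarized solve; toggling structural constraints invalidates
# the payoff table and recomputes it.

.as_objective_spec <- function(rec) {
  if (inherits(rec, "objective_spec")) return(rec)
  param <- rec$param
  if (!is.null(param) && identical(rec$temporal, "periodicTargets")) {
    param <- unlist(param)
  }
  objective_spec(
    key = rec$key, indicator = rec$indicator,
    sense = rec$sense %||% "max", temporal = rec$temporal,
    spatial = rec$spatial %||% "sum", param = param,
    slope = rec$slope %||% 0, label = rec$label %||% rec$key
  )
}

.as_constraint_spec <- function(rec) {
  if (inherits(rec, "constraint_spec")) return(rec)
  constraint_spec(
    key = rec$key, kind = rec$kind, allowed = unlist(rec$allowed),
    flag = rec$flag, indicator = rec$indicator,
    spatial = rec$spatial %||% "sum", alpha = rec$alpha %||% 1,
    enabled = rec$enabled %||% TRUE, label = rec$label %||% rec$key
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a scenario configuration
#'
#' @param data list with `path` and optional schema fields (`stand`,
#'   `regime`, `year`, `area`, `flags`) plus `per_hectare`.
#' @param objectives list of [objective_spec()] or plain records.
#' @param constraints list of [constraint_spec()] or plain records.
#' @param reference_point named aspiration levels (may be empty).
#' @param epsilon named epsilon bounds (may be empty).
#' @param params [scalarization_params()] or a plain record.
#' @param binary whole-stand (MILP) mode.
#' @param output default export directory.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(data = NULL, objectives, constraints = list(),
                            reference_point = list(), epsilon = list(),
                            params = scalarization_params(), binary = FALSE,
                            output = NULL) {
  objectives <- lapply(objectives, .as_objective_spec)
  if (!length(objectives)) stop("scenario declares no objectives")
  keys <- vapply(objectives, function(o) o$key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate objective key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  constraints <- lapply(constraints, .as_constraint_spec)
  ckeys <- vapply(constraints, function(cs) cs$key, character(1))
  if (anyDuplicated(ckeys)) {
    stop("duplicate constraint key(s): ",
         paste(unique(ckeys[duplicated(ckeys)]), collapse = ", "))
  }
  for (nm in c("reference_point", "epsilon")) {
    vals <- get(nm)
    unknown <- setdiff(names(vals), keys)
    if (length(unknown)) {
      stop(nm, " refers to undeclared objective(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!inherits(params, "scalarization_params")) {
    params <- scalarization_params(rho = params$rho %||% 1e-6,
                                   range_floor = params$range_floor %||% 1e-9)
  }
  structure(
    list(data = data, objectives = objectives, constraints = constraints,
         reference_point = reference_point, epsilon = epsilon,
         params = params, binary = isTRUE(binary), output = output),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file; relative data paths are resolved against the
#'   file's directory.
#' @return a `scenario_config`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$data$path) && !grepl("^(/|[A-Za-z]:)", y$data$path)) {
    y$data$path <- file.path(dirname(path), y$data$path)
  }
  scenario_config(
    data = y$data, objectives = y$objectives,
    constraints = y$constraints %||% list(),
    reference_point = y$reference_point %||% list(),
    epsilon = y$epsilon %||% list(),
    params = y$params %||% scalarization_params(),
    binary = y$binary %||% FALSE, output = y$output
  )
}

.load_scenario_data <- function(config) {
  d <- config$data
  if (is.null(d) || is.null(d$path)) stop("scenario has no data path")
  schema <- forest_schema(
    stand = d$stand %||% "standid", regime = d$regime %||% "regime",
    year = d$year %||% "year", area = d$area %||% "area",
    flags = unlist(d$flags) %||% character()
  )
  read_forest_data(d$path, schema)
}

#' Open an interactive planning session
#'
#' Compiles the problem and payoff table once; preference updates re-solve
#' only the scalarization.
#'
#' @param config a `scenario_config`.
#' @param fd optional pre-loaded `forest_data` (otherwise read from the
#'   config's data path).
#' @return a `forest_session` environment with fields `problem`, `payoff`,
#'   `solution` and `history`.
#' @export
forest_session <- function(config, fd = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(fd)) fd <- .load_scenario_data(config)
  ses <- new.env(parent = emptyenv())
  ses$config <- config
  ses$fd <- fd
  ses$history <- list()
  ses$solution <- NULL
  class(ses) <- "forest_session"
  .session_compile(ses)
  ses
}

.session_compile <- function(ses) {
  ses$problem <- build_problem(
    ses$fd, ses$config$objectives, ses$config$constraints,
    binary = ses$config$binary,
    per_hectare = isTRUE(ses$config$data$per_hectare)
  )
  ses$payoff <- compute_payoff(ses$problem)
  invisible(ses)
}

#' @export
print.forest_session <- function(x, ...) {
  cat(sprintf("<forest_session: %d objectives, %d constraints, %d solves so far>\n",
              length(x$config$objectives), length(x$config$constraints),
              length(x$history)))
  invisible(x)
}

#' Update preferences and re-solve
#'
#' Changing the reference point or epsilon bounds reuses the cached payoff
#' table; enabling/disabling structural constraints changes the feasible set
#' (and hence the slider ranges), so the problem and payoff table are
#' recompiled first.  An infeasible preference set is reported and the
#' previous solution retained.
#'
#' @param ses a `forest_session`.
#' @param ref,eps new reference point / epsilon entries (named; merged into
#'   the current ones; an `NA` epsilon entry removes the bound).
#' @param enable,disable character vectors of constraint keys to toggle.
#' @return the new (or retained) `forest_solution`, invisibly also stored on
#'   the session.
#' @export
update_preferences <- function(ses, ref = NULL, eps = NULL,
                               enable = NULL, disable = NULL) {
  stopifnot(inherits(ses, "forest_session"))
  cfg <- ses$config
  toggled <- FALSE
  if (length(enable) || length(disable)) {
    ckeys <- vapply(cfg$constraints, function(cs) cs$key, character(1))
    unknown <- setdiff(c(enable, disable), ckeys)
    if (length(unknown)) {
      stop("unknown constraint key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in enable) {
      i <- match(k, ckeys)
      toggled <- toggled || !cfg$constraints[[i]]$enabled
      cfg$constraints[[i]]$enabled <- TRUE
    }
    for (k in disable) {
      i <- match(k, ckeys)
      toggled <- toggled || cfg$constraints[[i]]$enabled
      cfg$constraints[[i]]$enabled <- FALSE
    }
  }
  if (!is.null(ref)) cfg$reference_point[names(ref)] <- as.list(ref)
  if (!is.null(eps)) {
    cfg$epsilon[names(eps)] <- as.list(eps)
    cfg$epsilon <- Filter(function(v) !is.na(v), cfg$epsilon)
  }
  ses$config <- cfg
  if (toggled) .session_compile(ses)

  sol <- solve_scalarized(
    ses$problem, ses$payoff,
    ref = unlist(cfg$reference_point), eps = cfg$epsilon,
    params = cfg$params
  )
  ses$history[[length(ses$history) + 1L]] <- list(
    reference_point = cfg$reference_point, epsilon = cfg$epsilon,
    enabled = vapply(Filter(function(cs) cs$enabled, cfg$constraints),
                     `[[`, character(1), "key"),
    status = sol$status, objective_values = sol$objective_values
  )
  if (sol$status != "optimal") {
    message("preference set infeasible (", sol$status, ") ",
            if (length(sol$diagnosis)) sol$diagnosis else "",
            "; previous solution retained")
    if (!is.null(ses$solution)) return(invisible(ses$solution))
  }
  ses$solution <- sol
  invisible(sol)
}

#' Run a scenario end to end
#'
#' Load data, compile, compute the payoff table, solve the scalarization,
#' export tables (and plots, when ggplot2 is available).
#'
#' @param config a `scenario_config`, or a path to a scenario YAML.
#' @param fd optional pre-loaded `forest_data`.
#' @param out_dir export directory (default: the config's `output`; `NULL`
#'   skips writing).
#' @param plots write figure files alongside the tables.
#' @return list with `session`, `solution` and `export`.
#' @export
run_scenario <- function(config, fd = NULL, out_dir = config$output,
                         plots = TRUE) {
  if (is.character(config)) config <- read_scenario(config)
  stage <- "load"
  result <- tryCatch({
    ses <- forest_session(config, fd = fd)   # load + compile + payoff
    stage <- "solve"
    sol <- update_preferences(ses)
    if (sol$status != "optimal") {
      stop("scalarized solve ", sol$status,
           if (length(sol$diagnosis)) paste0(" (", sol$diagnosis, ")") else "")
    }
    stage <- "export"
    exp <- export_solution(ses, out_dir = out_dir)
    if (plots && !is.null(out_dir)) plot_solution(exp, file.path(out_dir, "figures"))
    list(session = ses, solution = sol, export = exp)
  }, error = function(e) {
    stop(sprintf("scenario failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

.fmt6 <- function(x) {
  if (is.numeric(x)) trimws(formatC(x, digits = 6, format = "g")) else x
}

.write_table <- function(df, path) {
  out <- df
  for (col in names(out)) out[[col]] <- .fmt6(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Export a solved session as plain tables
#'
#' Produces the stand-level management-share table (share > 0 rows only),
#' the yearly landscape aggregates of every indicator under the optimal
#' allocation (recomputed from the raw table, not taken from the solver),
#' the payoff table and the per-objective achievement table.  Numbers are
#' written with 6 significant digits.
#'
#' @param ses a solved `forest_session` (or a list with `problem`, `payoff`,
#'   `solution`).
#' @param out_dir directory for `stand_solution.csv`,
#'   `aggregate_solution.csv`, `payoff.csv`, `achievement.csv`; `NULL`
#'   returns the tables without writing.
#' @return a `solution_export` list of the four data frames.
#' @export
export_solution <- function(ses, out_dir = NULL) {
  problem <- ses$problem
  payoff <- ses$payoff
  sol <- ses$solution
  if (is.null(sol) || sol$status != "optimal") stop("no optimal solution to export")

  vars <- problem$vars
  keep <- sol$shares > 1e-9
  stand_table <- data.frame(
    stand = vars$stand[keep], regime = vars$regime[keep],
    share = sol$shares[keep], stringsAsFactors = FALSE
  )
  stand_table <- stand_table[order(stand_table$stand, stand_table$regime), ]
  rownames(stand_table) <- NULL

  aggregate_table <- aggregate_solution(problem, sol$shares)

  payoff_df <- data.frame(objective = payoff$keys,
                          as.data.frame(payoff$matrix),
                          check.names = FALSE, stringsAsFactors = FALSE)
  achievement_table <- data.frame(
    objective = payoff$keys,
    value = unname(sol$objective_values[payoff$keys]),
    nadir = unname(payoff$nadir), ideal = unname(payoff$ideal),
    achievement = unname(sol$achievements[payoff$keys]),
    stringsAsFactors = FALSE
  )

  export <- structure(
    list(stand_table = stand_table, aggregate_table = aggregate_table,
         payoff_table = payoff_df, achievement_table = achievement_table),
    class = "solution_export"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_table(stand_table, file.path(out_dir, "stand_solution.csv"))
    .write_table(aggregate_table, file.path(out_dir, "aggregate_solution.csv"))
    .write_table(payoff_df, file.path(out_dir, "payoff.csv"))
    .write_table(achievement_table, file.path(out_dir, "achievement.csv"))
  }
  export
}

#' Plot a solution export
#'
#' Writes (a) the landscape management portfolio (share of area per regime),
#' (b) normalized objective achievements in \[0, 1\], and (c) temporal line
#' plots of every indicator aggregate.  Plotting problems are reported as
#' messages and never abort a run.
#'
#' @param export a `solution_export`.
#' @param out_dir directory for the PNG files.
#' @param areas optional named per-stand areas used to weight regime shares
#'   (default: equal weights).
#' @return invisibly, the written file paths.
#' @export
plot_solution <- function(export, out_dir, areas = NULL) {
  stopifnot(inherits(export, "solution_export"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not available; skipping plots")
    return(invisible(character(0)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  g <- ggplot2::ggplot
  a <- ggplot2::aes
  try_plot <- function(name, expr) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      ggplot2::ggsave(path, expr, width = 7, height = 4.5, dpi = 120)
      TRUE
    }, error = function(e) {
      message("plot '", name, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }

  st <- export$stand_table
  w <- if (is.null(areas)) rep(1, nrow(st)) else unname(areas[st$stand])
  portf <- stats::aggregate(list(share = st$share * w), list(regime = st$regime), sum)
  portf$share <- 100 * portf$share / sum(portf$share)
  try_plot("management_portfolio.png",
    g(portf, a(x = regime, y = share)) +
      ggplot2::geom_col(fill = "forestgreen") +
      ggplot2::labs(y = "share of landscape (%)", x = NULL,
                    title = "Optimal management portfolio") +
      ggplot2::theme_minimal())

  ach <- export$achievement_table
  try_plot("achievement.png",
    g(ach, a(x = objective, y = pmin(pmax(achievement, 0), 1))) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(y = "achievement (nadir = 0, ideal = 1)", x = NULL,
                    title = "Objective achievement") +
      ggplot2::theme_minimal())

  agg <- export$aggregate_table
  try_plot("indicators.png",
    g(agg, a(x = year, y = value)) +
      ggplot2::geom_line(color = "grey30") +
      ggplot2::facet_wrap(~indicator, scales = "free_y") +
      ggplot2::labs(title = "Landscape indicator trajectories", y = NULL) +
      ggplot2::theme_minimal())

  invisible(written)
}
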