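# Problem assembly and the reference-point solve.
#
# The decision model is the classic stand-by-regime allocation LP: one
# variable x[s,r] in [0,1] per simulated (stand, regime) pair with a simplex
# row sum_r x[s,r] = 1 per stand (binary mode declares the same variables
# integral, forcing whole-stand assignments).  The payoff table estimates
# ideal and nadir vectors from single-objective optima, and the scalarized
# solve maximizes an augmented Chebyshev achievement function around the
# user's reference point under epsilon-constraints.

#' Scalarization parameters
#'
#' @param rho augmentation coefficient of the achievement function; any
#'   small positive value guarantees Pareto optimality of the optimum.
#' @param range_floor smallest usable ideal-nadir range; objectives whose
#'   range falls below it are normalized by 1 instead (with a warning).
#' @return a `scalarization_params` list.
#' @export
scalarization_params <- function(rho = 1e-6, range_floor = 1e-9) {
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (rho > 1e-3) {
    warning("rho = ", rho, " is large; the augmentation term may distort the solution",
            call. = FALSE)
  }
  if (!is.numeric(range_floor) || range_floor <= 0) stop("range_floor must be > 0")
  structure(list(rho = rho, range_floor = range_floor),
            class = "scalarization_params")
}

lp_clone <- function(lp) {
  cl <- new.env(parent = emptyenv())
  for (nm in ls(lp, all.names = TRUE)) assign(nm, get(nm, envir = lp), envir = cl)
  class(cl) <- "lp_model"
  cl
}

#' Build the allocation problem
#'
#' Creates one allocation variable per simulated (stand, regime) pair, the
#' per-stand simplex rows, the enabled structural constraint rows, and
#' compiles every objective into the model (auxiliary variables and rows
#' included).
#'
#' @param fd a `forest_data`.
#' @param objectives list of [objective_spec()] with unique keys.
#' @param constraints list of [constraint_spec()]; only `enabled` ones are
#'   compiled in.
#' @param binary if `TRUE`, whole-stand (MILP) assignments instead of
#'   fractional shares.
#' @param per_hectare if `TRUE`, indicator values are per-hectare rates and
#'   are multiplied by stand area during spatial aggregation.
#' @return a `forest_problem` environment.
#' @export
build_problem <- function(fd, objectives, constraints = list(),
                          binary = FALSE, per_hectare = FALSE) {
  stopifnot(inherits(fd, "forest_data"))
  if (!length(objectives)) stop("at least one objective is required")
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  keys <- vapply(objectives, function(o) o$key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate objective key(s): ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }

  d <- fd$data
  pair <- paste(d$stand, d$regime, sep = "\r")
  upair <- !duplicated(pair)
  vars <- data.frame(stand = d$stand[upair], regime = d$regime[upair],
                     stringsAsFactors = FALSE)
  vars <- vars[order(vars$stand, vars$regime), , drop = FALSE]
  rownames(vars) <- NULL
  vars$var <- seq_len(nrow(vars))
  if (!all(fd$stands %in% vars$stand)) {
    stop("stand without any simulated regime: ",
         paste(setdiff(fd$stands, vars$stand), collapse = ", "))
  }

  lp <- lp_new(nrow(vars), lb = 0, ub = 1, integer = binary,
               names = paste(vars$stand, vars$regime, sep = ":"))
  for (s in fd$stands) {
    j <- vars$var[vars$stand == s]
    lp_add_row(lp, j, rep(1, length(j)), "=", 1, paste0("simplex:", s))
  }

  problem <- new.env(parent = emptyenv())
  problem$fd <- fd
  problem$vars <- vars
  problem$row_var <- vars$var[match(pair, paste(vars$stand, vars$regime, sep = "\r"))]
  problem$lp <- lp
  problem$n_alloc <- nrow(vars)
  problem$binary <- binary
  problem$per_hectare <- per_hectare
  problem$form_cache <- list()
  class(problem) <- "forest_problem"

  enabled <- Filter(function(cs) cs$enabled, constraints)
  for (cs in enabled) {
    if (cs$kind == "allowed_regimes") {
      compile_allowed_regimes(lp, cs, problem)
    } else {
      compile_threshold(lp, cs, problem)
    }
  }
  problem$constraints <- constraints

  problem$compiled <- lapply(objectives, function(spec) {
    forms <- aggregate_per_year(problem, spec$indicator, spec$spatial)
    compile_objective(lp, spec, forms, fd$years)
  })
  names(problem$compiled) <- keys
  problem$base_rows <- lp$n_row    # everything up to here is preference-free
  problem
}

#' @export
print.forest_problem <- function(x, ...) {
  cat(sprintf(
    "<forest_problem: %d allocation vars (%s), %d stands, %d objectives, %d rows>\n",
    x$n_alloc, if (x$binary) "binary" else "continuous",
    length(x$fd$stands), length(x$compiled), x$lp$n_row
  ))
  invisible(x)
}

objective_keys <- function(problem) names(problem$compiled)

# Canonical max-form value of every objective at an allocation vector,
# re-derived from the raw table by plain arithmetic (never from the solver).
evaluate_all_objectives <- function(problem, x) {
  vapply(problem$compiled, function(co) {
    forms <- aggregate_per_year(problem, co$spec$indicator, co$spec$spatial)
    V <- vapply(forms, linform_eval, numeric(1), x = x)
    evaluate_objective(co$spec, V, problem$fd$years)
  }, numeric(1))
}

#' Yearly landscape aggregates of every indicator under an allocation
#'
#' @param problem a `forest_problem`.
#' @param shares allocation vector over `problem$vars` (or a solution).
#' @param spatial spatial mode used for all indicators.
#' @return data frame (year, indicator, value).
#' @export
aggregate_solution <- function(problem, shares, spatial = "sum") {
  if (inherits(shares, "forest_solution")) shares <- shares$shares
  rows <- lapply(problem$fd$indicators, function(ind) {
    forms <- aggregate_per_year(problem, ind, spatial)
    data.frame(
      year = problem$fd$years, indicator = ind,
      value = vapply(forms, linform_eval, numeric(1), x = shares),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Compute the payoff table
#'
#' Solves one single-objective maximization per declared objective over the
#' feasible set (structural constraints included, preferences excluded).
#' Row i holds every objective's value at the solution maximizing objective
#' i; the diagonal is the ideal vector and the column minima estimate the
#' nadir vector.
#'
#' @param problem a `forest_problem`.
#' @return a `payoff_table` with fields `matrix`, `ideal`, `nadir`.
#' @export
compute_payoff <- function(problem) {
  keys <- objective_keys(problem)
  n <- length(keys)
  objs <- lapply(problem$compiled, function(co) {
    linform_dense(co$expr, problem$lp$n_var)
  })
  sols <- lp_solve(problem$lp, unname(objs), maximize = TRUE)
  mat <- matrix(NA_real_, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    if (sols[[i]]$status != "optimal") {
      enabled <- Filter(function(cs) cs$enabled, problem$constraints)
      stop(sprintf(
        "payoff solve for objective '%s' %s (enabled constraints: %s)",
        keys[i], sols[[i]]$status,
        if (length(enabled)) {
          paste(vapply(enabled, `[[`, character(1), "key"), collapse = ", ")
        } else "none"
      ))
    }
    mat[i, ] <- evaluate_all_objectives(problem, sols[[i]]$x)
  }
  ideal <- diag(mat)
  if (n == 1) ideal <- mat[1, 1]
  names(ideal) <- keys
  nadir <- apply(mat, 2, min)
  structure(list(matrix = mat, ideal = ideal, nadir = nadir, keys = keys),
            class = "payoff_table")
}

#' @export
print.payoff_table <- function(x, digits = 4, ...) {
  cat("Payoff table (row i = solution maximizing objective i):\n")
  print(round(x$matrix, digits))
  cat("ideal:", paste(sprintf("%s=%.*g", x$keys, digits, x$ideal), collapse = "  "), "\n")
  cat("nadir:", paste(sprintf("%s=%.*g", x$keys, digits, x$nadir), collapse = "  "), "\n")
  invisible(x)
}

.normalization_ranges <- function(payoff, range_floor) {
  r <- payoff$ideal - payoff$nadir
  flat <- r < range_floor
  if (any(flat)) {
    warning("objective(s) with degenerate ideal-nadir range, normalizing by 1: ",
            paste(payoff$keys[flat], collapse = ", "), call. = FALSE)
    r[flat] <- 1
  }
  r
}

#' Achievement scalarizing function value of an objective vector
#'
#' `min_i (F_i - z_ref_i) / (z_ideal_i - z_nadir_i) + rho * sum_i F_i / r_i`
#' in canonical maximization form: the worst normalized deviation from the
#' reference point, plus the augmentation term that breaks ties toward
#' Pareto optimal solutions.
#'
#' @param values named objective vector (canonical max form).
#' @param ref reference point (aspiration levels).
#' @param payoff a [compute_payoff()] result supplying ideal and nadir.
#' @param params [scalarization_params()].
#' @return scalar ASF value (larger is better).
#' @export
asf_value <- function(values, ref, payoff, params = scalarization_params()) {
  r <- .normalization_ranges(payoff, params$range_floor)
  values <- values[payoff$keys]
  ref <- ref[payoff$keys]
  min((values - ref) / r) + params$rho * sum(values / r)
}

#' Solve the augmented Chebyshev scalarization
#'
#' Maximizes `alpha + rho * sum_i F_i / r_i` subject to
#' `alpha <= (F_i - z_ref_i) / r_i` for every objective, the
#' epsilon-constraints `F_i >= eps_i`, and the allocation constraints, where
#' `r_i = z_ideal_i - z_nadir_i`.  Aspiration levels outside
#' `[nadir, ideal]` are clamped (with a warning) before solving.
#'
#' @param problem a `forest_problem`.
#' @param payoff the payoff table computed from the same problem.
#' @param ref named aspiration levels (objective units, canonical max form);
#'   objectives without an aspiration default to their ideal value.
#' @param eps named list/vector of epsilon bounds (may be empty).
#' @param params [scalarization_params()].
#' @return a `forest_solution`: per-stand regime shares, achieved objective
#'   values, normalized achievements, solver status and ASF value.
#' @export
solve_scalarized <- function(problem, payoff, ref = NULL, eps = NULL,
                             params = scalarization_params()) {
  keys <- objective_keys(problem)
  stopifnot(identical(payoff$keys, keys))
  r <- .normalization_ranges(payoff, params$range_floor)

  full_ref <- payoff$ideal
  if (!is.null(ref)) {
    ref <- unlist(ref)
    if (is.null(names(ref))) {
      if (length(ref) != length(keys)) {
        stop("an unnamed reference point must give one aspiration per objective")
      }
      names(ref) <- keys
    }
    unknown <- setdiff(names(ref), keys)
    if (length(unknown)) {
      stop("reference point refers to undeclared objective(s): ",
           paste(unknown, collapse = ", "))
    }
    full_ref[names(ref)] <- ref
  }
  lo <- pmin(payoff$nadir, payoff$ideal)
  hi <- pmax(payoff$nadir, payoff$ideal)
  clamped <- pmin(pmax(full_ref, lo), hi)
  moved <- abs(clamped - full_ref) > 0
  if (any(moved)) {
    warning("aspiration level(s) outside [nadir, ideal] clamped: ",
            paste(keys[moved], collapse = ", "), call. = FALSE)
  }
  full_ref <- clamped

  lp <- lp_clone(problem$lp)
  alpha <- lp_add_var(lp, -Inf, Inf, FALSE, "asf_alpha")
  for (i in seq_along(keys)) {
    ex <- problem$compiled[[i]]$expr
    lp_add_row(lp, c(ex$j, alpha), c(ex$a, -r[i]), ">=",
               full_ref[i] - ex$const, paste0("asf:", keys[i]))
  }
  if (!is.null(eps) && length(eps)) {
    eps <- as.list(eps)
    compile_epsilon(lp, eps, problem$compiled)
  }
  obj <- numeric(lp$n_var)
  obj[alpha] <- 1
  for (i in seq_along(keys)) {
    ex <- problem$compiled[[i]]$expr
    obj[ex$j] <- obj[ex$j] + params$rho * ex$a / r[i]
  }

  sol <- lp_solve(lp, list(obj), maximize = TRUE)[[1]]
  if (sol$status != "optimal") {
    diagnosis <- character(0)
    if (!is.null(eps) && length(eps)) {
      over <- names(eps)[unlist(eps) > payoff$ideal[names(eps)] + 1e-9]
      if (length(over)) {
        diagnosis <- paste0("epsilon above the payoff ideal for: ",
                            paste(over, collapse = ", "))
      }
    }
    if (sol$status == "unbounded") {
      stop("scalarized problem unbounded: the allocation simplex is bounded, so this flags a modeling bug")
    }
    return(structure(
      list(status = sol$status, shares = NULL, objective_values = NULL,
           achievements = NULL, scalar_value = NA_real_, alpha = NA_real_,
           ref = full_ref, eps = eps, params = params, diagnosis = diagnosis),
      class = "forest_solution"
    ))
  }

  x <- sol$x
  shares <- x[seq_len(problem$n_alloc)]
  shares[shares < 0 & shares > -1e-9] <- 0
  values <- evaluate_all_objectives(problem, x)
  achievements <- (values - payoff$nadir) / r
  structure(
    list(
      status = "optimal",
      shares = shares,
      x = x,
      lp = lp,
      objective_values = values,
      achievements = achievements,
      alpha = min((values - full_ref) / r),
      scalar_value = min((values - full_ref) / r) + params$rho * sum(values / r),
      ref = full_ref, eps = eps, params = params, diagnosis = character(0)
    ),
    class = "forest_solution"
  )
}

#' @export
print.forest_solution <- function(x, digits = 4, ...) {
  cat(sprintf("<forest_solution: %s>\n", x$status))
  if (length(x$diagnosis)) cat("  ", x$diagnosis, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  ASF value: %.*g (worst normalized deviation %.*g)\n",
                digits, x$scalar_value, digits, x$alpha))
    for (k in names(x$objective_values)) {
      cat(sprintf("  %s: %.*g (achievement %.*g)\n", k,
                  digits, x$objective_values[k], digits, x$achievements[k]))
    }
  }
  invisible(x)
}

#' Verify a solution against every model row
#'
#' Independent post-hoc check: evaluates all constraint rows of the solved
#' model at the returned point and reports the largest violation.
#'
#' @param solution an optimal `forest_solution`.
#' @return max violation (0 when feasible); row details in attribute `rows`.
#' @export
verify_solution <- function(solution) {
  stopifnot(inherits(solution, "forest_solution"),
            solution$status == "optimal")
  rows <- lp_row_values(solution$lp, solution$x)
  structure(max(c(0, rows$violation)), rows = rows)
}

#' Is an objective vector Pareto-dominated by any of a set of vectors?
#'
#' All vectors in canonical maximization form.  A vector dominates the
#' candidate when it is at least as good in every coordinate and strictly
#' better in at least one.
#'
#' @param candidate numeric objective vector.
#' @param others list of equal-length numeric vectors.
#' @param tol comparison tolerance.
#' @return `TRUE` when some vector in `others` dominates `candidate`.
#' @export
check_dominance <- function(candidate, others, tol = 1e-9) {
  if (!is.list(others)) others <- list(others)
  for (o in others) {
    if (length(o) != length(candidate)) {
      stop("objective vector length mismatch: ", length(o), " vs ", length(candidate))
    }
    if (all(o >= candidate - tol) && any(o > candidate + tol)) return(TRUE)
  }
  FALSE
}
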