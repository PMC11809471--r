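# Objective declaration and compilation.
#
# An objective names an indicator, a sense, one of twelve temporal operators
# and a spatial aggregation; compilation turns it into a linear expression
# over the allocation variables, adding at most one auxiliary variable and a
# handful of inequality rows (the standard LP linearization of min/max
# constructs).  Everything is kept in canonical MAXIMIZATION form: a
# sense = "min" objective negates the yearly aggregates before the temporal
# operator is applied, so "min deadwood / min" means "minimize the peak".

TEMPORAL_OPERATORS <- c(
  "min", "average", "firstYear", "sum", "targetYear", "targetYearWithSlope",
  "lastYear", "periodicTargets", "minYearlyIncrease", "maxYearlyIncrease",
  "minDecreaseDuringNPeriods", "maxIncreaseDuringNPeriods"
)
SPATIAL_MODES <- c("sum", "areaWeightedMean")
.PARAM_OPS <- c("targetYear", "targetYearWithSlope", "periodicTargets",
                "minDecreaseDuringNPeriods", "maxIncreaseDuringNPeriods")

#' Declare an optimization objective
#'
#' Mirrors the descriptor lists used by forest-planning configuration files:
#' a unique key, a human-readable label, the simulator indicator column, the
#' optimization sense, a temporal operator, a spatial aggregation mode, and
#' (for the operators that need one) a parameter.
#'
#' @param key unique identifier.
#' @param indicator indicator column name.
#' @param sense `"max"` or `"min"`.
#' @param temporal one of `r paste(TEMPORAL_OPERATORS, collapse = ", ")`.
#' @param spatial `"sum"` (landscape total) or `"areaWeightedMean"`.
#' @param param the target year (`targetYear`, `targetYearWithSlope`), a
#'   named year-to-target vector with positive targets (`periodicTargets`),
#'   or the window length N (`minDecreaseDuringNPeriods`,
#'   `maxIncreaseDuringNPeriods`).
#' @param slope relative per-period growth required after the target year
#'   (`targetYearWithSlope` only, >= 0).
#' @param label human-readable description.
#' @return an `objective_spec`.
#' @export
objective_spec <- function(key, indicator, sense = "max", temporal,
                           spatial = "sum", param = NULL, slope = 0,
                           label = key) {
  stopifnot(is.character(key), nzchar(key))
  if (!sense %in% c("max", "min")) stop("sense must be 'max' or 'min'")
  if (!temporal %in% TEMPORAL_OPERATORS) {
    stop("unknown temporal operator: ", temporal)
  }
  if (!spatial %in% SPATIAL_MODES) stop("unknown spatial mode: ", spatial)
  needs <- temporal %in% .PARAM_OPS
  if (needs && is.null(param)) {
    stop(sprintf("temporal operator '%s' requires a param", temporal))
  }
  if (!needs && !is.null(param)) {
    stop(sprintf("temporal operator '%s' takes no param", temporal))
  }
  if (temporal == "periodicTargets") {
    if (is.null(names(param)) || any(!nzchar(names(param)))) {
      stop("periodicTargets param must be a named year -> target vector")
    }
    if (any(param <= 0)) stop("periodicTargets targets must be positive")
  }
  if (slope < 0) stop("slope must be >= 0")
  if (slope > 0 && temporal != "targetYearWithSlope") {
    stop("slope only applies to targetYearWithSlope")
  }
  structure(
    list(key = key, label = label, indicator = indicator, sense = sense,
         temporal = temporal, spatial = spatial, param = param, slope = slope),
    class = "objective_spec"
  )
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective %s: %s %s(%s) over %s>\n",
              x$key, x$sense, x$temporal, x$indicator, x$spatial))
  invisible(x)
}

#' Per-year landscape aggregates as linear forms
#'
#' For spatial `"sum"` the year-t form is `sum_s sum_r x[s,r] d[s,r,t]`
#' (times stand area when values are per hectare); `"areaWeightedMean"`
#' divides the area-weighted sum by total landscape area.
#'
#' @param problem a `forest_problem` (see [build_problem()]).
#' @param indicator indicator column name.
#' @param spatial spatial mode.
#' @return list of `linform`s, one per simulated year, in year order.
#' @export
aggregate_per_year <- function(problem, indicator, spatial = "sum") {
  if (!indicator %in% problem$fd$indicators) {
    stop("unknown indicator: ", indicator)
  }
  if (!spatial %in% SPATIAL_MODES) stop("unknown spatial mode: ", spatial)
  cache_key <- paste(indicator, spatial, sep = "\r")
  cached <- problem$form_cache[[cache_key]]
  if (!is.null(cached)) return(cached)

  d <- problem$fd$data
  area <- problem$fd$stand_info$area[match(d$stand, problem$fd$stand_info$stand)]
  w <- if (spatial == "areaWeightedMean") {
    area / sum(problem$fd$stand_info$area)
  } else if (problem$per_hectare) area else rep(1, nrow(d))
  vals <- d[[indicator]] * w
  forms <- lapply(problem$fd$years, function(t) {
    sel <- d$year == t
    linform(problem$row_var[sel], vals[sel])
  })
  problem$form_cache[[cache_key]] <- forms
  forms
}

# Attach one objective to the problem's LP: adds the auxiliary variable and
# rows its temporal operator needs and returns the compiled objective, whose
# `expr` linform references final variable indices.  The auxiliary rows never
# restrict the allocation variables on their own (the auxiliary is free), so
# they can safely stay in the model when other objectives are being optimized.
compile_objective <- function(lp, spec, forms, years) {
  T_ <- length(years)
  if (T_ < 1) stop("no years to compile over")
  neg <- spec$sense == "min"
  W <- if (neg && spec$temporal != "periodicTargets") {
    lapply(forms, linform_scale, k = -1)
  } else {
    forms
  }
  aux <- NULL
  aux_rows <- integer(0)
  add_aux <- function() {
    lp_add_var(lp, -Inf, Inf, FALSE, paste0("aux_", spec$key))
  }
  # row: aux*k - W_t <=/>= rhs helpers
  row_aux_le_form <- function(f, k = 1, name = "") {
    # k*aux <= f  <=>  k*aux - f <= const(f)
    lp_add_row(lp, c(f$j, aux), c(-f$a, k), "<=", f$const, name)
  }
  row_aux_ge_form <- function(f, name = "") {
    lp_add_row(lp, c(f$j, aux), c(-f$a, 1), ">=", f$const, name)
  }
  expr <- switch(spec$temporal,
    min = {
      aux <- add_aux()
      aux_rows <- vapply(seq_len(T_), function(t) {
        row_aux_le_form(W[[t]], name = paste0(spec$key, ":min:", years[t]))
      }, integer(1))
      linform(aux, 1)
    },
    average = {
      f <- Reduce(linform_add, W)
      linform_scale(f, 1 / T_)
    },
    sum = Reduce(linform_add, W),
    firstYear = W[[1]],
    lastYear = W[[T_]],
    targetYear = {
      k <- match(spec$param, years)
      if (is.na(k)) stop("target year ", spec$param, " not in simulated years")
      W[[k]]
    },
    targetYearWithSlope = {
      k <- match(spec$param, years)
      if (is.na(k)) stop("target year ", spec$param, " not in simulated years")
      aux <- add_aux()
      aux_rows <- vapply(k:T_, function(t) {
        fac <- 1 + spec$slope * (t - k)
        row_aux_le_form(linform_scale(W[[t]], 1 / fac),
                        name = paste0(spec$key, ":slope:", years[t]))
      }, integer(1))
      linform(aux, 1)
    },
    periodicTargets = {
      tau <- spec$param[match(years, as.integer(names(spec$param)))]
      if (anyNA(tau)) stop("periodicTargets must provide a target for every year")
      aux <- add_aux()
      if (neg) {
        # stay below targets: V_t <= aux * tau_t, maximize -aux
        aux_rows <- vapply(seq_len(T_), function(t) {
          lp_add_row(lp, c(forms[[t]]$j, aux), c(forms[[t]]$a, -tau[t]), "<=",
                     -forms[[t]]$const, paste0(spec$key, ":ptarget:", years[t]))
        }, integer(1))
        linform(aux, -1)
      } else {
        # worst relative fulfilment: V_t >= aux * tau_t, maximize aux
        aux_rows <- vapply(seq_len(T_), function(t) {
          row_aux_le_form(linform_scale(forms[[t]], 1 / tau[t]),
                          name = paste0(spec$key, ":ptarget:", years[t]))
        }, integer(1))
        linform(aux, 1)
      }
    },
    maxYearlyIncrease = {
      aux <- add_aux()
      aux_rows <- vapply(seq_len(T_ - 1), function(t) {
        diff_f <- linform_add(W[[t + 1]], linform_scale(W[[t]], -1))
        row_aux_le_form(diff_f, name = paste0(spec$key, ":incr:", years[t]))
      }, integer(1))
      linform(aux, 1)
    },
    minYearlyIncrease = {
      aux <- add_aux()
      aux_rows <- vapply(seq_len(T_ - 1), function(t) {
        diff_f <- linform_add(W[[t + 1]], linform_scale(W[[t]], -1))
        row_aux_ge_form(diff_f, name = paste0(spec$key, ":incr:", years[t]))
      }, integer(1))
      linform(aux, -1)
    },
    maxIncreaseDuringNPeriods = {
      N <- .check_window(spec$param, T_)
      aux <- add_aux()
      aux_rows <- vapply(seq_len(T_ - N), function(t) {
        diff_f <- linform_add(W[[t + N]], linform_scale(W[[t]], -1))
        row_aux_le_form(diff_f, name = paste0(spec$key, ":nincr:", years[t]))
      }, integer(1))
      linform(aux, 1)
    },
    minDecreaseDuringNPeriods = {
      N <- .check_window(spec$param, T_)
      aux <- add_aux()
      aux_rows <- vapply(seq_len(T_ - N), function(t) {
        diff_f <- linform_add(W[[t]], linform_scale(W[[t + N]], -1))
        row_aux_ge_form(diff_f, name = paste0(spec$key, ":ndecr:", years[t]))
      }, integer(1))
      linform(aux, -1)
    }
  )
  structure(
    list(spec = spec, expr = expr, aux = aux, aux_rows = aux_rows),
    class = "compiled_objective"
  )
}

.check_window <- function(N, T_) {
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("window length N must be a positive integer")
  if (N >= T_) stop("window length N must be smaller than the number of periods")
  N
}

#' Evaluate a temporal operator by direct arithmetic
#'
#' Given the realized yearly aggregates `V` of an objective's indicator
#' under some fixed allocation, returns the objective's value in canonical
#' maximization units.  This is the arithmetic definition of each operator,
#' independent of the LP linearization, and is what solution reports use.
#'
#' @param spec an [objective_spec()].
#' @param V numeric vector of yearly aggregates, one per simulated year.
#' @param years the simulated year labels.
#' @return scalar objective value.
#' @export
evaluate_objective <- function(spec, V, years) {
  stopifnot(length(V) == length(years))
  T_ <- length(years)
  W <- if (spec$sense == "min") -V else V
  switch(spec$temporal,
    min = min(W),
    average = mean(W),
    sum = sum(W),
    firstYear = W[1],
    lastYear = W[T_],
    targetYear = W[match(spec$param, years)],
    targetYearWithSlope = {
      k <- match(spec$param, years)
      min(W[k:T_] / (1 + spec$slope * (seq.int(k, T_) - k)))
    },
    periodicTargets = {
      tau <- spec$param[match(years, as.integer(names(spec$param)))]
      if (spec$sense == "min") -max(V / tau) else min(V / tau)
    },
    maxYearlyIncrease = min(diff(W)),
    minYearlyIncrease = -max(diff(W)),
    maxIncreaseDuringNPeriods = {
      N <- .check_window(spec$param, T_)
      min(W[(1 + N):T_] - W[seq_len(T_ - N)])
    },
    minDecreaseDuringNPeriods = {
      N <- .check_window(spec$param, T_)
      -max(W[seq_len(T_ - N)] - W[(1 + N):T_])
    }
  )
}
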