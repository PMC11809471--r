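# Structural constraints and epsilon-constraints.
#
# Two structural families: "allowed_regimes" fixes disallowed allocation
# variables to zero on flagged stands (e.g. only continuous-cover or
# set-aside regimes on peatland), and "indicator_threshold" forbids a
# landscape aggregate from falling below a fraction alpha of its own
# first-year value under the chosen plan (alpha = 1 is a no-decline rule).
# Epsilon rows bound individual objectives from below.

#' Declare a structural constraint
#'
#' @param key unique identifier.
#' @param kind `"allowed_regimes"` or `"indicator_threshold"`.
#' @param allowed (allowed_regimes) nonempty character vector of regimes that
#'   remain available on flagged stands.
#' @param flag (allowed_regimes) name of the boolean stand flag marking where
#'   the restriction applies.
#' @param indicator,spatial (indicator_threshold) the aggregate to protect.
#' @param alpha (indicator_threshold) minimum retained fraction of the
#'   first-year aggregate, > 0; 1 means "no decline allowed".
#' @param enabled whether the constraint participates in the next solve.
#' @param label human-readable description.
#' @return a `constraint_spec`.
#' @export
constraint_spec <- function(key, kind, allowed = NULL, flag = NULL,
                            indicator = NULL, spatial = "sum", alpha = 1,
                            enabled = TRUE, label = key) {
  stopifnot(is.character(key), nzchar(key))
  if (!kind %in% c("allowed_regimes", "indicator_threshold")) {
    stop("unknown constraint kind: ", kind)
  }
  if (kind == "allowed_regimes") {
    if (is.null(allowed) || !length(allowed)) {
      stop("allowed_regimes constraint needs a nonempty allowed regime list")
    }
    if (is.null(flag)) stop("allowed_regimes constraint needs a stand flag column")
  } else {
    if (is.null(indicator)) stop("indicator_threshold constraint needs an indicator")
    if (!spatial %in% SPATIAL_MODES) stop("unknown spatial mode: ", spatial)
    if (!is.numeric(alpha) || alpha <= 0) {
      stop("validation error: alpha must be > 0")
    }
  }
  structure(
    list(key = key, kind = kind, label = label, allowed = allowed, flag = flag,
         indicator = indicator, spatial = spatial, alpha = alpha,
         enabled = isTRUE(enabled)),
    class = "constraint_spec"
  )
}

#' @export
print.constraint_spec <- function(x, ...) {
  desc <- if (x$kind == "allowed_regimes") {
    sprintf("only {%s} where %s", paste(x$allowed, collapse = ", "), x$flag)
  } else {
    sprintf("%s(%s) >= %g x first year", x$spatial, x$indicator, x$alpha)
  }
  cat(sprintf("<constraint %s [%s]: %s>\n", x$key,
              if (x$enabled) "enabled" else "disabled", desc))
  invisible(x)
}

# Fix x[s, r] = 0 for every flagged stand and disallowed regime.  Returns the
# flagged stands; warns if a flagged stand has no allowed regime simulated
# (the per-stand simplex row then makes the model infeasible).
compile_allowed_regimes <- function(lp, spec, problem) {
  fd <- problem$fd
  if (!spec$flag %in% fd$flags) {
    stop(sprintf("constraint '%s': unknown stand flag column '%s'",
                 spec$key, spec$flag))
  }
  flagged <- fd$stand_info$stand[fd$stand_info[[spec$flag]]]
  vars <- problem$vars
  n_fixed <- 0L
  for (s in flagged) {
    sel <- vars$stand == s & !(vars$regime %in% spec$allowed)
    if (all(sel[vars$stand == s])) {
      warning(sprintf(
        "constraint '%s': stand %s has no allowed regime simulated; model will be infeasible",
        spec$key, s
      ), call. = FALSE)
    }
    for (j in vars$var[sel]) lp_fix_var(lp, j, 0)
    n_fixed <- n_fixed + sum(sel)
  }
  invisible(list(stands = flagged, n_fixed = n_fixed))
}

# Rows V(t) >= alpha * V(t_first) for every t after the first year; both
# sides are linear in the allocation, so the baseline is the plan's own
# first-year aggregate, not a pre-computed constant.
compile_threshold <- function(lp, spec, problem) {
  forms <- aggregate_per_year(problem, spec$indicator, spec$spatial)
  base <- linform_scale(forms[[1]], -spec$alpha)
  rows <- vapply(seq_along(forms)[-1], function(t) {
    f <- linform_add(forms[[t]], base)
    lp_add_row(lp, f$j, f$a, ">=", -f$const,
               paste0(spec$key, ":", problem$fd$years[t]))
  }, integer(1))
  invisible(rows)
}

# One row per epsilon entry: objective expression >= eps (canonical max
# form).  For auxiliary-variable objectives this constrains the auxiliary,
# which in turn pins the allocation through the objective's own rows.
compile_epsilon <- function(lp, eps, compiled) {
  if (is.null(eps) || !length(eps)) return(invisible(integer(0)))
  keys <- vapply(compiled, function(o) o$spec$key, character(1))
  unknown <- setdiff(names(eps), keys)
  if (length(unknown)) {
    stop("epsilon refers to undeclared objective(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(unlist(eps)))) stop("epsilon values must be finite")
  rows <- vapply(names(eps), function(k) {
    ex <- compiled[[match(k, keys)]]$expr
    lp_add_row(lp, ex$j, ex$a, ">=", eps[[k]] - ex$const, paste0("eps:", k))
  }, integer(1))
  invisible(rows)
}
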