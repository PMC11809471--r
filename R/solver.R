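# Solver backend.
#
# The package keeps model construction, evaluation and verification in R and
# delegates only the LP/MILP solves to the HiGHS solver, reached through
# scipy.optimize.milp in a python subprocess from the same environment.  The
# contract is deliberately minimal (rows in, variable values out) so any
# LP/MILP backend can stand behind it; several objective vectors sharing one
# constraint matrix are solved per subprocess call, which is what the payoff
# table needs.

solver_python <- function() {
  py <- getOption("forestmop.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the LP backend")
  py
}

solver_script <- function() {
  path <- system.file("python", "lp_solve.py", package = "forestmop")
  if (!nzchar(path)) stop("bundled solver script not found")
  path
}

.encode_inf <- function(x) {
  x[x == Inf] <- 1e30
  x[x == -Inf] <- -1e30
  x
}

#' Solve one or more objectives over a linear program
#'
#' All objective vectors are maximized (or minimized) over the same rows and
#' bounds in a single solver invocation.
#'
#' @param lp an `lp_model`.
#' @param objectives list of dense objective coefficient vectors (length
#'   `lp$n_var`).
#' @param maximize logical.
#' @return list of solutions, each with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"` or `"error"`), `objective` and `x`.
#' @keywords internal
lp_solve <- function(lp, objectives, maximize = TRUE) {
  stopifnot(inherits(lp, "lp_model"), length(objectives) >= 1)
  tr <- lp_triplets(lp)
  # I() keeps length-1 vectors as JSON arrays despite auto_unbox
  payload <- list(
    n = lp$n_var,
    lb = I(.encode_inf(lp$lb)),
    ub = I(.encode_inf(lp$ub)),
    integrality = I(as.integer(lp$integer)),
    maximize = maximize,
    rows = list(
      ri = I(tr$ri - 1L), ji = I(tr$ji - 1L), ai = I(tr$ai),
      lower = I(.encode_inf(lp$row_lower)), upper = I(.encode_inf(lp$row_upper))
    ),
    objectives = lapply(objectives, I)
  )
  fin <- tempfile("lp_", fileext = ".json")
  fout <- tempfile("lp_", fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(system2(
    solver_python(), c(solver_script(), shQuote(fin), shQuote(fout)),
    stdout = TRUE, stderr = TRUE
  ))
  if (!file.exists(fout)) {
    stop("LP backend failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(res$solutions, function(sol) {
    list(
      status = switch(as.character(sol$status),
        "0" = "optimal", "1" = "iteration_limit", "2" = "infeasible",
        "3" = "unbounded", "error"
      ),
      success = isTRUE(sol$success),
      objective = if (!is.null(sol$objective)) as.numeric(sol$objective) else NA_real_,
      x = if (!is.null(sol$x)) as.numeric(sol$x) else NULL,
      message = sol$message
    )
  })
}
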