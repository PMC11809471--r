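# Sparse linear-program container.
#
# Models are built row-wise: allocation variables first, auxiliary variables
# appended as objectives/scalarizations require them.  Rows are stored as
# triplets (row index, column index, coefficient) with per-row lower/upper
# bounds, so "<=", ">=" and "=" senses share one representation.

#' Create an empty linear program
#'
#' @param n_var number of variables.
#' @param lb,ub numeric bounds, recycled to length `n_var`.
#' @param integer logical vector (recycled): which variables are integral.
#' @param names optional variable names.
#' @return an `lp_model` environment.
#' @keywords internal
lp_new <- function(n_var, lb = 0, ub = 1, integer = FALSE, names = NULL) {
  lp <- new.env(parent = emptyenv())
  lp$n_var <- n_var
  lp$lb <- rep_len(as.numeric(lb), n_var)
  lp$ub <- rep_len(as.numeric(ub), n_var)
  lp$integer <- rep_len(as.logical(integer), n_var)
  lp$var_names <- if (is.null(names)) paste0("x", seq_len(n_var)) else names
  lp$ri <- vector("list", 0L)
  lp$ji <- vector("list", 0L)
  lp$ai <- vector("list", 0L)
  lp$row_lower <- numeric(0)
  lp$row_upper <- numeric(0)
  lp$row_names <- character(0)
  lp$n_row <- 0L
  class(lp) <- "lp_model"
  lp
}

#' Append a variable to a linear program
#' @return the (1-based) index of the new variable.
#' @keywords internal
lp_add_var <- function(lp, lb = -Inf, ub = Inf, integer = FALSE, name = NULL) {
  lp$n_var <- lp$n_var + 1L
  lp$lb <- c(lp$lb, as.numeric(lb))
  lp$ub <- c(lp$ub, as.numeric(ub))
  lp$integer <- c(lp$integer, isTRUE(integer))
  lp$var_names <- c(lp$var_names, if (is.null(name)) paste0("x", lp$n_var) else name)
  lp$n_var
}

#' Append a linear row `sense` `rhs` to a linear program
#'
#' @param j integer column indices; `a` matching coefficients (zeros dropped).
#' @param sense one of `"<="`, `">="`, `"="`.
#' @keywords internal
lp_add_row <- function(lp, j, a, sense, rhs, name = NULL) {
  keep <- a != 0
  j <- j[keep]; a <- a[keep]
  lp$n_row <- lp$n_row + 1L
  k <- length(lp$ri) + 1L
  lp$ri[[k]] <- rep.int(lp$n_row, length(j))
  lp$ji[[k]] <- as.integer(j)
  lp$ai[[k]] <- as.numeric(a)
  bounds <- switch(sense,
    "<=" = c(-Inf, rhs),
    ">=" = c(rhs, Inf),
    "="  = c(rhs, rhs),
    stop("unknown row sense: ", sense)
  )
  lp$row_lower <- c(lp$row_lower, bounds[1])
  lp$row_upper <- c(lp$row_upper, bounds[2])
  lp$row_names <- c(lp$row_names, if (is.null(name)) "" else name)
  invisible(lp$n_row)
}

#' Fix a variable to a value by collapsing its bounds
#' @keywords internal
lp_fix_var <- function(lp, j, value = 0) {
  lp$lb[j] <- value
  lp$ub[j] <- value
  invisible(NULL)
}

# Collapse accumulated row chunks into flat triplet vectors.
lp_triplets <- function(lp) {
  list(
    ri = if (length(lp$ri)) unlist(lp$ri, use.names = FALSE) else integer(0),
    ji = if (length(lp$ji)) unlist(lp$ji, use.names = FALSE) else integer(0),
    ai = if (length(lp$ai)) unlist(lp$ai, use.names = FALSE) else numeric(0)
  )
}

#' Evaluate every row of a linear program at a point
#'
#' Independent re-evaluation used to verify returned solutions against the
#' constraint rows without trusting the solver.
#'
#' @return data frame with columns `row`, `value`, `lower`, `upper`,
#'   `violation` (positive = infeasible by that much).
#' @keywords internal
lp_row_values <- function(lp, x) {
  tr <- lp_triplets(lp)
  vals <- numeric(lp$n_row)
  if (length(tr$ri)) {
    sums <- rowsum(tr$ai * x[tr$ji], tr$ri)
    vals[as.integer(rownames(sums))] <- sums[, 1]
  }
  viol <- pmax(lp$row_lower - vals, vals - lp$row_upper, 0)
  data.frame(
    row = seq_len(lp$n_row), name = lp$row_names, value = vals,
    lower = lp$row_lower, upper = lp$row_upper, violation = viol
  )
}

#' @export
print.lp_model <- function(x, ...) {
  cat(sprintf(
    "<lp_model: %d variables (%d integer), %d rows>\n",
    x$n_var, sum(x$integer), x$n_row
  ))
  invisible(x)
}

# A sparse linear form c0 + sum_j a_j x_j over the variables of an lp_model.
linform <- function(j = integer(0), a = numeric(0), const = 0) {
  keep <- a != 0
  structure(list(j = as.integer(j[keep]), a = as.numeric(a[keep]),
                 const = as.numeric(const)), class = "linform")
}

linform_eval <- function(f, x) sum(f$a * x[f$j]) + f$const

linform_scale <- function(f, k) linform(f$j, f$a * k, f$const * k)

# f + g (merging duplicate indices).
linform_add <- function(f, g) {
  j <- c(f$j, g$j); a <- c(f$a, g$a)
  if (anyDuplicated(j)) {
    a <- as.numeric(rowsum(a, j))
    j <- sort(unique(j))
  }
  linform(j, a, f$const + g$const)
}

# Dense coefficient vector of length n (constant dropped).
linform_dense <- function(f, n) {
  v <- numeric(n)
  v[f$j] <- v[f$j] + f$a
  v
}
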