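# Independent oracle: brute-force enumeration of whole-stand assignments and
# plain-loop arithmetic on the raw table.  Deliberately avoids the package's
# linear-form / LP machinery so it can stand as a second route.

# Yearly landscape aggregate of one indicator under a whole-stand assignment
# (named stand -> regime vector), by direct summation over the raw rows.
oracle_yearly <- function(fd, assign, indicator, spatial = "sum",
                          per_hectare = FALSE) {
  vapply(fd$years, function(t) {
    acc <- 0
    for (s in names(assign)) {
      sel <- fd$data$stand == s & fd$data$regime == assign[[s]] &
        fd$data$year == t
      v <- fd$data[[indicator]][sel]
      a <- fd$stand_info$area[fd$stand_info$stand == s]
      w <- if (spatial == "areaWeightedMean" || per_hectare) a else 1
      acc <- acc + v * w
    }
    if (spatial == "areaWeightedMean") acc / sum(fd$stand_info$area) else acc
  }, numeric(1))
}

# Temporal operators written out from their definitions with explicit loops.
oracle_temporal <- function(spec, V, years) {
  T_ <- length(V)
  lo <- function(v) { m <- Inf; for (z in v) if (z < m) m <- z; m }
  hi <- function(v) { m <- -Inf; for (z in v) if (z > m) m <- z; m }
  W <- if (identical(spec$sense, "min")) -V else V
  switch(spec$temporal,
    min = lo(W),
    average = sum(W) / T_,
    sum = sum(W),
    firstYear = W[1],
    lastYear = W[T_],
    targetYear = W[which(years == spec$param)],
    targetYearWithSlope = {
      k <- which(years == spec$param)
      lo(vapply(k:T_, function(t) W[t] / (1 + spec$slope * (t - k)), numeric(1)))
    },
    periodicTargets = {
      tau <- spec$param[as.character(years)]
      if (identical(spec$sense, "min")) -hi(V / tau) else lo(V / tau)
    },
    maxYearlyIncrease = lo(W[-1] - W[-T_]),
    minYearlyIncrease = -hi(W[-1] - W[-T_]),
    maxIncreaseDuringNPeriods = {
      N <- spec$param
      lo(vapply(seq_len(T_ - N), function(k) W[k + N] - W[k], numeric(1)))
    },
    minDecreaseDuringNPeriods = {
      N <- spec$param
      -hi(vapply(seq_len(T_ - N), function(k) W[k] - W[k + N], numeric(1)))
    }
  )
}

oracle_objective <- function(fd, assign, spec, per_hectare = FALSE) {
  V <- oracle_yearly(fd, assign, spec$indicator, spec$spatial, per_hectare)
  oracle_temporal(spec, V, fd$years)
}

# All whole-stand assignments (stand -> one simulated regime each).
oracle_assignments <- function(fd) {
  per_stand <- lapply(fd$stands, function(s) {
    sort(unique(fd$data$regime[fd$data$stand == s]))
  })
  names(per_stand) <- fd$stands
  grid <- expand.grid(per_stand, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

# Objective vectors (canonical max form) of every whole-stand assignment.
oracle_enumerate <- function(fd, specs, per_hectare = FALSE) {
  assigns <- oracle_assignments(fd)
  vecs <- lapply(assigns, function(a) {
    vapply(specs, function(sp) oracle_objective(fd, a, sp, per_hectare),
           numeric(1))
  })
  list(assignments = assigns, vectors = vecs)
}

# Augmented Chebyshev achievement value of an objective vector.
oracle_asf <- function(F, ref, ideal, nadir, rho = 1e-6, range_floor = 1e-9) {
  r <- ideal - nadir
  r[r < range_floor] <- 1
  worst <- Inf
  for (i in seq_along(F)) {
    d <- (F[i] - ref[i]) / r[i]
    if (d < worst) worst <- d
  }
  worst + rho * sum(F / r)
}
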