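# Seeded generator of simulator-like landscapes.
#
# Emulates the statistical structure of forest-simulator output — divergent
# indicator trajectories across management regimes — without any claim of
# silvicultural realism: logistic standing-stock growth, harvest pulses under
# rotation regimes, monotone deadwood accumulation under set-aside, plus
# multiplicative lognormal noise.

#' Configuration for the synthetic landscape generator
#'
#' @param n_stands number of stands (> 0).
#' @param regimes named character vector mapping regime name to behavior, one
#'   of `"rotation"`, `"extensive"`, `"ccf"`, `"set_aside"`.  At least two
#'   regimes, at least one `set_aside`.
#' @param year_start first simulated year label.
#' @param year_step spacing between period labels (> 0).
#' @param n_periods number of periods (> 1).
#' @param seed RNG seed; the generated table is a pure function of the
#'   configuration.
#' @param noise_sd standard deviation of the lognormal indicator noise
#'   (0 disables noise).
#' @param p_peat probability that a stand is flagged as peatland.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_stands = 50,
                         regimes = c(BAU = "rotation", INT = "rotation",
                                     EXT = "extensive", CCF_1 = "ccf",
                                     SA = "set_aside"),
                         year_start = 2016, year_step = 5, n_periods = 21,
                         seed = 1, noise_sd = 0.1, p_peat = 0.2) {
  behaviors <- c("rotation", "extensive", "ccf", "set_aside")
  if (!is.numeric(n_stands) || n_stands < 1) stop("invalid config: n_stands must be > 0")
  if (length(regimes) < 2) stop("invalid config: need at least 2 regimes")
  if (is.null(names(regimes)) || any(!nzchar(names(regimes)))) {
    stop("invalid config: regimes must be named")
  }
  if (!all(regimes %in% behaviors)) {
    stop("invalid config: unknown behavior(s): ",
         paste(setdiff(regimes, behaviors), collapse = ", "))
  }
  if (!any(regimes == "set_aside")) stop("invalid config: need a set_aside regime")
  if (year_step < 1) stop("invalid config: year_step must be > 0")
  if (n_periods < 2) stop("invalid config: n_periods must be > 1")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  structure(
    list(n_stands = as.integer(n_stands), regimes = regimes,
         year_start = as.integer(year_start), year_step = as.integer(year_step),
         n_periods = as.integer(n_periods), seed = as.integer(seed),
         noise_sd = noise_sd, p_peat = p_peat),
    class = "synth_config"
  )
}

# One stand x regime trajectory over the period grid; returns a matrix with a
# column per indicator.  `stand` carries the latent stand state drawn once
# per stand so regimes differ only through management.
.synth_trajectory <- function(stand, behavior, n_periods, noise_sd, regime_id) {
  K <- stand$site * 600                  # m3/ha carrying capacity
  growth <- 0.25 * stand$site            # per-period logistic rate
  stock <- numeric(n_periods)
  harvest <- numeric(n_periods)
  deadwood <- numeric(n_periods)
  v <- stand$v0
  dw <- stand$dw0
  # regime-specific pulse schedule
  offset <- (stand$phase + regime_id) %% 6L
  for (t in seq_len(n_periods)) {
    v <- v + growth * v * (1 - v / K)
    cut <- switch(behavior,
      rotation  = if ((t + offset) %% 6L == 0L && v > 0.35 * K) 0.9 else 0,
      extensive = if ((t + offset) %% 9L == 0L && v > 0.5 * K) 0.7 else 0,
      ccf       = if ((t + offset) %% 3L == 0L) 0.25 else 0,
      set_aside = 0
    )
    harvest[t] <- cut * v
    v <- v - harvest[t]
    dw <- if (behavior == "set_aside") {
      dw + 0.03 * v                       # strictly accumulating
    } else {
      max(0.85 * dw + 0.012 * v - 0.5 * harvest[t] * 0.02, 0.1)
    }
    stock[t] <- v
    deadwood[t] <- dw
  }
  noise <- function(n) exp(stats::rnorm(n, 0, noise_sd) - noise_sd^2 / 2)
  biomass <- stock * 0.55 * noise(n_periods)
  harvested <- harvest * ifelse(harvest > 0, noise(n_periods), 0)
  deadwood <- deadwood * noise(n_periods)
  decid <- 100 * stats::plogis(stand$decid +
    0.3 * (behavior == "set_aside") - 0.4 * (behavior == "rotation") +
    stats::rnorm(n_periods, 0, noise_sd))
  large <- pmax(0, (stock / K - 0.3) * 60 * (1 + 0.5 * (behavior == "set_aside"))) *
    noise(n_periods)
  recreation <- stats::plogis(-1 + 2.5 * stock / K + 0.2 * (behavior != "rotation") +
    stats::rnorm(n_periods, 0, noise_sd))
  cbind(
    harvested_volume = harvested, biomass = biomass, deadwood_volume = deadwood,
    deciduous_share = decid, large_trees = large, recreation_index = recreation
  )
}

#' Generate a synthetic simulator dataset
#'
#' Deterministic given the configuration: the same `synth_config` always
#' yields the same table.  Behavioral contracts: `set_aside` regimes have
#' zero harvest in every period and non-decreasing expected deadwood;
#' rotation regimes show at least one harvest pulse; `recreation_index` stays
#' in \[0, 1\]; roughly `p_peat` of stands carry the `PEAT` flag.
#'
#' @param config a [synth_config()].
#' @return a `forest_data` object.
#' @export
generate_forest <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  years <- config$year_start + config$year_step * (seq_len(config$n_periods) - 1L)
  withr::with_seed(config$seed, {
    width <- max(3L, nchar(as.character(config$n_stands)))
    ids <- sprintf(paste0("S%0", width, "d"), seq_len(config$n_stands))
    info <- data.frame(
      stand = ids,
      area = round(stats::runif(config$n_stands, 0.5, 5), 2),
      PEAT = stats::runif(config$n_stands) < config$p_peat,
      stringsAsFactors = FALSE
    )
    n_blocks <- config$n_stands * length(config$regimes)
    blocks <- vector("list", n_blocks)
    block_stand <- character(n_blocks)
    block_regime <- character(n_blocks)
    k <- 0L
    for (s in seq_len(config$n_stands)) {
      stand <- list(
        site = exp(stats::rnorm(1, 0, 0.25)),
        v0 = stats::runif(1, 50, 250),
        dw0 = stats::runif(1, 1, 8),
        decid = stats::rnorm(1, -0.5, 0.6),
        phase = sample.int(6L, 1)
      )
      for (r in seq_along(config$regimes)) {
        k <- k + 1L
        blocks[[k]] <- .synth_trajectory(stand, config$regimes[[r]],
                                         config$n_periods, config$noise_sd, r)
        block_stand[k] <- ids[s]
        block_regime[k] <- names(config$regimes)[r]
      }
    }
    traj <- do.call(rbind, blocks)
    d <- data.frame(
      stand = rep(block_stand, each = config$n_periods),
      regime = rep(block_regime, each = config$n_periods),
      year = rep(years, times = n_blocks),
      traj, stringsAsFactors = FALSE
    )
    forest_data(d, info)
  })
}
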