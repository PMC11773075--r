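# Synthetic catch-effort generator: logistic dynamics, proportional
# catchability, multiplicative log-normal observation error on catch.

#' Simulation configuration
#'
#' @param true_params A [biological_params()] object driving the dynamics.
#' @param initial_depletion First-year biomass as a fraction of K, in (0, 1].
#' @param obs_sigma Standard deviation of the log-catch observation error
#'   (unitless, >= 0). The multiplicative error is mean-one
#'   (bias-corrected), so expected observed catch equals true catch.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(true_params, initial_depletion = 1,
                              obs_sigma = 0.2, seed = 1L) {
  stopifnot(inherits(true_params, "biological_params"))
  assert_scalar_num(initial_depletion, "initial_depletion")
  assert_scalar_num(obs_sigma, "obs_sigma")
  if (initial_depletion <= 0 || initial_depletion > 1)
    stop_domain("initial_depletion must be in (0, 1]")
  if (obs_sigma < 0) stop_domain("obs_sigma must be >= 0")
  structure(list(true_params = true_params,
                 initial_depletion = initial_depletion,
                 obs_sigma = obs_sigma, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Build an annual effort trajectory
#'
#' Three shapes: `"constant"`, `"ramp"` (linear interpolation from `e_start`
#' to `e_end`), and `"one_way_trip"` (rise to `e_end` over the first 60% of
#' the series, then a plateau with small seeded jitter) — the latter gives
#' the contrast-rich effort history a production-model fit needs.
#'
#' @param n_years Number of years, at least 2.
#' @param pattern One of `"constant"`, `"ramp"`, `"one_way_trip"`.
#' @param e_start,e_end Effort in boats at the start/end; non-negative.
#' @param seed Integer seed for the plateau jitter (deterministic given it).
#' @param start_year First calendar year.
#' @return An `effort_path` data frame with columns `year`, `effort_boats`.
#' @export
make_effort_path <- function(n_years, pattern = c("one_way_trip", "constant", "ramp"),
                             e_start, e_end = e_start, seed = 1L,
                             start_year = 1990L) {
  pattern <- match.arg(pattern)
  if (n_years < 2) stop_domain("n_years must be >= 2")
  if (e_start < 0 || e_end < 0) stop_domain("efforts must be >= 0")
  years <- seq.int(start_year, length.out = n_years)
  eff <- switch(pattern,
    constant = rep(e_start, n_years),
    ramp = seq(e_start, e_end, length.out = n_years),
    one_way_trip = {
      n_rise <- max(2L, ceiling(0.6 * n_years))
      rise <- seq(e_start, e_end, length.out = n_rise)
      plateau <- rep(e_end, n_years - n_rise)
      jitter <- with_seed(seed,
                          stats::rnorm(length(plateau), 0, 0.02 * max(e_end, 1)))
      c(rise, pmax(plateau + jitter, 0))
    })
  structure(data.frame(year = as.integer(years), effort_boats = eff),
            class = c("effort_path", "data.frame"))
}

#' Simulate a catch-effort series
#'
#' Forward-simulates the annual Schaefer dynamics along an effort path.
#' Biomass starts at `initial_depletion * K`; the true catch each year is
#' \eqn{qE_tB_t}; the observed catch is the true catch times a mean-one
#' log-normal factor \eqn{\exp(\epsilon_t - \sigma^2/2)},
#' \eqn{\epsilon_t \sim N(0, \sigma^2)}. The biomass update uses the true
#' (noise-free) catch: the error is observation-only, matching an
#' observation-error estimator. A stock that hits the collapse floor is
#' returned flagged, not truncated.
#'
#' @param config A [simulation_config()].
#' @param path An effort path from [make_effort_path()].
#' @return A [catch_effort_series()] with attributes `true_biomass` (the
#'   simulated trajectory, one value per year), `true_catch`, and `collapsed`.
#' @export
simulate_fishery <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"), inherits(path, "effort_path"))
  bio <- config$true_params
  n <- nrow(path)
  eps <- if (config$obs_sigma > 0)
    with_seed(config$seed, stats::rnorm(n, 0, config$obs_sigma))
  else rep(0, n)
  B <- numeric(n); catch_true <- numeric(n)
  state <- biomass_state(path$year[1], config$initial_depletion * bio$K)
  collapsed <- FALSE
  for (t in seq_len(n)) {
    B[t] <- state$biomass
    catch_true[t] <- catch_rate(path$effort_boats[t], state$biomass, bio)
    state <- step_biomass(state, catch_true[t], bio)
    collapsed <- collapsed || state$collapsed
  }
  obs <- catch_true * exp(eps - config$obs_sigma^2 / 2)
  out <- catch_effort_series(path$year, obs, path$effort_boats)
  attr(out, "true_biomass") <- B
  attr(out, "true_catch") <- catch_true
  attr(out, "collapsed") <- collapsed
  out
}

#' Preset simulation scenarios for the four Omani fisheries
#'
#' One scenario per species — Indian mackerel (*Rastrelliger kanagurta*),
#' yellowfin tuna (*Thunnus albacares*), kingfish (*Scomberomorus
#' commerson*) and Indian oil sardine (*Sardinella longiceps*) — with true
#' parameters equal to the published Schaefer estimates for each stock (see
#' [oman_benchmarks()]), initial depletion set to the stock's
#' initial-proportion value, and a 31-year (1990-2020) one-way-trip effort
#' path rising from 0.1x to 1.5x the species' MSY effort.
#'
#' @param obs_sigma Log-catch observation error; default 0.2.
#' @param seed Base integer seed; each species offsets it deterministically.
#' @return Named list of `list(config, path)` pairs.
#' @export
oman_like_scenarios <- function(obs_sigma = 0.2, seed = 1L) {
  bm <- oman_benchmarks()
  out <- lapply(seq_along(bm), function(i) {
    b <- bm[[i]]
    e_msy <- b$bio$r / (2 * b$bio$q)
    list(config = simulation_config(b$bio,
                                    initial_depletion = b$ip,
                                    obs_sigma = obs_sigma,
                                    seed = seed + i),
         path = make_effort_path(31L, "one_way_trip",
                                 e_start = 0.1 * 1.5 * e_msy,
                                 e_end = 1.5 * e_msy, seed = seed + 100L + i))
  })
  names(out) <- names(bm)
  out
}
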