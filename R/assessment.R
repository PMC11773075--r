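# Stock assessment from a catch-effort series: dynamic Schaefer fit with
# log-normal observation error and an initial-proportion input, plus the
# equilibrium CPUE regression and derived quantities.

#' Initial proportion of a catch series
#'
#' First-year catch divided by the maximum catch of the series. Used as the
#' initial-depletion input of the dynamic fit.
#'
#' @param series A [catch_effort_series()].
#' @return A fraction in (0, 1].
#' @export
compute_ip <- function(series) {
  stopifnot(inherits(series, "catch_effort_series"))
  if (nrow(series) == 0 || all(series$catch_t == 0))
    stop_domain("initial proportion undefined: no positive catch in series")
  series$catch_t[1] / max(series$catch_t)
}

#' Surplus production at a given (final) biomass
#'
#' The replacement yield \eqn{rB_f(1 - B_f/K)}: the catch that would hold
#' the stock constant at biomass `final_biomass`.
#'
#' @param final_biomass Biomass in tonnes, non-negative (vectorised).
#' @param bio A [biological_params()] object.
#' @return Replacement yield in tonnes per year.
#' @export
replacement_yield <- function(final_biomass, bio) {
  growth_increment(final_biomass, bio)
}

#' Equilibrium CPUE regression
#'
#' Ordinary least squares of CPUE on effort, \eqn{CPUE = a + bE}. Under
#' equilibrium Schaefer dynamics \eqn{a = qK} and \eqn{b = -q^2K/r}, so the
#' effort maximising yield is \eqn{-a/(2b)} and the yield there is
#' \eqn{-a^2/(4b)} — both available without knowing q. Given an external q,
#' [params_from_cpue_line()] recovers K and r.
#'
#' @param series A [catch_effort_series()] with at least 3 rows of positive
#'   effort.
#' @return A list with `line` (a [cpue_line()] carrying the regression R²),
#'   `e_at_max` (boats), `yield_at_max` (tonnes/yr), and `meaningful`
#'   (`FALSE`, with `e_at_max`/`yield_at_max` `NA`, when the slope is not
#'   negative: CPUE does not decline with effort and the equilibrium
#'   estimates are undefined).
#' @export
fit_equilibrium_cpue <- function(series) {
  stopifnot(inherits(series, "catch_effort_series"))
  ok <- series$effort_boats > 0 & is.finite(series$cpue)
  if (sum(ok) < 3)
    stop_estimation("need at least 3 observations with positive effort")
  fit <- stats::lm(cpue ~ effort_boats, data = series[ok, , drop = FALSE])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  ss_tot <- sum((series$cpue[ok] - mean(series$cpue[ok]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  line <- cpue_line(a, b, r_squared = r2)
  if (b >= 0 || a <= 0) {
    warning("CPUE does not decline with effort (a = ", signif(a, 4), ", b = ",
            signif(b, 4), "); equilibrium estimates undefined")
    return(list(line = line, e_at_max = NA_real_, yield_at_max = NA_real_,
                meaningful = FALSE))
  }
  list(line = line, e_at_max = -a / (2 * b), yield_at_max = -a^2 / (4 * b),
       meaningful = TRUE)
}

default_schaefer_bounds <- function(series) {
  cmax <- max(series$catch_t)
  list(K = c(cmax, 100 * cmax), q = c(1e-8, 1e-2), r = c(0.01, 2))
}

# Predicted catch trajectory of the annual Schaefer recursion.
# conditioning = "predicted": deplete with the model's own catch (observation-
# error estimator); "observed": deplete with the recorded catch.
schaefer_predict <- function(K, q, r, series, ip,
                             conditioning = c("predicted", "observed")) {
  conditioning <- match.arg(conditioning)
  n <- nrow(series)
  eff <- series$effort_boats
  obs <- series$catch_t
  floor <- biomass_floor(K)
  B <- numeric(n + 1)
  pred <- numeric(n)
  B[1] <- ip * K
  collapsed <- FALSE
  for (t in seq_len(n)) {
    pred[t] <- q * eff[t] * B[t]
    removal <- if (conditioning == "observed") obs[t] else pred[t]
    b_next <- B[t] + r * B[t] * (1 - B[t] / K) - removal
    if (b_next < floor) { b_next <- floor; collapsed <- TRUE }
    B[t + 1] <- b_next
  }
  list(pred = pred, biomass = B, collapsed = collapsed)
}

schaefer_loss <- function(K, q, r, series, ip, conditioning) {
  pr <- schaefer_predict(K, q, r, series, ip, conditioning)
  ok <- series$catch_t > 0 & series$effort_boats > 0 & pr$pred > 0
  sum((log(series$catch_t[ok]) - log(pr$pred[ok]))^2)
}

# box-constrained parameterisation: unconstrained u <-> log-parameter within
# [log lo, log hi] via a scaled logistic
u_to_par <- function(u, lo, hi) exp(log(lo) + (log(hi) - log(lo)) * stats::plogis(u))
par_to_u <- function(p, lo, hi) stats::qlogis((log(p) - log(lo)) / (log(hi) - log(lo)))

#' Dynamic Schaefer fit with log-normal observation error
#'
#' Estimates (K, q, r) by minimising the log-normal observation-error sum of
#' squares \eqn{\sum_t [\ln C_t - \ln(qE_t\hat B_t)]^2}, where the predicted
#' biomass follows the annual recursion
#' \eqn{\hat B_{t+1} = \hat B_t + r\hat B_t(1-\hat B_t/K) - \hat C_t} with
#' \eqn{\hat B_1 = ip \cdot K}. By default the recursion is depleted by the
#' model-predicted catch (pure observation-error estimator);
#' `conditioning = "observed"` uses the recorded catch instead, for
#' sensitivity analysis. Optimisation is a seeded multi-start Nelder-Mead
#' search in a log-spaced parameter box; starts landing on the box boundary
#' are flagged, not silently accepted.
#'
#' @param series A [catch_effort_series()] with at least 10 years of data.
#' @param ip Initial proportion passed as the initial-depletion input
#'   \eqn{B_1/K}; defaults to [compute_ip()] of the series.
#' @param bounds List with elements `K`, `q`, `r`, each `c(lo, hi)`;
#'   defaults to K in `[max catch, 100*max catch]`, q in `[1e-8, 1e-2]`,
#'   r in `[0.01, 2]`.
#' @param n_starts Number of multi-start points (default 20).
#' @param seed Integer seed making the starts reproducible.
#' @param conditioning `"predicted"` (default) or `"observed"` catch in the
#'   biomass update.
#' @return An object of class `assessment_result`: `params`
#'   ([biological_params()]), `ip`, `msy`, `replacement_yield`,
#'   `final_biomass` (stock after the last modeled year), `r_squared`
#'   (observed vs predicted log-catch), `loss`, `converged`, `at_bounds`,
#'   `collapsed`, plus the predicted biomass trajectory in
#'   `biomass_trajectory`.
#' @export
fit_dynamic_schaefer <- function(series, ip = compute_ip(series),
                                 bounds = default_schaefer_bounds(series),
                                 n_starts = 20L, seed = 1L,
                                 conditioning = c("predicted", "observed")) {
  stopifnot(inherits(series, "catch_effort_series"))
  conditioning <- match.arg(conditioning)
  if (nrow(series) < 10)
    stop_estimation("need at least 10 years of data for the dynamic fit")
  if (any(series$catch_t[series$effort_boats > 0] <= 0))
    stop_estimation("positive effort with zero catch breaks the log-normal loss")
  if (ip <= 0 || ip > 1) stop_domain("ip must be in (0, 1]")
  lo <- c(bounds$K[1], bounds$q[1], bounds$r[1])
  hi <- c(bounds$K[2], bounds$q[2], bounds$r[2])

  obj <- function(u) {
    p <- u_to_par(u, lo, hi)
    schaefer_loss(p[1], p[2], p[3], series, ip, conditioning)
  }

  # moment-style heuristic start: K from catch scale, q from mean CPUE / (K/2)
  cpue_bar <- mean(series$cpue, na.rm = TRUE)
  k0 <- min(max(10 * max(series$catch_t), lo[1] * 1.01), hi[1] * 0.99)
  q0 <- min(max(cpue_bar / (0.5 * k0), lo[2] * 1.01), hi[2] * 0.99)
  starts <- with_seed(seed, {
    rand <- replicate(max(n_starts - 1L, 0L),
                      stats::runif(3, log(lo) + 0.05 * (log(hi) - log(lo)),
                                   log(hi) - 0.05 * (log(hi) - log(lo))))
    cbind(log(c(k0, q0, 0.3)), rand)
  })

  best <- NULL
  n_conv <- 0L
  for (j in seq_len(ncol(starts))) {
    u0 <- par_to_u(exp(starts[, j]), lo, hi)
    fit <- stats::optim(u0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the winner with a restart from its own optimum
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))

  p <- u_to_par(best$par, lo, hi)
  names(p) <- c("K", "q", "r")
  rel_pos <- (log(p) - log(lo)) / (log(hi) - log(lo))
  at_bounds <- any(rel_pos < 0.005 | rel_pos > 0.995)
  params <- biological_params(p[["K"]], p[["q"]], p[["r"]])
  pr <- schaefer_predict(p[["K"]], p[["q"]], p[["r"]], series, ip, conditioning)
  ok <- series$catch_t > 0 & series$effort_boats > 0 & pr$pred > 0
  lobs <- log(series$catch_t[ok]); lpred <- log(pr$pred[ok])
  ss_res <- sum((lobs - lpred)^2)
  ss_tot <- sum((lobs - mean(lobs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  final_b <- pr$biomass[length(pr$biomass)]

  structure(list(params = params, ip = ip, msy = msy(params),
                 replacement_yield = replacement_yield(final_b, params),
                 final_biomass = final_b,
                 r_squared = r2, loss = best$value,
                 converged = n_conv > 0L && best$convergence == 0,
                 at_bounds = at_bounds, collapsed = pr$collapsed,
                 conditioning = conditioning,
                 biomass_trajectory = pr$biomass,
                 n_starts = n_starts, bounds = bounds),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat("Dynamic Schaefer assessment (log-normal observation error)\n")
  cat("  IP (B1/K input)  :", signif(x$ip, 4), "\n")
  cat("  K                :", fmt_num(x$params$K), "t\n")
  cat("  q                :", format(signif(x$params$q, 6)), "per boat-year\n")
  cat("  r                :", signif(x$params$r, 6), "per year\n")
  cat("  MSY = rK/4       :", fmt_num(x$msy), "t/yr\n")
  cat("  replacement yield:", fmt_num(x$replacement_yield), "t/yr\n")
  cat("  final biomass    :", fmt_num(x$final_biomass), "t\n")
  cat("  R² (log catch)   :", signif(x$r_squared, 4),
      " loss:", format(x$loss, digits = 4), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$at_bounds) cat("  WARNING: parameters at bounds (possible non-identifiability)\n")
  if (x$collapsed) cat("  note: predicted stock hit the collapse floor\n")
  invisible(x)
}

#' One-row summary in the published key-parameter layout
#'
#' @param result An `assessment_result`.
#' @param species Optional species label.
#' @return A one-row data frame with columns `species`, `ip`, `K_t`, `q`,
#'   `r`, `msy_t`, `r_yield_t`, `final_biomass_t`, `r_squared`.
#' @export
assessment_row <- function(result, species = NA_character_) {
  stopifnot(inherits(result, "assessment_result"))
  data.frame(species = species, ip = result$ip, K_t = result$params$K,
             q = result$params$q, r = result$params$r, msy_t = result$msy,
             r_yield_t = result$replacement_yield,
             final_biomass_t = result$final_biomass,
             r_squared = result$r_squared)
}
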