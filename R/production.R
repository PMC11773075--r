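# Pure Schaefer-system mathematics: logistic growth, proportional harvest,
# the equilibrium yield parabola, and the CPUE-effort line.

#' Biological parameters of a Schaefer stock
#'
#' Bundles the three parameters of the logistic surplus-production model:
#' carrying capacity \eqn{K} (tonnes), catchability coefficient \eqn{q}
#' (per boat-year) and intrinsic growth rate \eqn{r} (per year). Maximum
#' sustainable yield is the derived quantity \eqn{rK/4}.
#'
#' @param K Carrying capacity in tonnes; must be positive.
#' @param q Catchability coefficient (fraction of stock taken by one boat in
#'   one year); must be positive.
#' @param r Intrinsic growth rate per year; must be non-negative.
#' @return An object of class `biological_params`.
#' @examples
#' bio <- biological_params(K = 163745.5, q = 2.177e-5, r = 0.260469)
#' msy(bio) # rK/4
#' @export
biological_params <- function(K, q, r) {
  assert_scalar_num(K, "K"); assert_scalar_num(q, "q"); assert_scalar_num(r, "r")
  if (K <= 0) stop_domain("carrying capacity K must be > 0")
  if (q <= 0) stop_domain("catchability q must be > 0")
  if (r < 0) stop_domain("intrinsic growth rate r must be >= 0")
  structure(list(K = K, q = q, r = r), class = "biological_params")
}

#' @export
print.biological_params <- function(x, ...) {
  cat("Schaefer biological parameters\n")
  cat("  K (carrying capacity):", fmt_num(x$K), "t\n")
  cat("  q (catchability)     :", format(x$q), "per boat-year\n")
  cat("  r (growth rate)      :", format(x$r), "per year\n")
  cat("  MSY = rK/4           :", fmt_num(msy(x)), "t/yr\n")
  invisible(x)
}

#' Maximum sustainable yield of a parameter set
#'
#' @param bio A [biological_params()] object.
#' @return MSY in tonnes per year, \eqn{rK/4}.
#' @export
msy <- function(bio) {
  stopifnot(inherits(bio, "biological_params"))
  bio$r * bio$K / 4
}

#' Logistic surplus production
#'
#' Net growth of the stock at biomass `biomass`:
#' \eqn{rx(1 - x/K)}. Zero at the origin and at carrying capacity, maximal
#' (equal to MSY) at \eqn{K/2}.
#'
#' @param biomass Stock biomass in tonnes; non-negative (vectorised).
#' @param bio A [biological_params()] object.
#' @return Surplus production in tonnes per year.
#' @export
growth_increment <- function(biomass, bio) {
  stopifnot(inherits(bio, "biological_params"))
  if (any(!is.finite(biomass)) || any(biomass < 0))
    stop_domain("biomass must be finite and >= 0")
  bio$r * biomass * (1 - biomass / bio$K)
}

#' Instantaneous catch under proportional catchability
#'
#' The harvest-rate hypothesis: catch per unit effort is proportional to
#' stock density, so the catch rate is \eqn{qEx}.
#'
#' @param effort Fishing effort in boats; non-negative (vectorised).
#' @param biomass Stock biomass in tonnes; non-negative (vectorised).
#' @param q Catchability coefficient, or a [biological_params()] object whose
#'   `q` is used.
#' @return Catch in tonnes per year.
#' @export
catch_rate <- function(effort, biomass, q) {
  if (inherits(q, "biological_params")) q <- q$q
  if (any(!is.finite(effort)) || any(effort < 0)) stop_domain("effort must be >= 0")
  if (any(!is.finite(biomass)) || any(biomass < 0)) stop_domain("biomass must be >= 0")
  if (any(q <= 0)) stop_domain("q must be > 0")
  q * effort * biomass
}

#' Annual biomass state
#'
#' @param year Calendar year (integer).
#' @param biomass Stock biomass in tonnes, non-negative.
#' @param collapsed Logical; `TRUE` when the stock has been clamped at the
#'   collapse floor.
#' @return An object of class `biomass_state`.
#' @export
biomass_state <- function(year, biomass, collapsed = FALSE) {
  assert_scalar_num(year, "year"); assert_scalar_num(biomass, "biomass")
  if (biomass < 0) stop_domain("biomass must be >= 0")
  structure(list(year = as.integer(year), biomass = biomass,
                 collapsed = isTRUE(collapsed)),
            class = "biomass_state")
}

# Collapse floor: stocks are clamped at a small positive fraction of K so the
# log-normal observation likelihood keeps a positive predicted catch.
biomass_floor <- function(K) 1e-6 * K

#' Advance the stock one year under the annual difference equation
#'
#' \eqn{B_{t+1} = B_t + rB_t(1 - B_t/K) - C_t}, the discrete annual form of
#' the logistic-harvest dynamics that matches annual catch bookkeeping.
#' Biomass is floored at \eqn{10^{-6}K} and flagged `collapsed` rather than
#' allowed to go negative.
#'
#' @param state A [biomass_state()].
#' @param catch Catch removed during the year, in tonnes; non-negative.
#' @param bio A [biological_params()] object.
#' @return The [biomass_state()] for the following year.
#' @export
step_biomass <- function(state, catch, bio) {
  stopifnot(inherits(state, "biomass_state"), inherits(bio, "biological_params"))
  assert_scalar_num(catch, "catch")
  if (catch < 0) stop_domain("catch must be >= 0")
  b <- state$biomass + growth_increment(state$biomass, bio) - catch
  floor <- biomass_floor(bio$K)
  collapsed <- b < floor
  biomass_state(state$year + 1L, max(b, floor), collapsed = collapsed)
}

#' Equilibrium (sustainable) yield at a given effort
#'
#' The yield parabola \eqn{H(E) = qEK - q^2E^2K/r}: zero at \eqn{E = 0} and
#' \eqn{E = r/q}, maximal (\eqn{rK/4}) at \eqn{E = r/(2q)}. The raw parabola
#' is returned, so values are negative beyond \eqn{r/q}; callers working with
#' reference points restrict to \eqn{[0, r/q]}.
#'
#' @param effort Fishing effort in boats; non-negative (vectorised).
#' @param bio A [biological_params()] object with `r > 0` when `effort > 0`.
#' @return Sustainable yield in tonnes per year.
#' @export
equilibrium_yield <- function(effort, bio) {
  stopifnot(inherits(bio, "biological_params"))
  if (any(!is.finite(effort)) || any(effort < 0)) stop_domain("effort must be >= 0")
  if (bio$r == 0 && any(effort > 0))
    stop_domain("equilibrium yield undefined for r = 0 with positive effort")
  if (bio$r == 0) return(rep(0, length(effort)))
  bio$q * effort * bio$K - bio$q^2 * effort^2 * bio$K / bio$r
}

#' CPUE-effort line
#'
#' The equilibrium relationship \eqn{CPUE = a + bE} with \eqn{a = qK} and
#' \eqn{b = -q^2K/r}. A biologically meaningful fishery has a positive
#' intercept and a negative slope.
#'
#' @param a Intercept in tonnes per boat.
#' @param b Slope in tonnes per boat squared.
#' @param r_squared Optional goodness of fit in \[0, 1\].
#' @return An object of class `cpue_line`.
#' @export
cpue_line <- function(a, b, r_squared = NA_real_) {
  assert_scalar_num(a, "a"); assert_scalar_num(b, "b")
  structure(list(a = a, b = b, r_squared = r_squared), class = "cpue_line")
}

#' @export
print.cpue_line <- function(x, ...) {
  cat("CPUE-effort line: CPUE =", format(x$a), if (x$b < 0) "-" else "+",
      format(abs(x$b)), "x E",
      if (!is.na(x$r_squared)) paste0("  (R² = ", signif(x$r_squared, 4), ")"),
      "\n")
  invisible(x)
}

#' Predicted CPUE at a given effort
#'
#' @param effort Fishing effort in boats (vectorised).
#' @param line A [cpue_line()].
#' @return CPUE in tonnes per boat, \eqn{a + bE}.
#' @export
cpue_from_effort <- function(effort, line) {
  stopifnot(inherits(line, "cpue_line"))
  line$a + line$b * effort
}

#' CPUE-effort line implied by biological parameters
#'
#' Forward map onto the line coefficients: \eqn{a = qK}, \eqn{b = -q^2K/r}.
#'
#' @param bio A [biological_params()] object with `r > 0`.
#' @return A [cpue_line()].
#' @export
cpue_line_from_params <- function(bio) {
  stopifnot(inherits(bio, "biological_params"))
  if (bio$r <= 0) stop_domain("r must be > 0 to form the CPUE line slope")
  cpue_line(a = bio$q * bio$K, b = -bio$q^2 * bio$K / bio$r)
}

#' Biological parameters from an estimated CPUE-effort line
#'
#' Inverts the equilibrium line given an externally known catchability:
#' \eqn{K = a/q}, \eqn{r = -aq/b}. Round-trips exactly with
#' [cpue_line_from_params()].
#'
#' @param line A [cpue_line()] with `a > 0` and `b < 0`.
#' @param q Catchability coefficient, positive.
#' @return A [biological_params()] object.
#' @export
params_from_cpue_line <- function(line, q) {
  stopifnot(inherits(line, "cpue_line"))
  assert_scalar_num(q, "q")
  if (q <= 0) stop_domain("q must be > 0")
  if (line$a <= 0 || line$b >= 0)
    stop_estimation("no biologically meaningful parabola: need a > 0 and b < 0 ",
                    "(got a = ", format(line$a), ", b = ", format(line$b), ")")
  biological_params(K = line$a / q, q = q, r = -line$a * q / line$b)
}
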