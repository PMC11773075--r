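# Discounted optimal sustainable yield: the singular-path (golden rule)
# equilibrium of the present-value harvesting problem.

#' Optimal stock level under discounting
#'
#' The stationary stock of the discounted harvesting problem, in closed form:
#' \deqn{x^* = \frac{K}{4}\left[\left(1+\theta-\frac{\delta}{r}\right) +
#'   \sqrt{\left(1+\theta-\frac{\delta}{r}\right)^2 +
#'   \frac{8\theta\delta}{r}}\right]}
#' with \eqn{\theta = c/(pqK)}. Limits: \eqn{\delta = 0} gives the MEY stock
#' \eqn{K/2 + c/(2pq)}; \eqn{\delta \to \infty} gives the open-access stock
#' \eqn{c/(pq)}. The closed form is the root of the golden-rule marginal
#' condition \eqn{F'(x) - c'(x)F(x)/(p - c(x)) = \delta} with stock-dependent
#' harvest cost \eqn{c(x) = c/(qx)}.
#'
#' @param bio A [biological_params()] object with `r > 0`.
#' @param econ An [economic_params()] object with \eqn{\theta < 1}.
#' @param delta Discount rate per year, non-negative (vectorised).
#' @return Optimal biomass x* in tonnes.
#' @export
optimal_stock <- function(bio, econ, delta) {
  stopifnot(inherits(bio, "biological_params"), inherits(econ, "economic_params"))
  if (bio$r <= 0) stop_domain("optimal stock undefined for r = 0")
  if (any(!is.finite(delta)) || any(delta < 0))
    stop_domain("delta must be finite and >= 0")
  theta <- cost_price_ratio(bio, econ)
  if (theta >= 1)
    stop_domain("theta = c/(pqK) >= 1: fishing never profitable, no interior optimum")
  a <- 1 + theta - delta / bio$r
  bio$K / 4 * (a + sqrt(a^2 + 8 * theta * delta / bio$r))
}

#' Discounted optimum: stock, harvest, effort, profit, present value
#'
#' Evaluates the singular-path equilibrium at discount rate `delta`:
#' \eqn{H^* = rx^*(1-x^*/K)}, \eqn{E^* = H^*/(qx^*)}, sustainable profit
#' \eqn{\pi = pH^* - (c/(qx^*))H^*}, and present value \eqn{\pi/\delta}
#' (infinite at \eqn{\delta = 0}, where the optimum coincides with MEY).
#'
#' @inheritParams optimal_stock
#' @param delta A single discount rate per year, non-negative.
#' @return An object of class `discounted_optimum` with fields `delta`,
#'   `x_star`, `h_star`, `e_star`, `profit`, `present_value`, and
#'   `at_collapse_bound` (`TRUE` when x* sits at the open-access floor
#'   c/(pq) to within 0.1%).
#' @export
discounted_optimum <- function(bio, econ, delta) {
  assert_scalar_num(delta, "delta")
  x <- optimal_stock(bio, econ, delta)
  h <- growth_increment(x, bio)
  e <- h / (bio$q * x)
  profit <- econ$price * h - econ$unit_cost / (bio$q * x) * h
  pv <- if (delta > 0) profit / delta else Inf
  x_oa <- econ$unit_cost / (econ$price * bio$q)
  structure(list(delta = delta, x_star = x, h_star = h, e_star = e,
                 profit = profit, present_value = pv,
                 at_collapse_bound = x <= x_oa * 1.001),
            class = "discounted_optimum")
}

#' @export
print.discounted_optimum <- function(x, ...) {
  cat(sprintf("Discounted optimum at delta = %s/yr\n", format(x$delta)))
  cat(sprintf("  x* = %s t, H* = %s t/yr, E* = %s boats\n",
              fmt_num(x$x_star), fmt_num(x$h_star), fmt_num(x$e_star)))
  cat(sprintf("  profit = %s OMR/yr, PV = %s OMR\n",
              fmt_num(x$profit),
              if (is.finite(x$present_value)) fmt_num(x$present_value)
              else "infinite (delta = 0)"))
  invisible(x)
}

#' Sweep the discounted optimum over a discount-rate grid
#'
#' One row per discount rate, in input order — the basis for plots of
#' optimal biomass, harvest, effort and profit against the discount rate.
#' Profit and x* are non-increasing in delta; E* is non-decreasing.
#'
#' @inheritParams optimal_stock
#' @param deltas Vector of discount rates per year, each >= 0.
#' @return A data frame with columns `delta`, `x_star`, `h_star`, `e_star`,
#'   `profit`, `present_value`.
#' @export
discount_sweep <- function(bio, econ, deltas = seq(0, 1, by = 0.01)) {
  rows <- lapply(deltas, function(d) {
    o <- discounted_optimum(bio, econ, d)
    data.frame(delta = d, x_star = o$x_star, h_star = o$h_star,
               e_star = o$e_star, profit = o$profit,
               present_value = o$present_value)
  })
  do.call(rbind, rows)
}
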