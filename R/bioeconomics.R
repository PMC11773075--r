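# Static reference points with revenue/cost/rent accounting: maximum
# sustainable yield, maximum economic yield, open-access equilibrium.

#' Economic parameters of a fishery
#'
#' @param price Ex-vessel price p in OMR per tonne; positive.
#' @param unit_cost Cost of one boat-year of effort c in OMR; non-negative.
#' @return An object of class `economic_params`.
#' @export
economic_params <- function(price, unit_cost) {
  assert_scalar_num(price, "price"); assert_scalar_num(unit_cost, "unit_cost")
  if (price <= 0) stop_domain("price must be > 0")
  if (unit_cost < 0) stop_domain("unit_cost must be >= 0")
  structure(list(price = price, unit_cost = unit_cost), class = "economic_params")
}

#' @export
print.economic_params <- function(x, ...) {
  cat("Fishery economics: price", fmt_num(x$price), "OMR/t,",
      "unit cost", fmt_num(x$unit_cost), "OMR/boat-year\n")
  invisible(x)
}

#' Cost-price ratio theta = c / (pqK)
#'
#' The dimensionless ratio governing every economic reference point: the
#' cost of one unit of effort over the revenue it earns on the unfished
#' stock. An interior (profitable) fishery requires theta < 1.
#'
#' @param bio A [biological_params()] object.
#' @param econ An [economic_params()] object.
#' @return theta, non-negative.
#' @export
cost_price_ratio <- function(bio, econ) {
  stopifnot(inherits(bio, "biological_params"), inherits(econ, "economic_params"))
  econ$unit_cost / (econ$price * bio$q * bio$K)
}

#' A management regime's equilibrium reference point
#'
#' @param regime One of `"MSY"`, `"MEY"`, `"OAE"`, `"OSY"`.
#' @param effort Boats.
#' @param harvest Tonnes per year.
#' @param biomass Tonnes.
#' @param total_revenue,total_cost OMR per year; rent is their difference.
#' @param feasible `FALSE` marks a structurally infeasible target (e.g. a
#'   fishery that is never profitable).
#' @return An object of class `reference_point`.
#' @export
reference_point <- function(regime, effort, harvest, biomass,
                            total_revenue, total_cost, feasible = TRUE) {
  regime <- match.arg(regime, c("MSY", "MEY", "OAE", "OSY"))
  structure(list(regime = regime, effort = effort, harvest = harvest,
                 biomass = biomass, total_revenue = total_revenue,
                 total_cost = total_cost,
                 rent = total_revenue - total_cost,
                 feasible = isTRUE(feasible)),
            class = "reference_point")
}

#' @export
print.reference_point <- function(x, ...) {
  cat(sprintf("%s point: E = %s boats, H = %s t, X = %s t\n", x$regime,
              fmt_num(x$effort), fmt_num(x$harvest), fmt_num(x$biomass)))
  cat(sprintf("  TR = %s, TC = %s, rent = %s OMR/yr\n",
              fmt_num(x$total_revenue), fmt_num(x$total_cost), fmt_num(x$rent)))
  if (!x$feasible) cat("  (infeasible: fishing never profitable at these prices/costs)\n")
  invisible(x)
}

point_economics <- function(regime, effort, harvest, biomass, econ,
                            feasible = TRUE) {
  reference_point(regime, effort, harvest, biomass,
                  total_revenue = econ$price * harvest,
                  total_cost = econ$unit_cost * effort,
                  feasible = feasible)
}

#' Maximum sustainable yield reference point
#'
#' \eqn{E_{MSY} = r/(2q)}, \eqn{H_{MSY} = rK/4}, \eqn{X_{MSY} = K/2},
#' with revenue, cost and rent evaluated at those levels.
#'
#' @param bio A [biological_params()] object.
#' @param econ An [economic_params()] object.
#' @return A [reference_point()].
#' @export
msy_point <- function(bio, econ) {
  stopifnot(inherits(bio, "biological_params"), inherits(econ, "economic_params"))
  point_economics("MSY", effort = bio$r / (2 * bio$q), harvest = msy(bio),
                  biomass = bio$K / 2, econ = econ)
}

#' Maximum economic yield reference point
#'
#' The rent-maximising sustainable equilibrium:
#' \eqn{E_{MEY} = (r/2q)(1-\theta)}, \eqn{H_{MEY} = (rK/4)(1-\theta^2)},
#' \eqn{X_{MEY} = K/2 + c/(2pq)}, with \eqn{\theta = c/(pqK)}. When
#' \eqn{\theta \ge 1} fishing is never profitable and a zero-effort point is
#' returned with `feasible = FALSE`.
#'
#' @inheritParams msy_point
#' @return A [reference_point()].
#' @export
mey_point <- function(bio, econ) {
  theta <- cost_price_ratio(bio, econ)
  if (theta >= 1)
    return(point_economics("MEY", 0, 0, bio$K, econ, feasible = FALSE))
  point_economics("MEY",
                  effort = bio$r / (2 * bio$q) * (1 - theta),
                  harvest = msy(bio) * (1 - theta^2),
                  biomass = bio$K / 2 + econ$unit_cost / (2 * econ$price * bio$q),
                  econ = econ)
}

#' Open-access equilibrium reference point
#'
#' The zero-rent outcome under unrestricted entry:
#' \eqn{E_{OAE} = (r/q)(1-\theta)} (twice the MEY effort),
#' \eqn{H_{OAE} = (rc/pq)(1-\theta)}, biomass \eqn{c/(pq)}. Total cost is
#' set equal to total revenue so rent is exactly zero by construction. With
#' \eqn{\theta \ge 1} no one enters: the zero-effort point is returned
#' flagged.
#'
#' @inheritParams msy_point
#' @return A [reference_point()].
#' @export
oae_point <- function(bio, econ) {
  theta <- cost_price_ratio(bio, econ)
  if (theta >= 1)
    return(reference_point("OAE", 0, 0, bio$K, 0, 0, feasible = FALSE))
  harvest <- bio$r * econ$unit_cost / (econ$price * bio$q) * (1 - theta)
  tr <- econ$price * harvest
  reference_point("OAE",
                  effort = bio$r / bio$q * (1 - theta),
                  harvest = harvest,
                  biomass = econ$unit_cost / (econ$price * bio$q),
                  total_revenue = tr, total_cost = tr)
}

#' Back-derive price and unit cost from a reference point
#'
#' Inverts the revenue and cost identities: price = TR/H, unit cost = TC/E.
#' Used to recover a fishery's economics from a published regime row.
#'
#' @param ref A [reference_point()] with positive harvest and effort.
#' @return An [economic_params()] object.
#' @export
derive_price_cost <- function(ref) {
  stopifnot(inherits(ref, "reference_point"))
  if (ref$harvest <= 0 || ref$effort <= 0)
    stop_domain("price/cost derivation needs positive harvest and effort")
  economic_params(price = ref$total_revenue / ref$harvest,
                  unit_cost = ref$total_cost / ref$effort)
}

#' Sustainable revenue, cost and rent at an arbitrary effort
#'
#' \eqn{TR = p H(E)} on the equilibrium yield parabola, \eqn{TC = cE},
#' rent their difference. Effort beyond \eqn{r/q} puts the parabola
#' negative; a warning is raised and the raw values returned.
#'
#' @param effort Boats (vectorised).
#' @inheritParams msy_point
#' @return A data frame with columns `effort`, `total_revenue`,
#'   `total_cost`, `rent`.
#' @export
economics_at_effort <- function(effort, bio, econ) {
  stopifnot(inherits(econ, "economic_params"))
  if (bio$r > 0 && any(effort > bio$r / bio$q))
    warning("effort beyond r/q: equilibrium yield parabola is negative there")
  tr <- econ$price * equilibrium_yield(effort, bio)
  tc <- econ$unit_cost * effort
  data.frame(effort = effort, total_revenue = tr, total_cost = tc,
             rent = tr - tc)
}

#' Full reference-point table for one fishery
#'
#' MSY, MEY and OAE rows (plus an OSY row when a discount rate is supplied,
#' computed by [discounted_optimum()]), each with effort, harvest, biomass
#' and the revenue/cost/rent accounting.
#'
#' @inheritParams msy_point
#' @param species Optional species label for the `species` column.
#' @param osy_delta Optional discount rate (1/year) adding an OSY row.
#' @return A data frame with columns `species`, `regime`, `effort_boats`,
#'   `harvest_t`, `biomass_t`, `total_revenue_omr`, `total_cost_omr`,
#'   `profit_omr`.
#' @export
reference_table <- function(bio, econ, species = NA_character_,
                            osy_delta = NULL) {
  pts <- list(msy_point(bio, econ), mey_point(bio, econ), oae_point(bio, econ))
  if (!is.null(osy_delta)) {
    o <- discounted_optimum(bio, econ, osy_delta)
    pts <- c(pts, list(point_economics("OSY", o$e_star, o$h_star, o$x_star, econ)))
  }
  do.call(rbind, lapply(pts, function(p)
    data.frame(species = species, regime = p$regime, effort_boats = p$effort,
               harvest_t = p$harvest, biomass_t = p$biomass,
               total_revenue_omr = p$total_revenue,
               total_cost_omr = p$total_cost, profit_omr = p$rent)))
}
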