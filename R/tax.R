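# Pigouvian tax instruments: the landing tax and effort tax that relocate
# the zero-rent (open-access) equilibrium onto a chosen target regime.

#' Landing tax achieving a target regime
#'
#' A per-tonne levy T such that after-tax revenue equals cost at the target:
#' \eqn{(p - T)H = cE}, i.e. \eqn{T = p - cE/H}. Under the taxed price the
#' open-access equilibrium lands on the target effort. A negative value
#' (target beyond open access, i.e. a subsidy) is returned with a warning.
#'
#' @param econ An [economic_params()] object.
#' @param target A [reference_point()] with positive harvest.
#' @return Tax in OMR per tonne.
#' @export
landing_tax <- function(econ, target) {
  stopifnot(inherits(econ, "economic_params"), inherits(target, "reference_point"))
  if (target$harvest <= 0) stop_domain("landing tax undefined for zero target harvest")
  tax <- econ$price - econ$unit_cost * target$effort / target$harvest
  if (tax < 0)
    warning("negative landing tax: target effort lies beyond open access (subsidy)")
  tax
}

#' Effort tax achieving a target regime
#'
#' A per-boat-year levy T such that revenue equals after-tax cost at the
#' target: \eqn{pH = (c + T)E}, i.e. \eqn{T = pH/E - c}.
#'
#' @param econ An [economic_params()] object.
#' @param target A [reference_point()] with positive effort.
#' @return Tax in OMR per boat-year.
#' @export
effort_tax <- function(econ, target) {
  stopifnot(inherits(econ, "economic_params"), inherits(target, "reference_point"))
  if (target$effort <= 0) stop_domain("effort tax undefined for zero target effort")
  tax <- econ$price * target$harvest / target$effort - econ$unit_cost
  if (tax < 0)
    warning("negative effort tax: target effort lies beyond open access (subsidy)")
  tax
}

#' Tax schedule for one regime target
#'
#' @param regime `"MSY"`, `"MEY"` or `"OSY"`.
#' @param econ An [economic_params()] object.
#' @param target The [reference_point()] to steer open access onto.
#' @return A `tax_schedule` list: `regime`, `landing_tax` (OMR/t),
#'   `effort_tax` (OMR/boat-year), `target_effort`, `target_harvest`.
#' @export
tax_schedule <- function(regime, econ, target) {
  structure(list(regime = regime,
                 landing_tax = landing_tax(econ, target),
                 effort_tax = effort_tax(econ, target),
                 target_effort = target$effort,
                 target_harvest = target$harvest),
            class = "tax_schedule")
}

#' @export
print.tax_schedule <- function(x, ...) {
  cat(sprintf("Taxes targeting %s (E = %s boats, H = %s t):\n", x$regime,
              fmt_num(x$target_effort), fmt_num(x$target_harvest)))
  cat(sprintf("  landing tax %s OMR/t, effort tax %s OMR/boat-year\n",
              fmt_num(x$landing_tax), fmt_num(x$effort_tax)))
  invisible(x)
}

#' Landing and effort taxes for the MSY, MEY and OSY targets
#'
#' Builds the three target regimes from the closed-form reference points
#' (OSY at discount rate `osy_delta`) and returns both instruments for each.
#'
#' @param bio A [biological_params()] object.
#' @param econ An [economic_params()] object with theta < 1.
#' @param osy_delta Discount rate defining the OSY target; default 0.10/yr.
#' @param species Optional species label.
#' @return A data frame with columns `species`, `regime`, `landing_tax_omr_t`,
#'   `effort_tax_omr_boat`, `target_effort_boats`, `target_harvest_t`.
#' @export
tax_table <- function(bio, econ, osy_delta = 0.10, species = NA_character_) {
  osy <- discounted_optimum(bio, econ, osy_delta)
  targets <- list(MSY = msy_point(bio, econ),
                  MEY = mey_point(bio, econ),
                  OSY = point_economics("OSY", osy$e_star, osy$h_star,
                                        osy$x_star, econ))
  do.call(rbind, lapply(names(targets), function(rg) {
    s <- tax_schedule(rg, econ, targets[[rg]])
    data.frame(species = species, regime = rg,
               landing_tax_omr_t = s$landing_tax,
               effort_tax_omr_boat = s$effort_tax,
               target_effort_boats = s$target_effort,
               target_harvest_t = s$target_harvest)
  }))
}
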