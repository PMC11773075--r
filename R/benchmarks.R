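# Published benchmark parameter sets for the four Omani study fisheries:
# Schaefer-model estimates (K, q, r, initial proportion, final biomass) and
# the MSY-regime economics (effort, harvest, total revenue, total cost) from
# which ex-vessel price and unit effort cost are back-derived.

oman_benchmark_data <- function() {
  list(
    R_kanagurta = list(
      species = "Rastrelliger kanagurta",
      K = 163745.5, q = 2.177e-05, r = 0.260469,
      ip = 0.05, final_biomass = 37782.5,
      msy_row = list(effort = 5982, harvest = 10662.65,
                     total_revenue = 102357373.5, total_cost = 51516277.33)),
    T_albacares = list(
      species = "Thunnus albacares",
      K = 463266.9, q = 8.48e-06, r = 0.11217,
      ip = 0.42, final_biomass = 51911.62,
      msy_row = list(effort = 6614, harvest = 12991.16,
                     total_revenue = 321452570.5, total_cost = 44553193.84)),
    S_commerson = list(
      species = "Scomberomorus commerson",
      K = 79007.23, q = 2.93e-05, r = 0.130359,
      ip = 1, final_biomass = 23323.35,
      msy_row = list(effort = 2222, harvest = 2574.83,
                     total_revenue = 3814143.98, total_cost = 2634359.44)),
    S_longiceps = list(
      species = "Sardinella longiceps",
      K = 4675602, q = 8.41e-06, r = 0.116227,
      ip = 0.095, final_biomass = 859669.6,
      msy_row = list(effort = 6913, harvest = 135857.8,
                     total_revenue = 839138246.4, total_cost = 87286012.84)))
}

#' Benchmark parameters and economics for the four Omani fisheries
#'
#' Published Schaefer-model estimates for Indian mackerel, yellowfin tuna,
#' kingfish and Indian oil sardine off Oman (fitted to 1990-2020
#' catch-effort records), together with the MSY-regime revenue/cost row used
#' to back-derive each fishery's ex-vessel price and unit effort cost via
#' [derive_price_cost()].
#'
#' @return A named list, one element per species, each containing:
#'   `species` (label), `bio` ([biological_params()]), `ip` (initial
#'   proportion: first-year catch over maximum catch), `final_biomass`
#'   (tonnes, final modeled year), `msy_row` (a MSY [reference_point()]),
#'   and `econ` ([economic_params()] derived from `msy_row`).
#' @examples
#' bm <- oman_benchmarks()
#' msy(bm$R_kanagurta$bio)
#' @export
oman_benchmarks <- function() {
  lapply(oman_benchmark_data(), function(d) {
    bio <- biological_params(d$K, d$q, d$r)
    ref <- reference_point(regime = "MSY",
                           effort = d$msy_row$effort,
                           harvest = d$msy_row$harvest,
                           biomass = d$K / 2,
                           total_revenue = d$msy_row$total_revenue,
                           total_cost = d$msy_row$total_cost)
    list(species = d$species, bio = bio, ip = d$ip,
         final_biomass = d$final_biomass,
         msy_row = ref, econ = derive_price_cost(ref))
  })
}
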