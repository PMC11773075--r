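# Pipeline orchestration: configuration, fitting, tables, report output.

#' Read a run configuration
#'
#' A single JSON document. Top-level fields: `species` (array of blocks),
#' `osy_delta` (default 0.10), `delta_grid` (`{"start","stop","step"}`,
#' default 0-1 by 0.01), `seed` (default 1). Each species block has `name`
#' and exactly one of `params` (`{"K","q","r"}`) or `series_csv` (path,
#' resolved relative to the config file, with optional `fit` settings
#' `{"n_starts","ip"}`), plus `economics`: either `{"price","unit_cost"}`
#' or `{"msy_row": {"effort","harvest","total_revenue","total_cost"}}` to
#' back-derive them. A species with neither form of economics is a
#' configuration error — nothing is silently defaulted.
#'
#' @param path Path to the JSON config.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg$.dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$species) || length(cfg$species) == 0)
    stop("config error: no species blocks")
  for (sp in cfg$species) {
    nm <- sp$name %||% "<unnamed>"
    has_par <- !is.null(sp$params); has_csv <- !is.null(sp$series_csv)
    if (has_par == has_csv)
      stop("config error (", nm, "): supply exactly one of 'params' or 'series_csv'")
    ec <- sp$economics
    if (is.null(ec) || (is.null(ec$price) || is.null(ec$unit_cost)) &&
        is.null(ec$msy_row))
      stop("config error (", nm, "): 'economics' must give price+unit_cost ",
           "or an msy_row to derive them from")
  }
  cfg$osy_delta <- cfg$osy_delta %||% 0.10
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$delta_grid <- cfg$delta_grid %||% list(start = 0, stop = 1, step = 0.01)
  structure(cfg, class = "run_config")
}

resolve_economics <- function(ec) {
  if (!is.null(ec$price) && !is.null(ec$unit_cost))
    return(economic_params(ec$price, ec$unit_cost))
  row <- ec$msy_row
  derive_price_cost(reference_point("MSY", row$effort, row$harvest,
                                    biomass = NA_real_,
                                    total_revenue = row$total_revenue,
                                    total_cost = row$total_cost))
}

#' Run the full bioeconomic pipeline
#'
#' For every species block: obtain biological parameters (given directly or
#' estimated from a catch-effort CSV with [fit_dynamic_schaefer()]), resolve
#' the economics, then assemble the reference-point table (MSY/MEY/OAE/OSY),
#' the discount-rate sweep and the tax table. Deterministic given the config
#' and seed.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @param quiet Suppress progress messages.
#' @return An `analysis_report`: per-species blocks (`bio`, `econ`,
#'   `assessment` where fitted, `reference_table`, `discount_sweep`,
#'   `tax_table`) plus `provenance` (seed, package version, config hash).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  g <- config$delta_grid
  deltas <- seq(g$start, g$stop, by = g$step)
  species <- lapply(config$species, function(sp) {
    say("[", sp$name, "] resolving parameters")
    assessment <- NULL
    if (!is.null(sp$params)) {
      bio <- biological_params(sp$params$K, sp$params$q, sp$params$r)
    } else {
      csv <- sp$series_csv
      if (!file.exists(csv) && !is.null(config$.dir))
        csv <- file.path(config$.dir, sp$series_csv)
      series <- read_series_csv(csv, species = sp$name)
      fitctl <- sp$fit %||% list()
      assessment <- fit_dynamic_schaefer(
        series,
        ip = fitctl$ip %||% compute_ip(series),
        n_starts = fitctl$n_starts %||% 20L,
        seed = config$seed)
      bio <- assessment$params
      say("[", sp$name, "] fitted K=", fmt_num(bio$K), " q=", format(bio$q),
          " r=", signif(bio$r, 5), " MSY=", fmt_num(msy(bio)))
    }
    econ <- resolve_economics(sp$economics)
    say("[", sp$name, "] price ", fmt_num(econ$price), " OMR/t, cost ",
        fmt_num(econ$unit_cost), " OMR/boat-year")
    list(name = sp$name, bio = bio, econ = econ, assessment = assessment,
         reference_table = reference_table(bio, econ, species = sp$name,
                                           osy_delta = config$osy_delta),
         discount_sweep = cbind(species = sp$name,
                                discount_sweep(bio, econ, deltas)),
         tax_table = tax_table(bio, econ, osy_delta = config$osy_delta,
                               species = sp$name))
  })
  cfg_for_hash <- unclass(config)
  cfg_for_hash$.dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg_for_hash, tmp, auto_unbox = TRUE, digits = NA)
  structure(list(species = species,
                 provenance = list(seed = config$seed,
                                   osy_delta = config$osy_delta,
                                   package_version =
                                     as.character(utils::packageVersion("gordonschaefer")),
                                   config_hash = unname(tools::md5sum(tmp)))),
            class = "analysis_report")
}

#' Write an analysis report to disk
#'
#' Emits `reference_table.csv`, `discount_sweep.csv`, `tax_table.csv`,
#' `assessment.csv` (fitted species only) and `report.json` (provenance +
#' per-species parameters) under `dir`. Numeric cells keep 12 significant
#' digits so a write-read round trip is lossless at that precision.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bind <- function(field) do.call(rbind, lapply(report$species, `[[`, field))
  write_tbl <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
      format(x, digits = 12, trim = TRUE, scientific = FALSE))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  write_tbl(bind("reference_table"), "reference_table.csv")
  write_tbl(bind("discount_sweep"), "discount_sweep.csv")
  write_tbl(bind("tax_table"), "tax_table.csv")
  fitted <- Filter(function(s) !is.null(s$assessment), report$species)
  if (length(fitted))
    write_tbl(do.call(rbind, lapply(fitted, function(s)
      assessment_row(s$assessment, species = s$name))), "assessment.csv")
  payload <- list(
    provenance = report$provenance,
    species = lapply(report$species, function(s)
      list(name = s$name,
           params = list(K = s$bio$K, q = s$bio$q, r = s$bio$r),
           economics = list(price = s$econ$price, unit_cost = s$econ$unit_cost),
           fitted = !is.null(s$assessment))))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
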