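# Catch-effort time series container and strict CSV I/O.

#' Annual catch-effort series for one species
#'
#' A data frame with one row per year holding catch (tonnes), effort (boats)
#' and the derived CPUE (tonnes/boat). CPUE is `NA` where effort is zero;
#' rows with zero effort but positive catch are counted in the
#' `n_undefined_cpue` attribute rather than silently dropped.
#'
#' @param years Ordered, strictly increasing calendar years.
#' @param catches Annual catch in tonnes, non-negative.
#' @param efforts Annual effort in boats, non-negative.
#' @param species Optional species label.
#' @return A `catch_effort_series` data frame with columns `year`, `catch_t`,
#'   `effort_boats`, `cpue`.
#' @export
catch_effort_series <- function(years, catches, efforts, species = NA_character_) {
  n <- length(years)
  if (length(catches) != n || length(efforts) != n)
    stop_domain("years, catches and efforts must have equal length")
  if (n > 0 && any(diff(years) <= 0))
    stop_domain("years must be strictly increasing")
  if (any(!is.finite(catches)) || any(catches < 0))
    stop_domain("catches must be finite and >= 0")
  if (any(!is.finite(efforts)) || any(efforts < 0))
    stop_domain("efforts must be finite and >= 0")
  cpue <- ifelse(efforts > 0, catches / efforts, NA_real_)
  out <- data.frame(year = as.integer(years), catch_t = as.numeric(catches),
                    effort_boats = as.numeric(efforts), cpue = cpue)
  structure(out,
            species = species,
            n_undefined_cpue = sum(efforts == 0 & catches > 0),
            class = c("catch_effort_series", "data.frame"))
}

#' @export
print.catch_effort_series <- function(x, ...) {
  sp <- attr(x, "species")
  cat("Catch-effort series",
      if (!is.na(sp)) paste0("for ", sp), "\n")
  cat("  years:", min(x$year), "-", max(x$year), " (", nrow(x), " rows)\n", sep = "")
  cat("  catch:", fmt_num(min(x$catch_t)), "-", fmt_num(max(x$catch_t)), "t\n")
  cat("  effort:", fmt_num(min(x$effort_boats)), "-",
      fmt_num(max(x$effort_boats)), "boats\n")
  if (isTRUE(attr(x, "collapsed"))) cat("  note: simulated stock hit the collapse floor\n")
  invisible(x)
}

series_csv_columns <- c("year", "catch_t", "effort_boats")

#' Read a catch-effort series from CSV
#'
#' Strict reader for the schema `year,catch_t,effort_boats` (UTF-8, '.'
#' decimal separator). Missing columns, non-numeric cells and duplicate years
#' are rejected with the offending line or year named.
#'
#' @param path Path to the CSV file.
#' @param species Optional species label attached to the series.
#' @return A [catch_effort_series()].
#' @export
read_series_csv <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(series_csv_columns, names(raw))
  if (length(missing))
    stop("malformed series CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  parse_col <- function(col) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad))
      stop("malformed series CSV ", path, ": non-numeric '", col,
           "' at data line(s) ", paste(bad, collapse = ", "))
    vals
  }
  years <- parse_col("year")
  dup <- years[duplicated(years)]
  if (length(dup))
    stop("malformed series CSV ", path, ": duplicate year(s) ",
         paste(unique(dup), collapse = ", "))
  ord <- order(years)
  catch_effort_series(years[ord], parse_col("catch_t")[ord],
                      parse_col("effort_boats")[ord], species = species)
}

#' Write a catch-effort series to CSV
#'
#' Inverse of [read_series_csv()]; numbers keep 12 significant digits so a
#' write-read round trip is lossless at that precision.
#'
#' @param series A [catch_effort_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "catch_effort_series"))
  out <- data.frame(year = series$year,
                    catch_t = format(series$catch_t, digits = 12, trim = TRUE,
                                     scientific = FALSE),
                    effort_boats = format(series$effort_boats, digits = 12,
                                          trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
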