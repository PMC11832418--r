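#' Bundled reference tables
#'
#' `species_thermal_reference()` returns the thermal and elevation
#' distribution parameters of the 15 dominant Andean study species
#' (thermal optimum, thermal spread, percentile extremes, altitude range,
#' wood density, botanical family, montane/lowland group).
#' `site_climate_reference()` returns the weather summary of the three
#' experimental sites (MAT and its 10th/90th percentiles, day/night
#' means, elevation, precipitation).
#'
#' @return data frame.
#' @export
species_thermal_reference <- function() {
  utils::read.csv(system.file("extdata", "andean_species_thermal.csv",
                              package = "thermotrans"),
                  stringsAsFactors = FALSE)
}

#' @rdname species_thermal_reference
#' @export
site_climate_reference <- function() {
  utils::read.csv(system.file("extdata", "andean_site_climate.csv",
                              package = "thermotrans"),
                  stringsAsFactors = FALSE)
}

# Header-driven CSV reader with schema validation. Column order in the
# file is irrelevant; missing required columns abort with their names;
# row-level violations are collected (with line numbers) and the rows
# dropped with a warning, aborting if more than max_bad_fraction of rows
# are bad.
read_validated <- function(path, required, row_check, max_bad_fraction = 0.25,
                           what = "table") {
  if (!file.exists(path)) stop("read_", what, ": file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("read_", what, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- row_check(d)
  if (any(bad)) {
    if (mean(bad) > max_bad_fraction) {
      stop(sprintf("read_%s: %d of %d rows invalid (> %.0f%%), aborting",
                   what, sum(bad), nrow(d), 100 * max_bad_fraction))
    }
    warning(sprintf("read_%s: dropped %d invalid row(s) at line(s) %s", what,
                    sum(bad), paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")))
    d <- d[!bad, , drop = FALSE]
  }
  d
}

#' Read and validate the input tables
#'
#' Schema-checked CSV readers for the three pipeline inputs. Headers are
#' required and drive the parse (column order is irrelevant); rows
#' violating basic invariants (coordinates out of range, inverted
#' temperature ordering, non-positive diameter on a living tree,
#' non-positive temperatures missing, unparseable dates) are dropped with
#' a warning carrying their line numbers, and the read aborts if more
#' than `max_bad_fraction` of rows are bad.
#'
#' @param path CSV file path.
#' @param max_bad_fraction abort threshold for the fraction of bad rows.
#' @return validated data frame.
#' @export
read_occurrences <- function(path, max_bad_fraction = 0.25) {
  d <- read_validated(
    path,
    required = c("species", "latitude", "longitude", "elevation_reported",
                 "elevation_dem", "grid_cell_id", "mat", "tmin", "tmax"),
    row_check = function(d) {
      !is.finite(d$mat) | !is.finite(d$tmin) | !is.finite(d$tmax) |
        d$latitude < -90 | d$latitude > 90 |
        d$longitude < -180 | d$longitude > 180 |
        d$tmin > d$mat + 1e-9 | d$mat > d$tmax + 1e-9
    },
    max_bad_fraction = max_bad_fraction, what = "occurrences")
  d
}

#' @rdname read_occurrences
#' @export
read_weather <- function(path, max_bad_fraction = 0.25) {
  read_validated(
    path,
    required = c("site", "timestamp", "temperature_c"),
    row_check = function(d) !is.finite(d$temperature_c),
    max_bad_fraction = max_bad_fraction, what = "weather")
}

#' @rdname read_occurrences
#' @export
read_census <- function(path, max_bad_fraction = 0.25) {
  d <- read_validated(
    path,
    required = c("tree_id", "species", "site", "campaign_index", "date",
                 "diameter", "alive", "planting_date"),
    row_check = function(d) {
      alive <- as.logical(d$alive)
      is.na(as.Date(d$date, optional = TRUE)) |
        (alive & (!is.finite(d$diameter) | d$diameter <= 0))
    },
    max_bad_fraction = max_bad_fraction, what = "census")
  d$date <- as.Date(d$date)
  d$planting_date <- as.Date(d$planting_date)
  d$alive <- as.logical(d$alive)
  d
}
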