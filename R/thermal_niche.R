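#' Deduplicate occurrence records by grid cell
#'
#' Collapses spatially clustered observations: at most one record per
#' species per 30 arc-second grid cell is retained, keeping the first
#' record in input order.
#'
#' @param records data frame of occurrence records with at least columns
#'   `species` and `grid_cell_id`.
#' @return the surviving records, input order preserved. The number of
#'   removed rows is attached as attribute `n_removed`.
#' @export
dedup_by_grid_cell <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  if (anyNA(records$grid_cell_id)) stop("dedup_by_grid_cell: grid_cell_id must be populated")
  dup <- duplicated(paste(records$species, records$grid_cell_id, sep = "\r"))
  out <- records[!dup, , drop = FALSE]
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Elevation quality control
#'
#' Drops records whose reported elevation disagrees with the digital
#' elevation model by more than `max_diff` metres (strictly greater than:
#' a difference of exactly `max_diff` is kept). Records without a DEM
#' elevation cannot be checked; by default they are retained and counted
#' as flagged.
#'
#' @param records data frame with columns `elevation_reported` and
#'   `elevation_dem` (the latter may contain `NA`).
#' @param max_diff maximum tolerated absolute elevation difference (m).
#' @param drop_missing_dem drop records with no DEM elevation instead of
#'   keeping them flagged.
#' @return list with elements `kept` and `dropped` (data frames that
#'   partition the input) plus `n_flagged_missing_dem`.
#' @export
elevation_qc <- function(records, max_diff = 200, drop_missing_dem = FALSE) {
  stopifnot(is.data.frame(records), max_diff > 0)
  if (nrow(records) == 0L) {
    return(list(kept = records, dropped = records, n_flagged_missing_dem = 0L))
  }
  diff <- abs(records$elevation_reported - records$elevation_dem)
  missing <- is.na(records$elevation_dem)
  keep <- (!missing & diff <= max_diff) | (missing & !drop_missing_dem)
  list(
    kept = records[keep, , drop = FALSE],
    dropped = records[!keep, , drop = FALSE],
    n_flagged_missing_dem = sum(missing & !drop_missing_dem)
  )
}

#' Estimate a species thermal distribution
#'
#' Summarises the cleaned occurrence records of one species into its
#' thermal distribution. The mean-annual-temperature (MAT), coldest-month
#' (tmin) and warmest-month (tmax) samples are each trimmed independently
#' with [trim_tails()] before any statistic is computed. The thermal
#' optimum `t_opt` is the mean of trimmed MAT and `t_sd` its sample
#' standard deviation (the denominator of the thermal displacement index);
#' the cold extreme is the 10th-25th percentile band of tmin and the hot
#' extreme the 75th-90th percentile band of tmax.
#'
#' @param records data frame of occurrence records of a single species
#'   (already deduplicated and elevation-checked) with numeric columns
#'   `mat`, `tmin`, `tmax`.
#' @param min_records minimum acceptable number of records; species with
#'   fewer are rejected rather than summarised.
#' @param lower_q,upper_q trimming fractions passed to [trim_tails()].
#' @return an object of class `thermal_distribution`: a list with fields
#'   `species`, `n_records` (after trimming), `t_opt`, `t_sd`,
#'   `mean_tmin`, `mean_tmax`, `thermal_range`, `cold_extreme` (p10, p25),
#'   `hot_extreme` (p75, p90).
#' @export
estimate_thermal_distribution <- function(records, min_records = 20L,
                                          lower_q = 0.05, upper_q = 0.95) {
  stopifnot(is.data.frame(records))
  species <- unique(as.character(records$species))
  if (length(species) > 1L) {
    stop("estimate_thermal_distribution: records span more than one species: ",
         paste(species, collapse = ", "))
  }
  if (length(species) == 0L || nrow(records) < min_records) {
    stop(sprintf(
      "estimate_thermal_distribution: species '%s' has %d records, fewer than min_records = %d",
      if (length(species)) species else "<none>", nrow(records), min_records))
  }
  mat  <- trim_tails(records$mat,  lower_q, upper_q)
  tmin <- trim_tails(records$tmin, lower_q, upper_q)
  tmax <- trim_tails(records$tmax, lower_q, upper_q)
  t_sd <- stats::sd(mat)
  if (!is.finite(t_sd) || t_sd == 0) {
    stop(sprintf(
      "estimate_thermal_distribution: species '%s' has zero thermal spread (t_sd = 0); TDI undefined",
      species))
  }
  out <- list(
    species = species,
    n_records = length(mat),
    t_opt = mean(mat),
    t_sd = t_sd,
    mean_tmin = mean(tmin),
    mean_tmax = mean(tmax),
    thermal_range = mean(tmax) - mean(tmin),
    cold_extreme = c(p10 = percentile(tmin, 0.10), p25 = percentile(tmin, 0.25)),
    hot_extreme  = c(p75 = percentile(tmax, 0.75), p90 = percentile(tmax, 0.90))
  )
  class(out) <- "thermal_distribution"
  out
}

#' @export
print.thermal_distribution <- function(x, ...) {
  cat(sprintf("Thermal distribution: %s (n = %d records after trimming)\n",
              x$species, x$n_records))
  cat(sprintf("  T_opt %.2f degC (T_SD %.2f)\n", x$t_opt, x$t_sd))
  cat(sprintf("  mean T_min %.2f, mean T_max %.2f, thermal range %.2f degC\n",
              x$mean_tmin, x$mean_tmax, x$thermal_range))
  cat(sprintf("  cold extreme (T_min p10-p25): %.2f-%.2f degC\n",
              x$cold_extreme[["p10"]], x$cold_extreme[["p25"]]))
  cat(sprintf("  hot extreme  (T_max p75-p90): %.2f-%.2f degC\n",
              x$hot_extreme[["p75"]], x$hot_extreme[["p90"]]))
  invisible(x)
}

#' Thermal-distribution table for many species
#'
#' Runs the full occurrence-cleaning chain (grid-cell deduplication,
#' elevation QC, tail trimming) and estimates one thermal distribution per
#' species. Species failing `min_records` or with zero thermal spread are
#' reported in the QC summary instead of aborting the whole table.
#'
#' @param records occurrence data frame (all species together).
#' @inheritParams estimate_thermal_distribution
#' @inheritParams elevation_qc
#' @return data frame with one row per estimated species and the
#'   `thermal_distribution` fields as columns; QC counts (records removed
#'   per filter, species rejected and why) attached as attribute `qc`.
#' @export
thermal_niche_table <- function(records, min_records = 20L, max_diff = 200,
                                lower_q = 0.05, upper_q = 0.95,
                                drop_missing_dem = FALSE) {
  deduped <- dedup_by_grid_cell(records)
  qcd <- elevation_qc(deduped, max_diff = max_diff, drop_missing_dem = drop_missing_dem)
  kept <- qcd$kept
  failed <- list()
  rows <- list()
  for (sp in unique(as.character(kept$species))) {
    td <- tryCatch(
      estimate_thermal_distribution(kept[kept$species == sp, , drop = FALSE],
                                    min_records = min_records,
                                    lower_q = lower_q, upper_q = upper_q),
      error = function(e) e)
    if (inherits(td, "error")) {
      failed[[sp]] <- conditionMessage(td)
    } else {
      rows[[sp]] <- data.frame(
        species = td$species, n_records = td$n_records,
        t_opt = td$t_opt, t_sd = td$t_sd,
        mean_tmin = td$mean_tmin, mean_tmax = td$mean_tmax,
        thermal_range = td$thermal_range,
        cold_p10 = td$cold_extreme[["p10"]], cold_p25 = td$cold_extreme[["p25"]],
        hot_p75 = td$hot_extreme[["p75"]], hot_p90 = td$hot_extreme[["p90"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(species = character(), n_records = integer(),
                      t_opt = numeric(), t_sd = numeric(),
                      mean_tmin = numeric(), mean_tmax = numeric(),
                      thermal_range = numeric(),
                      cold_p10 = numeric(), cold_p25 = numeric(),
                      hot_p75 = numeric(), hot_p90 = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "qc") <- list(
    n_input = nrow(records),
    n_removed_duplicate_cell = attr(deduped, "n_removed"),
    n_removed_elevation = nrow(qcd$dropped),
    n_flagged_missing_dem = qcd$n_flagged_missing_dem,
    species_rejected = failed
  )
  out
}
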