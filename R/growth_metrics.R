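#' Relative growth rate from two diameter measurements
#'
#' RGR is the log-diameter increment per year,
#' `RGR = (log(d_i) - log(d_0)) / (t_i - t_0)`, with natural logarithms,
#' diameters in mm and the interval expressed in years of 365.25 days.
#' Units are mm mm^-1 year^-1. Vectorised over all arguments.
#'
#' @param d0,di diameters (mm) at the first and later census, both > 0.
#' @param t0,ti census dates (`Date` or coercible), `ti > t0`.
#' @return numeric RGR.
#' @examples
#' compute_rgr(10, 20, as.Date("2019-01-01"), as.Date("2022-01-01"))
#' @export
compute_rgr <- function(d0, di, t0, ti) {
  if (any(d0 <= 0) || any(di <= 0)) stop("compute_rgr: diameters must be positive")
  years <- as.numeric(as.Date(ti) - as.Date(t0)) / 365.25
  if (any(years <= 0)) stop("compute_rgr: census interval must be positive")
  (log(di) - log(d0)) / years
}

#' Headline growth records from a census table
#'
#' One growth record per surviving tree: RGR over the full monitoring
#' window, from the first census (campaign 0) to the tree's final census.
#' Trees that died contribute no growth record; trees whose diameter
#' shrank get a negative RGR and are flagged rather than dropped.
#'
#' @param census long-format census data frame (one row per tree x
#'   campaign) with columns `tree_id`, `species`, `site`, `campaign_index`,
#'   `date`, `diameter`, `alive`.
#' @return data frame with columns `tree_id`, `species`, `site`, `t0`,
#'   `ti`, `years`, `d0`, `di`, `rgr`, `shrank`.
#' @export
growth_records <- function(census) {
  need <- c("tree_id", "species", "site", "campaign_index", "date", "diameter", "alive")
  miss <- setdiff(need, names(census))
  if (length(miss)) stop("growth_records: missing columns: ", paste(miss, collapse = ", "))
  census <- census[order(census$tree_id, census$campaign_index), , drop = FALSE]
  rows <- lapply(split(census, census$tree_id), function(tr) {
    if (!all(tr$alive)) return(NULL) # dead trees carry no growth record
    first <- tr[1L, ]
    last <- tr[nrow(tr), ]
    if (nrow(tr) < 2L) return(NULL)
    data.frame(tree_id = first$tree_id, species = first$species, site = first$site,
               t0 = as.Date(first$date), ti = as.Date(last$date),
               years = as.numeric(as.Date(last$date) - as.Date(first$date)) / 365.25,
               d0 = first$diameter, di = last$diameter,
               rgr = compute_rgr(first$diameter, last$diameter, first$date, last$date),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) stop("growth_records: no surviving tree has two censuses")
  out$shrank <- out$rgr < 0
  if (any(out$shrank)) {
    warning(sprintf("growth_records: %d trees shrank (negative RGR), flagged", sum(out$shrank)))
  }
  out
}

#' Scaled growth rate within species
#'
#' Scales each tree's RGR by the maximum RGR observed for its species
#' across all sites and treatments, `SGR = RGR_ij / max(RGR_j)`, making
#' growth comparable across species. SGR is unitless, at most 1, and
#' exactly 1 for at least one tree per species.
#'
#' @param growth growth-record data frame with columns `species` and `rgr`
#'   (as from [growth_records()]).
#' @param by optional extra grouping column(s) restricting the maximum
#'   (e.g. `"fertilised"`); default none, the maximum is taken over the
#'   whole species.
#' @return the input with an `sgr` column appended.
#' @export
compute_sgr <- function(growth, by = NULL) {
  stopifnot(is.data.frame(growth), all(c("species", "rgr") %in% names(growth)))
  key <- do.call(paste, c(growth[c("species", by)], sep = "\r"))
  mx <- tapply(growth$rgr, key, max)
  bad <- names(mx)[mx <= 0]
  if (length(bad)) {
    stop("compute_sgr: species with non-positive maximum RGR: ",
         paste(sub("\r.*$", "", bad), collapse = ", "))
  }
  growth$sgr <- growth$rgr / as.numeric(mx[key])
  growth
}

#' Site temperature metrics from a weather series
#'
#' Mean annual temperature and its 10th/90th percentiles from a
#' full-resolution site air-temperature series, using the shared
#' [percentile()] convention.
#'
#' @param temperature_c numeric vector of air temperatures (degC), or a
#'   data frame with a `temperature_c` column.
#' @param site optional site label carried through to the output.
#' @return data frame row with `site`, `mat`, `mat_p10`, `mat_p90`,
#'   `n_observations`.
#' @export
site_mat_metrics <- function(temperature_c, site = NA_character_) {
  if (is.data.frame(temperature_c)) {
    if (is.na(site) && "site" %in% names(temperature_c) &&
        length(unique(temperature_c$site)) == 1L) {
      site <- as.character(temperature_c$site[1L])
    }
    temperature_c <- temperature_c$temperature_c
  }
  if (length(temperature_c) == 0L) stop("site_mat_metrics: empty temperature series")
  p <- percentile(temperature_c, c(0.10, 0.90))
  data.frame(site = site, mat = mean(temperature_c),
             mat_p10 = p[1], mat_p90 = p[2],
             n_observations = length(temperature_c),
             stringsAsFactors = FALSE)
}

#' Thermal displacement index
#'
#' Signed distance, in units of the species' thermal spread, between a
#' site temperature metric and the species thermal optimum:
#' `TDI = (MAT_metric - T_opt) / T_SD`. Negative TDI means the species
#' optimum is warmer than the site; positive TDI means the site is warmer
#' than the optimum. Vectorised.
#'
#' @param metric_value site temperature metric (degC): the site MAT or its
#'   10th/90th percentile.
#' @param t_opt species thermal optimum (degC).
#' @param t_sd species thermal spread (degC), must be > 0.
#' @return unitless TDI.
#' @export
compute_tdi <- function(metric_value, t_opt, t_sd) {
  if (any(t_sd <= 0)) stop("compute_tdi: t_sd must be positive")
  (metric_value - t_opt) / t_sd
}

#' TDI table for species x site x metric combinations
#'
#' @param niche data frame with columns `species`, `t_opt`, `t_sd` (as
#'   from [thermal_niche_table()] or the bundled reference table).
#' @param site_metrics data frame with columns `site`, `mat`, `mat_p10`,
#'   `mat_p90` (as from [site_mat_metrics()]).
#' @param metrics which site metrics to use.
#' @return long data frame `species`, `site`, `metric`, `metric_value`,
#'   `tdi`.
#' @export
tdi_table <- function(niche, site_metrics,
                      metrics = c("mat", "mat_p10", "mat_p90")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  grid <- expand.grid(species = niche$species, site = site_metrics$site,
                      metric = metrics, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  isp <- match(grid$species, niche$species)
  ist <- match(grid$site, site_metrics$site)
  grid$metric_value <- mapply(function(row, m) site_metrics[[m]][row], ist, grid$metric)
  grid$tdi <- compute_tdi(grid$metric_value, niche$t_opt[isp], niche$t_sd[isp])
  grid
}
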