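# Independent oracles used across the suite. Each is a deliberately
# simple, brute-force computation kept separate from the package's own
# code paths.

# sort + linear interpolation at position q * (n - 1)
percentile_oracle <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  pos <- q * (n - 1)
  lo <- floor(pos)
  frac <- pos - lo
  v <- s[lo + 1]
  upper <- s[pmin(lo + 2, n)]
  v + frac * (upper - v)
}

# textbook Welch t statistic, Welch-Satterthwaite df and two-sided p
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# two-group Breslow log partial likelihood, closed form, vectorised over
# a grid of coefficients (x is 0/1 group membership)
breslow2_oracle <- function(beta, time, event, x) {
  ll <- numeric(length(beta))
  for (t in unique(time[event == 1])) {
    d <- event == 1 & time == t
    r <- time >= t
    ll <- ll + sum(x[d]) * beta -
      sum(d) * log(sum(r & x == 0) + sum(r & x == 1) * exp(beta))
  }
  ll
}

# minimal in-memory census for one tree
toy_tree <- function(tree_id, species, site, diameters, alive,
                     planting = as.Date("2018-11-15"),
                     dates = as.Date("2019-02-01") + 122 * seq_along(diameters) - 122) {
  data.frame(tree_id = tree_id, species = species, site = site,
             plot = 1L, block = 1L, fertilised = FALSE,
             planting_date = planting,
             campaign_index = seq_along(diameters) - 1L,
             date = dates, diameter = diameters, alive = alive,
             stringsAsFactors = FALSE)
}

# occurrence rows with explicit fields
toy_occurrences <- function(n, species = "sp", mat = 15, tmin = mat - 5,
                            tmax = mat + 5, cell = paste0("g", seq_len(n)),
                            elev_rep = 1000, elev_dem = 1000) {
  data.frame(species = species, latitude = 0, longitude = -70,
             elevation_reported = rep_len(elev_rep, n),
             elevation_dem = rep_len(elev_dem, n),
             grid_cell_id = rep_len(cell, n),
             mat = rep_len(mat, n), tmin = rep_len(tmin, n),
             tmax = rep_len(tmax, n), stringsAsFactors = FALSE)
}
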