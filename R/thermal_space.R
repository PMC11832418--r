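#' Two-group k-means partition of thermal space
#'
#' Splits a (temperature, elevation) point cloud into a cold/high and a
#' warm/low group with k = 2 k-means (Lloyd's algorithm). Because degC and
#' metres differ by orders of magnitude, both axes are z-score
#' standardised before clustering; centers are reported in original
#' units. `n_init` seeded initialisations are run and the partition with
#' the lowest within-cluster sum of squares wins (ties broken by the
#' lowest restart index), so the result is deterministic given `seed`.
#' Clusters are labelled so that cluster 1 is the colder center.
#'
#' @param points data frame or 2-column matrix: temperature (degC) and
#'   elevation (masl).
#' @param seed integer seed controlling all restarts.
#' @param n_init number of random initialisations.
#' @return object of class `thermal_partition`: list with
#'   `cluster_centers` (2 x 2 matrix, original units, cold cluster first),
#'   `breakpoint_temperature`, `breakpoint_elevation`, `assignments`,
#'   `tot_withinss`, `seed`.
#' @export
kmeans_two <- function(points, seed = 1L, n_init = 10L) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("kmeans_two: points must have two columns (temperature, elevation)")
  colnames(pts) <- c("temperature", "elevation")
  if (nrow(unique(pts)) < 2L) stop("kmeans_two: need at least two distinct points")
  ctr <- colMeans(pts)
  scl <- apply(pts, 2, stats::sd)
  scl[scl == 0] <- 1 # a degenerate axis carries no clustering information
  z <- sweep(sweep(pts, 2, ctr), 2, scl, "/")
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(seed + i - 1L)
    km <- tryCatch(stats::kmeans(z, centers = 2L, iter.max = 100L, algorithm = "Lloyd"),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
  }
  if (is.null(best)) stop("kmeans_two: clustering failed on all initialisations")
  centers <- sweep(sweep(best$centers, 2, scl, "*"), 2, ctr, "+")
  ord <- order(centers[, "temperature"])
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- c("cold", "warm")
  assignments <- match(best$cluster, ord)
  bp <- colMeans(centers)
  out <- list(
    cluster_centers = centers,
    breakpoint_temperature = bp[["temperature"]],
    breakpoint_elevation = bp[["elevation"]],
    assignments = assignments,
    tot_withinss = best$tot.withinss,
    seed = seed
  )
  class(out) <- "thermal_partition"
  out
}

#' Breakpoint between the two thermal-space clusters
#'
#' The breakpoint separating the cold/high from the warm/low group is the
#' arithmetic midpoint of the two cluster centers on each axis. For the
#' published Andean cluster means (13.7 degC, 2545 masl) and (22.02 degC,
#' 1108 masl) this gives (17.86 degC, 1826.5 masl), i.e. the familiar
#' 18 degC / 1825 masl montane-lowland divide to rounding.
#'
#' @param partition a `thermal_partition`, or a 2 x 2 matrix/data frame of
#'   cluster centers (temperature, elevation).
#' @return named numeric vector `c(temperature = , elevation = )`.
#' @export
find_breakpoint <- function(partition) {
  centers <- if (inherits(partition, "thermal_partition")) {
    partition$cluster_centers
  } else {
    as.matrix(partition)
  }
  if (nrow(centers) != 2L || ncol(centers) != 2L) {
    stop("find_breakpoint: need exactly two (temperature, elevation) centers")
  }
  bp <- colMeans(centers)
  names(bp) <- c("temperature", "elevation")
  bp
}

#' Classify species as montane or lowland
#'
#' A species is montane iff its thermal optimum lies strictly below the
#' breakpoint temperature (default 18 degC, the Andean thermal-space
#' divide); otherwise lowland.
#'
#' @param t_opt numeric vector of species thermal optima (degC).
#' @param breakpoint_temperature split temperature (degC).
#' @return character vector, `"montane"` or `"lowland"`.
#' @export
classify_species <- function(t_opt, breakpoint_temperature = 18) {
  if (any(!is.finite(t_opt)) || !is.finite(breakpoint_temperature)) {
    stop("classify_species: inputs must be finite")
  }
  ifelse(t_opt < breakpoint_temperature, "montane", "lowland")
}

#' @export
print.thermal_partition <- function(x, ...) {
  cat("Two-group k-means partition of thermal space\n")
  cat(sprintf("  cold cluster center: %6.2f degC, %7.1f masl\n",
              x$cluster_centers["cold", 1], x$cluster_centers["cold", 2]))
  cat(sprintf("  warm cluster center: %6.2f degC, %7.1f masl\n",
              x$cluster_centers["warm", 1], x$cluster_centers["warm", 2]))
  cat(sprintf("  breakpoint: %.2f degC / %.1f masl  (n = %d points, seed %d)\n",
              x$breakpoint_temperature, x$breakpoint_elevation,
              length(x$assignments), x$seed))
  invisible(x)
}

#' @export
plot.thermal_partition <- function(x, points = NULL, ...) {
  if (!is.null(points)) {
    pts <- as.matrix(points)
    graphics::plot(pts[, 1], pts[, 2], col = x$assignments + 1L, pch = 16, cex = 0.4,
                   xlab = "temperature (degC)", ylab = "elevation (masl)", ...)
  } else {
    graphics::plot(x$cluster_centers, xlab = "temperature (degC)",
                   ylab = "elevation (masl)", pch = 8, cex = 2, ...)
  }
  graphics::points(x$cluster_centers, pch = 8, cex = 2)
  graphics::abline(v = x$breakpoint_temperature, lty = 2)
  graphics::abline(h = x$breakpoint_elevation, lty = 2)
  invisible(x)
}
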