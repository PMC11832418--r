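#' Welch two-sample t test
#'
#' Two-sided unequal-variance t test with Welch-Satterthwaite degrees of
#' freedom, used e.g. to compare montane and lowland growth rates at a
#' common site.
#'
#' @param a,b numeric samples, each with n >= 2 and nonzero variance.
#' @return list of class `group_comparison`: `statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_summaries`.
#' @export
welch_t_test <- function(a, b) {
  check_sample <- function(x, nm) {
    if (length(x) < 2L || !is.finite(stats::var(x)) || stats::var(x) == 0) {
      stop("welch_t_test: sample '", nm, "' is degenerate (n < 2 or zero variance)")
    }
  }
  check_sample(a, "a"); check_sample(b, "b")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  out <- list(statistic = unname(ht$statistic),
              degrees_of_freedom = unname(ht$parameter),
              p_value = ht$p.value,
              group_summaries = data.frame(
                group = c("a", "b"), n = c(length(a), length(b)),
                mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b))))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (!is.null(x$statistic_name)) x$statistic_name else "t"
  cat(sprintf("%s = %.4f, df = %s, p = %.4g\n", lab, x$statistic,
              paste(signif(x$degrees_of_freedom, 4), collapse = ", "), x$p_value))
  print(round_df(x$group_summaries, 4), row.names = FALSE)
  invisible(x)
}

#' Welch heteroscedastic one-way ANOVA
#'
#' Welch's F test across k groups with unequal variances and sample
#' sizes. With two groups the statistic equals the square of the Welch t.
#'
#' @param groups list of numeric samples, each n >= 2 with nonzero
#'   variance.
#' @return `group_comparison` with `statistic` (F) and numerator /
#'   denominator `degrees_of_freedom`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  for (i in seq_along(groups)) {
    if (length(groups[[i]]) < 2L || stats::var(groups[[i]]) == 0) {
      stop("welch_anova: group ", i, " is degenerate (n < 2 or zero variance)")
    }
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
  out <- list(statistic = unname(ht$statistic),
              statistic_name = "F",
              degrees_of_freedom = unname(ht$parameter),
              p_value = ht$p.value,
              group_summaries = data.frame(
                group = seq_along(groups), n = lengths(groups),
                mean = vapply(groups, mean, numeric(1)),
                sd = vapply(groups, stats::sd, numeric(1))))
  class(out) <- "group_comparison"
  out
}

#' Two-way ANOVA of growth rates (type-II sums of squares)
#'
#' Growth-rate variation across species and sites (optionally the
#' fertilisation arm) on the survivor data, which is unbalanced because
#' mortality differs across cells; type-II sums of squares are therefore
#' used (via [car::Anova()]). Terms made inestimable by empty cells (an
#' interaction with an all-dead species x site cell) are dropped with a
#' warning.
#'
#' @param rgr numeric response (relative growth rates).
#' @param species,site factors.
#' @param fertilised optional factor for the nutrient-addition arm.
#' @param interaction include the species:site interaction when all cells
#'   are filled.
#' @return the [car::Anova()] table (class `anova`).
#' @export
two_way_anova <- function(rgr, species, site, fertilised = NULL, interaction = TRUE) {
  species <- droplevels(factor(species))
  site <- droplevels(factor(site))
  if (nlevels(species) < 2L || nlevels(site) < 2L) {
    stop("two_way_anova: need at least two levels of species and site")
  }
  dat <- data.frame(rgr = rgr, species = species, site = site)
  rhs <- "species + site"
  if (interaction) {
    if (any(table(species, site) == 0L)) {
      warning("two_way_anova: empty species x site cells; interaction term dropped")
    } else {
      rhs <- paste(rhs, "+ species:site")
    }
  }
  if (!is.null(fertilised)) {
    dat$fertilised <- droplevels(factor(fertilised))
    if (nlevels(dat$fertilised) >= 2L) rhs <- paste(rhs, "+ fertilised")
    else warning("two_way_anova: fertilised has a single level, dropped")
  }
  fit <- stats::lm(stats::as.formula(paste("rgr ~", rhs)), data = dat)
  car::Anova(fit, type = 2)
}

#' Tukey honest significant differences
#'
#' All pairwise group comparisons with studentized-range adjusted
#' p-values (classical Tukey HSD on the pooled one-way fit). Groups with
#' fewer than two observations are excluded with a warning. Significance
#' stars follow the usual thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param groups named list of numeric samples (names default to G1..Gk).
#' @param alpha familywise level used for the confidence bounds.
#' @return data frame of pairwise comparisons: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`, `stars`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  small <- lengths(groups) < 2L
  if (any(small)) {
    warning("tukey_hsd: groups excluded with n < 2: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2L) stop("tukey_hsd: fewer than two usable groups")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#' @param p numeric vector of p-values.
#' @return character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
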