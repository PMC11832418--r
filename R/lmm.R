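#' Mixed model of scaled growth against thermal displacement
#'
#' Fits the species-level growth model
#' `SGR ~ TDI x group + (1 | family)` by REML: per-group intercepts and
#' TDI slopes as fixed effects (montane vs lowland), and a botanical-
#' family random intercept absorbing taxonomic bias (all lowland species
#' in one genus, several montane species sharing a family). The single
#' variance ratio `lambda = var_family / var_residual` is profiled out of
#' the REML criterion and maximised by bounded 1-D optimisation on
#' `log(lambda)`; given `lambda`, the GLS fixed effects and both variance
#' components are closed-form. Per-group ordinary least squares fits
#' (slope, intercept, Pearson r) are also returned, as drawn on
#' scatterplots of SGR against TDI.
#'
#' With fewer than two families the random term is dropped with a warning
#' and the model reduces to OLS.
#'
#' @param data data frame with one row per species per site: numeric
#'   `sgr` and `tdi`, and factors `group` (montane/lowland) and `family`
#'   (botanical family). Column names can be remapped via the arguments.
#' @param sgr,tdi,group,family column names.
#' @param lambda optional fixed variance ratio
#'   `var_family / var_residual`; when supplied the REML profile is
#'   evaluated there instead of being optimised (useful for profile
#'   diagnostics).
#' @return object of class `sgr_tdi_lmm` with elements `fixed_effects`
#'   (estimate, se per coefficient), `slopes` (per-group slope, se and
#'   Wald z/p), `slope_difference` (estimate, se, z, p of the interaction
#'   contrast), `variance_components` (`family`, `residual`),
#'   `r2_marginal`, `r2_conditional`, `reml_loglik`, `n_observations`,
#'   `n_families`, `ols` (per-group OLS summaries), `lambda`, plus the
#'   internals needed by methods.
#' @export
lmm_fit <- function(data, sgr = "sgr", tdi = "tdi", group = "group",
                    family = "family", lambda = NULL) {
  y <- data[[sgr]]
  td <- data[[tdi]]
  g <- droplevels(factor(data[[group]]))
  fam <- droplevels(factor(data[[family]]))
  stopifnot(length(y) == length(td), length(y) == length(g))
  if (nlevels(g) < 1L) stop("lmm_fit: no groups")
  n <- length(y)
  X <- stats::model.matrix(~ 0 + g + g:td)
  colnames(X) <- c(paste0("intercept_", levels(g)),
                   paste0("slope_", levels(g)))
  p <- ncol(X)
  q <- nlevels(fam)
  drop_random <- q < 2L
  if (drop_random) {
    warning("lmm_fit: fewer than two families; random intercept dropped, fitting OLS")
  }

  K <- if (drop_random) matrix(0, n, n) else {
    tcrossprod(stats::model.matrix(~ 0 + fam)) # relatedness through shared family
  }

  # -2 * REML log-likelihood profiled on lambda = var_family / var_residual
  reml_pieces <- function(lambda) {
    V <- diag(n) + lambda * K
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(Vi_X, y))
    r <- y - X %*% beta
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    rss <- drop(crossprod(r, Vi_r))
    logdetV <- 2 * sum(log(diag(cV)))
    logdetXtViX <- determinant(XtViX, logarithm = TRUE)$modulus
    sigma2 <- rss / (n - p)
    m2ll <- (n - p) * (log(2 * pi * sigma2) + 1) + logdetV + as.numeric(logdetXtViX)
    list(m2ll = m2ll, beta = drop(beta), sigma2 = sigma2,
         cov_beta = sigma2 * solve(XtViX))
  }
  if (drop_random) {
    lambda <- 0
  } else if (is.null(lambda)) {
    obj <- function(loglam) reml_pieces(exp(loglam))$m2ll
    opt <- stats::optimize(obj, interval = c(-15, 15), tol = 1e-8)
    lambda <- exp(opt$minimum)
    if (reml_pieces(0)$m2ll <= opt$objective) lambda <- 0 # boundary: no family variance
  }
  fit <- reml_pieces(lambda)
  beta <- fit$beta
  se <- sqrt(diag(fit$cov_beta))
  names(se) <- names(beta) <- colnames(X)
  var_resid <- fit$sigma2
  var_family <- lambda * fit$sigma2

  slope_idx <- grep("^slope_", colnames(X))
  slopes <- data.frame(group = levels(g), slope = beta[slope_idx],
                       se = se[slope_idx], row.names = NULL)
  slopes$z <- slopes$slope / slopes$se
  slopes$p <- 2 * stats::pnorm(-abs(slopes$z))

  slope_difference <- NULL
  if (nlevels(g) == 2L) {
    ctr <- numeric(p)
    ctr[slope_idx] <- c(1, -1)
    est <- sum(ctr * beta)
    sdiff <- sqrt(drop(t(ctr) %*% fit$cov_beta %*% ctr))
    z <- est / sdiff
    slope_difference <- c(estimate = est, se = sdiff, z = z,
                          p = 2 * stats::pnorm(-abs(z)))
  }

  fitted_fixed <- drop(X %*% beta)
  var_fixed <- stats::var(fitted_fixed)
  denom <- var_fixed + var_family + var_resid
  r2 <- if (denom > 0) {
    c(marginal = var_fixed / denom, conditional = (var_fixed + var_family) / denom)
  } else {
    stop("lmm_fit: all variance components are zero")
  }

  ols <- do.call(rbind, lapply(levels(g), function(lev) {
    k <- g == lev
    lmf <- stats::lm(y[k] ~ td[k])
    ct <- suppressWarnings(stats::cor.test(td[k], y[k]))
    data.frame(group = lev, intercept = stats::coef(lmf)[1],
               slope = stats::coef(lmf)[2],
               pearson_r = unname(ct$estimate), p = ct$p.value,
               n = sum(k), row.names = NULL)
  }))

  out <- list(fixed_effects = data.frame(term = colnames(X), estimate = beta,
                                         se = se, row.names = NULL),
              slopes = slopes, slope_difference = slope_difference,
              variance_components = c(family = var_family, residual = var_resid),
              r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
              reml_loglik = -fit$m2ll / 2, lambda = lambda,
              n_observations = n, n_families = q, random_dropped = drop_random,
              ols = ols, data = data.frame(sgr = y, tdi = td, group = g, family = fam))
  class(out) <- "sgr_tdi_lmm"
  out
}

#' @export
print.sgr_tdi_lmm <- function(x, ...) {
  cat(sprintf("SGR ~ TDI x group mixed model (REML, family random intercept)\n"))
  cat(sprintf("  n = %d observations, %d families%s\n", x$n_observations,
              x$n_families, if (x$random_dropped) " (random term dropped)" else ""))
  print(round_df(x$fixed_effects, 4), row.names = FALSE)
  cat(sprintf("  variance components: family %.5f, residual %.5f\n",
              x$variance_components[["family"]], x$variance_components[["residual"]]))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f; REML loglik %.3f\n",
              x$r2_marginal, x$r2_conditional, x$reml_loglik))
  if (!is.null(x$slope_difference)) {
    cat(sprintf("  slope difference: %.4f +/- %.4f (p = %.4g)\n",
                x$slope_difference[["estimate"]], x$slope_difference[["se"]],
                x$slope_difference[["p"]]))
  }
  invisible(x)
}

#' @export
coef.sgr_tdi_lmm <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @export
plot.sgr_tdi_lmm <- function(x, ...) {
  d <- x$data
  cols <- c(montane = "red", lowland = "blue")
  col <- cols[as.character(d$group)]
  col[is.na(col)] <- "black"
  graphics::plot(d$tdi, d$sgr, col = col, pch = 16,
                 xlab = "thermal displacement index (TDI)",
                 ylab = "scaled growth rate (SGR)", ...)
  for (i in seq_len(nrow(x$ols))) {
    graphics::abline(x$ols$intercept[i], x$ols$slope[i], lty = 2,
                     col = cols[x$ols$group[i]])
  }
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for a random-intercept model: the
#' marginal R2 is the share of total variance (fixed + random + residual)
#' explained by the fixed effects alone; the conditional R2 adds the
#' random-intercept variance to the numerator. Always
#' `marginal <= conditional <= 1`.
#'
#' @param fit an [lmm_fit()] object, or a named list/vector with
#'   `var_fixed`, `var_random`, `var_residual`.
#' @return named numeric vector `c(marginal = , conditional = )`.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "sgr_tdi_lmm")) {
    return(c(marginal = fit$r2_marginal, conditional = fit$r2_conditional))
  }
  v <- unlist(fit)
  vf <- v[["var_fixed"]]; vr <- v[["var_random"]]; ve <- v[["var_residual"]]
  tot <- vf + vr + ve
  if (tot <= 0) stop("nakagawa_r2: all variance components are zero")
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}
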