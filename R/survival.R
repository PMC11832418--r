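#' Survival records from a census table
#'
#' Converts the long census table into one (time, event) record per tree.
#' Death is interval-censored by the four-monthly visits; the event time
#' is mapped to the right endpoint, i.e. the date of the first census at
#' which the tree was recorded dead (`midpoint = TRUE` uses the midpoint
#' of the last-alive/first-dead interval instead). Trees alive at their
#' last census are right-censored there. The planting day is Day 1, so
#' `time = days since planting + 1`.
#'
#' @param census census data frame with columns `tree_id`, `species`,
#'   `site`, `campaign_index`, `date`, `alive`, `planting_date`.
#' @param midpoint use midpoint imputation for interval-censored deaths.
#' @return data frame with columns `tree_id`, `species`, `site`, `time`
#'   (days, Day 1 = planting), `event` (1 death observed, 0 censored).
#' @export
build_survival_records <- function(census, midpoint = FALSE) {
  need <- c("tree_id", "species", "site", "campaign_index", "date", "alive", "planting_date")
  miss <- setdiff(need, names(census))
  if (length(miss)) stop("build_survival_records: missing columns: ", paste(miss, collapse = ", "))
  census <- census[order(census$tree_id, census$campaign_index), , drop = FALSE]
  never_observed <- 0L
  rows <- lapply(split(census, census$tree_id), function(tr) {
    planted <- as.Date(tr$planting_date[1L])
    alive <- as.logical(tr$alive)
    if (any(alive & cumsum(!alive) > 0)) {
      stop(sprintf("build_survival_records: tree '%s' recorded alive after dead", tr$tree_id[1L]))
    }
    day <- as.numeric(as.Date(tr$date) - planted) + 1
    if (nrow(tr) == 0L) return(NULL)
    if (any(!alive)) {
      k <- which(!alive)[1L]
      t <- if (midpoint && k > 1L) (day[k - 1L] + day[k]) / 2 else day[k]
      ev <- 1L
    } else {
      t <- day[nrow(tr)]
      ev <- 0L
    }
    data.frame(tree_id = tr$tree_id[1L], species = tr$species[1L], site = tr$site[1L],
               time = t, event = ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param records data frame with columns `time` and `event` (and any
#'   others, ignored). Individuals censored at an event time are counted
#'   in the risk set at that time.
#' @return object of class `km_fit`: event times, numbers at risk, event
#'   counts and the survival step function values.
#' @export
kaplan_meier <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  time <- records$time
  event <- records$event
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
                 n = length(time), n_events = sum(event == 1)),
            class = "km_fit")
}

#' Evaluate a survival step function
#'
#' @param fit a `km_fit` or the survival curve returned by
#'   [predict_survival()].
#' @param t times at which to evaluate S(t).
#' @return survival probabilities, right-continuous step function with
#'   S(t) = 1 before the first event.
#' @export
survival_at <- function(fit, t) {
  if (length(fit$time) == 0L) return(rep(1, length(t)))
  vapply(t, function(tt) {
    k <- sum(fit$time <= tt)
    if (k == 0L) 1 else fit$surv[k]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  if (length(x$time)) {
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     survival = round(x$surv, 4)), row.names = FALSE)
  } else {
    cat("  no events observed; S(t) = 1 throughout\n")
  }
  invisible(x)
}

#' @export
plot.km_fit <- function(x, xlab = "days since planting", ylab = "P(survival)", ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$surv, each = 2)[-length(x$surv) * 2])
  graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

## ---- Cox proportional hazards (Breslow ties) ----

# Breslow log partial likelihood, gradient and Hessian for dummy-coded
# covariates. Small-n implementation: loops over distinct event times.
cox_breslow_ll <- function(beta, time, event, X) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  g <- numeric(ncol(X))
  H <- matrix(0, ncol(X), ncol(X))
  for (t in unique(time[event == 1])) {
    d <- which(event == 1 & time == t)
    r <- which(time >= t)
    sw <- sum(w[r])
    xbar <- colSums(X[r, , drop = FALSE] * w[r]) / sw
    x2 <- crossprod(X[r, , drop = FALSE] * sqrt(w[r])) / sw
    nd <- length(d)
    ll <- ll + sum(eta[d]) - nd * log(sw)
    g <- g + colSums(X[d, , drop = FALSE]) - nd * xbar
    H <- H - nd * (x2 - tcrossprod(xbar))
  }
  list(loglik = ll, gradient = g, hessian = H)
}

#' Cox proportional-hazards fit with site as covariate
#'
#' Fits the Cox model by maximising the Breslow-ties partial likelihood
#' with damped Newton iterations (step-halving whenever a step would
#' decrease the likelihood). Convergence is declared when the gradient
#' max-norm falls below `tol`. Monotone likelihood -- a covariate level
#' whose deaths separate completely from the rest, common in degenerate
#' strata such as a site where every tree dies before any death elsewhere
#' -- is detected when a coefficient exceeds `coef_cap` in absolute value;
#' the coefficient is capped there and flagged instead of diverging.
#' The baseline cumulative hazard uses the Breslow estimator at the
#' reference level.
#'
#' @param records survival records (columns `time`, `event`, plus the
#'   covariate column).
#' @param covariate name of the factor covariate column (default "site").
#' @param reference_level reference factor level; defaults to the first
#'   level. A natural choice is the site whose MAT is nearest the species
#'   thermal optimum, so coefficients read as warming/cooling hazards.
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @param coef_cap |coefficient| beyond which monotone likelihood is
#'   declared.
#' @return object of class `cox_fit`: `coefficients` (log hazard ratios
#'   per non-reference level), `standard_errors`, `log_partial_likelihood`,
#'   `loglik_path` (per-iteration, nondecreasing), `baseline` (Breslow
#'   cumulative-hazard step function at the reference level),
#'   `convergence`, `monotone_likelihood` (flag per level), `levels`,
#'   `reference_level`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariate = "site", reference_level = NULL,
                    tol = 1e-8, max_iter = 100L, coef_cap = 10) {
  stopifnot(is.data.frame(records), covariate %in% names(records))
  time <- records$time
  event <- records$event
  if (sum(event) < 1) stop("cox_fit: no events observed")
  x <- droplevels(factor(records[[covariate]]))
  if (nlevels(x) < 2L) stop("cox_fit: covariate has a single level")
  if (!is.null(reference_level)) {
    if (!as.character(reference_level) %in% levels(x)) {
      stop("cox_fit: unknown reference level '", reference_level, "'")
    }
    x <- stats::relevel(x, ref = as.character(reference_level))
  }
  X <- stats::model.matrix(~x)[, -1, drop = FALSE]
  colnames(X) <- levels(x)[-1]
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_breslow_ll(beta, time, event, X)
  path <- cur$loglik
  status <- "maxiter"
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$gradient)) < tol) { status <- "converged"; break }
    step <- tryCatch(solve(cur$hessian, -cur$gradient), error = function(e) NULL)
    if (is.null(step)) step <- -cur$gradient # fall back to gradient ascent
    for (h in 0:30) {
      cand <- beta + step / 2^h
      nxt <- cox_breslow_ll(cand, time, event, X)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
    }
    beta <- cand
    cur <- nxt
    path <- c(path, cur$loglik)
    if (any(abs(beta) > coef_cap)) break
  }
  monotone <- abs(beta) > coef_cap
  if (any(monotone)) {
    beta <- pmin(pmax(beta, -coef_cap), coef_cap)
    cur <- cox_breslow_ll(beta, time, event, X)
    path <- c(path, cur$loglik)
    status <- "monotone_likelihood"
  }
  se <- rep(NA_real_, p)
  vc <- tryCatch(solve(-cur$hessian), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- names(monotone) <- colnames(X)
  # Breslow baseline cumulative hazard at the reference level
  w <- exp(drop(X %*% beta))
  et <- sort(unique(time[event == 1]))
  dH <- vapply(et, function(t) sum(event == 1 & time == t) / sum(w[time >= t]), numeric(1))
  baseline <- list(time = et, cumhaz = cumsum(dH))
  out <- list(coefficients = beta, standard_errors = se,
              log_partial_likelihood = cur$loglik, loglik_path = path,
              baseline = baseline, convergence = status,
              monotone_likelihood = monotone,
              levels = levels(x), reference_level = levels(x)[1L],
              covariate = covariate, n = length(time), n_events = sum(event))
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Breslow ties): n = %d, events = %d\n",
              x$n, x$n_events))
  cat(sprintf("  covariate '%s', reference level '%s'; %s\n",
              x$covariate, x$reference_level, x$convergence))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$standard_errors, flagged = x$monotone_likelihood,
                    check.names = FALSE)
  print(round_df(tab, 4))
  cat(sprintf("  log partial likelihood: %.4f\n", x$log_partial_likelihood))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
summary.cox_fit <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  tab <- data.frame(coef = object$coefficients, se = object$standard_errors,
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    monotone = object$monotone_likelihood)
  structure(list(fit = object, table = tab), class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

round_df <- function(d, digits) {
  d[] <- lapply(d, function(c) if (is.numeric(c)) round(c, digits) else c)
  d
}

#' Predicted survival curve at a covariate level
#'
#' `S(t) = exp(-Lambda0(t) * exp(x beta))`, with `Lambda0` the Breslow
#' baseline cumulative hazard of the fit. Values are in `[0, 1]` and
#' nonincreasing in time.
#'
#' @param fit a [cox_fit()] object.
#' @param level covariate level to predict for.
#' @return list (same shape as a `km_fit` curve) with `time` and `surv`,
#'   usable with [survival_at()].
#' @export
predict_survival <- function(fit, level) {
  stopifnot(inherits(fit, "cox_fit"))
  level <- as.character(level)
  if (!level %in% fit$levels) stop("predict_survival: unknown level '", level, "'")
  eta <- if (level == fit$reference_level) 0 else fit$coefficients[[level]]
  list(time = fit$baseline$time,
       surv = exp(-fit$baseline$cumhaz * exp(eta)),
       level = level)
}

#' Raw survival proportion at a horizon
#'
#' Fraction of planted trees of one species at one site still alive at
#' `horizon` days after planting, judged by each tree's last census at or
#' before the horizon (trees without any census by then count as alive,
#' i.e. not yet observed dead).
#'
#' @param census census table (see [build_survival_records()]).
#' @param species,site selection.
#' @param horizon days since planting (Day 1 = planting).
#' @return fraction in `[0, 1]`.
#' @export
survival_rate <- function(census, species, site, horizon) {
  sel <- census[census$species == species & census$site == site, , drop = FALSE]
  if (nrow(sel) == 0L) stop("survival_rate: no trees for ", species, " at ", site)
  sel <- sel[order(sel$tree_id, sel$campaign_index), , drop = FALSE]
  alive <- vapply(split(sel, sel$tree_id), function(tr) {
    day <- as.numeric(as.Date(tr$date) - as.Date(tr$planting_date[1L])) + 1
    k <- which(day <= horizon)
    if (length(k) == 0L) TRUE else as.logical(tr$alive[max(k)])
  }, logical(1))
  mean(alive)
}
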