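library(survival)

sim_surv <- function(n, rates, censor_day, seed, sites = names(rates)) {
  set.seed(seed)
  site <- rep(sites, each = n / length(rates))
  t <- stats::rexp(n, rates[site] / 365.25)
  data.frame(tree_id = paste0("t", 1:n), species = "sp", site = site,
             time = pmin(t, censor_day), event = as.integer(t <= censor_day),
             stringsAsFactors = FALSE)
}

test_that("survival records map interval-censored deaths to the right endpoint", {
  surv <- toy_tree("t1", "sp", "s1", rep(10, 9), rep(TRUE, 9))
  dead <- toy_tree("t2", "sp", "s1", rep(10, 9), c(TRUE, TRUE, TRUE, rep(FALSE, 6)))
  rec <- build_survival_records(rbind(surv, dead))
  day <- function(k) as.numeric(as.Date("2019-02-01") + 122 * k - as.Date("2018-11-15")) + 1
  expect_equal(rec$time[rec$tree_id == "t1"], day(8))
  expect_equal(rec$event[rec$tree_id == "t1"], 0L)
  expect_equal(rec$time[rec$tree_id == "t2"], day(3)) # first campaign seen dead
  expect_equal(rec$event[rec$tree_id == "t2"], 1L)
  # midpoint imputation option
  rec2 <- build_survival_records(rbind(surv, dead), midpoint = TRUE)
  expect_equal(rec2$time[rec2$tree_id == "t2"], (day(2) + day(3)) / 2)
  # one record per tree, positive times
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$time > 0))
  zombie <- toy_tree("t3", "sp", "s1", rep(10, 9),
                     c(TRUE, FALSE, TRUE, rep(FALSE, 6)))
  expect_error(build_survival_records(zombie), "alive after dead")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  rec <- data.frame(time = c(10, 20, 25, 30), event = c(1, 1, 0, 1))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(10, 20, 30))
  expect_equal(km$surv, c(0.75, 0.50, 0.00))
  expect_equal(survival_at(km, c(5, 10, 22, 27, 31)), c(1, 0.75, 0.5, 0.5, 0))
  allc <- kaplan_meier(data.frame(time = c(5, 8), event = c(0, 0)))
  expect_equal(survival_at(allc, c(1, 10)), c(1, 1))
  one <- kaplan_meier(data.frame(time = 7, event = 1))
  expect_equal(survival_at(one, c(6.9, 7)), c(1, 0))
})

test_that("Kaplan-Meier agrees with survival::survfit under ties and censoring", {
  set.seed(8)
  rec <- data.frame(time = sample(1:20, 120, replace = TRUE),
                    event = stats::rbinom(120, 1, 0.6))
  km <- kaplan_meier(rec)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  at_events <- summary(sf, times = km$time)
  expect_equal(km$surv, at_events$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, at_events$n.risk, tolerance = 1e-12)
})

test_that("Cox fit is symmetric, rank-invariant and matches coxph (Breslow)", {
  # identical event patterns in two sites
  rec <- data.frame(time = rep(c(10, 20, 30, 40), 2),
                    event = rep(c(1, 1, 0, 1), 2),
                    site = rep(c("A", "B"), each = 4))
  f <- cox_fit(rec)
  expect_lt(abs(f$coefficients[["B"]]), 1e-6)
  # moderate 3-site data with heavy ties against the reference fit
  rec2 <- sim_surv(120, c(A = 0.2, B = 0.5, C = 0.9), 900, seed = 31)
  rec2$time <- ceiling(rec2$time / 122) * 122 # census-date ties
  f2 <- cox_fit(rec2, reference_level = "A")
  cp <- survival::coxph(survival::Surv(time, event) ~ site, data = rec2,
                        ties = "breslow")
  expect_equal(unname(f2$coefficients), unname(stats::coef(cp)), tolerance = 1e-6)
  expect_equal(unname(f2$standard_errors), unname(sqrt(diag(stats::vcov(cp)))),
               tolerance = 1e-5)
  expect_equal(f2$log_partial_likelihood, cp$loglik[2], tolerance = 1e-8)
  expect_equal(f2$convergence, "converged")
  # rank invariance: doubling all times leaves the coefficients unchanged
  rec3 <- rec2
  rec3$time <- rec3$time * 2
  expect_equal(cox_fit(rec3, reference_level = "A")$coefficients,
               f2$coefficients, tolerance = 1e-8)
})

test_that("Newton iterations never decrease the Breslow partial likelihood", {
  for (seed in c(2, 5, 9)) {
    rec <- sim_surv(60, c(A = 0.3, B = 0.9), 1000, seed = seed)
    f <- cox_fit(rec)
    expect_true(all(diff(f$loglik_path) >= -1e-10))
    expect_gte(f$log_partial_likelihood, f$loglik_path[1]) # beats beta = 0
    expect_true(all(diff(f$baseline$cumhaz) >= 0))
  }
})

test_that("Cox maximiser matches a brute-force likelihood grid on a small instance", {
  set.seed(14)
  t <- c(3, 7, 11, 15, 19, 24, 30, 37) # tie-free
  rec <- data.frame(time = t, event = c(1, 1, 0, 1, 1, 0, 1, 1),
                    site = c("A", "B", "A", "B", "A", "B", "A", "B"))
  f <- cox_fit(rec, reference_level = "A")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- breslow2_oracle(grid, rec$time, rec$event, as.integer(rec$site == "B"))
  expect_lt(abs(f$coefficients[["B"]] - grid[which.max(ll)]), 1e-3)
})

test_that("complete separation of deaths across sites is capped and flagged", {
  rec <- data.frame(time = c(1:10, rep(400, 10)),
                    event = c(rep(1, 10), rep(0, 10)),
                    site = rep(c("A", "B"), each = 10))
  f <- expect_silent(cox_fit(rec, reference_level = "A"))
  expect_true(f$monotone_likelihood[["B"]])
  expect_equal(f$convergence, "monotone_likelihood")
  expect_equal(abs(unname(f$coefficients)), 10)
  expect_error(cox_fit(rec[rec$site == "A", ]), "single level")
  expect_error(cox_fit(within(rec, event <- 0L)), "no events")
})

test_that("predicted survival curves are proper and ordered by hazard", {
  rec <- sim_surv(100, c(A = 0.3, B = 1.2), 1000, seed = 4)
  f <- cox_fit(rec, reference_level = "A")
  sa <- predict_survival(f, "A")
  sb <- predict_survival(f, "B")
  expect_equal(sa$surv, exp(-f$baseline$cumhaz)) # reference curve
  expect_true(all(sa$surv >= 0 & sa$surv <= 1))
  expect_true(all(diff(sa$surv) <= 1e-12))
  expect_true(all(sb$surv <= sa$surv + 1e-12)) # higher hazard, lower curve
  expect_error(predict_survival(f, "Z"), "unknown level")
})

test_that("with a null coefficient the Cox curve matches the pooled Kaplan-Meier", {
  # tie-free symmetric data force beta ~ 0; then exp(-Breslow baseline)
  # approximates the product-limit curve within estimator tolerance
  set.seed(12)
  t <- sort(stats::runif(80, 1, 1000))
  rec <- data.frame(time = t, event = rep(c(1, 1, 1, 0), 20),
                    site = rep(c("A", "B"), 40))
  null_fit <- cox_fit(rec, coef_cap = 1e-12) # caps beta at ~0
  km <- kaplan_meier(rec)
  expect_lt(max(abs(exp(-null_fit$baseline$cumhaz) - km$surv)), 0.02)
})

test_that("Cox estimates recover a known log hazard ratio across replicates", {
  # n = 72, true log-HR 1.0, continuous times with administrative censoring
  betas <- ses <- numeric(200)
  for (i in 1:200) {
    rec <- sim_surv(72, c(A = 0.25, B = 0.25 * exp(1)), 1096, seed = 5000 + i)
    f <- cox_fit(rec, reference_level = "A")
    betas[i] <- f$coefficients[["B"]]
    ses[i] <- f$standard_errors[["B"]]
  }
  expect_lt(abs(mean(betas) - 1), 0.1)
  expect_lt(abs(stats::sd(betas) - mean(ses)) / stats::sd(betas), 0.25)
})

test_that("survival rate counts last observations at or before the horizon", {
  all_alive <- toy_tree("a1", "sp", "s1", rep(10, 9), rep(TRUE, 9))
  expect_equal(survival_rate(all_alive, "sp", "s1", 2000), 1.0)
  dead <- toy_tree("a2", "sp", "s2", rep(10, 9), c(TRUE, rep(FALSE, 8)))
  expect_equal(survival_rate(dead, "sp", "s2", 2000), 0.0)
  expect_error(survival_rate(dead, "sp", "nowhere", 100), "no trees")
  # counting oracle on a synthetic cohort
  tr <- scenario_truth(3)
  cen <- gen_census(tr, seed = 3)
  truth <- attr(cen, "truth_trees")
  sp <- "Quercus humboldtii"
  for (site in c("14C", "22C")) {
    camp_days <- sort(unique(as.numeric(as.Date(cen$date) - as.Date(cen$planting_date))))
    horizon <- 800
    last_camp <- max(camp_days[camp_days <= horizon - 1])
    expected <- mean(truth$death_day[truth$species == sp & truth$site == site] > last_camp)
    expect_equal(survival_rate(cen, sp, site, horizon), expected)
  }
  # 24 planted, one death: the 23/24 proportion
  one_death <- do.call(rbind, lapply(1:24, function(i) {
    toy_tree(paste0("q", i), "sp", "s3", rep(10, 9),
             if (i == 1) c(rep(TRUE, 5), rep(FALSE, 4)) else rep(TRUE, 9))
  }))
  expect_equal(survival_rate(one_death, "sp", "s3", 2000), 23 / 24)
})
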