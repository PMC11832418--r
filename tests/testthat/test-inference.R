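library(lme4)

sim_lmm_data <- function(seed, b_m = -0.08, b_l = 0.07, a = 0.95,
                         fam_sd = 0.05, res_sd = 0.1) {
  set.seed(seed)
  ref <- species_thermal_reference()
  sites <- site_climate_reference()
  d <- tdi_table(ref, sites, metrics = "mat")
  d$group <- ref$group[match(d$species, ref$species)]
  d$family <- ref$family[match(d$species, ref$species)]
  u <- stats::rnorm(length(unique(d$family)), 0, fam_sd)
  names(u) <- unique(d$family)
  b <- ifelse(d$group == "montane", b_m, b_l)
  d$sgr <- a + b * d$tdi + u[d$family] + stats::rnorm(nrow(d), 0, res_sd)
  d
}

test_that("Welch t matches the textbook formula and behaves at the extremes", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_t_test(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(got$statistic, ora$t, tolerance = 1e-10)
  expect_equal(got$degrees_of_freedom, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- welch_t_test(stats::rnorm(10, 0, 0.01), stats::rnorm(10, 100, 0.01))
  expect_lt(far$p_value, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "degenerate")
  expect_error(welch_t_test(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("Welch statistics are invariant under common affine transforms", {
  set.seed(71)
  a <- stats::rnorm(12, 5, 2); b <- stats::rnorm(20, 6, 4)
  t1 <- welch_t_test(a, b)
  t2 <- welch_t_test(3 * a - 7, 3 * b - 7)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  g <- list(a, b, stats::rnorm(8, 5, 1))
  f1 <- welch_anova(g)
  f2 <- welch_anova(lapply(g, function(x) -2 * x + 1))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
})

test_that("Welch ANOVA reduces to the squared Welch t with two groups", {
  set.seed(19)
  a <- stats::rnorm(14, 1, 1); b <- stats::rnorm(9, 2, 3)
  fa <- welch_anova(list(a, b))
  tt <- welch_t_test(a, b)
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(fa$p_value, tt$p_value, tolerance = 1e-10)
  flat <- welch_anova(list(c(1, 2, 3), c(1.001, 2, 2.999), c(1, 2.001, 3)))
  expect_lt(flat$statistic, 0.01)
  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "degenerate")
})

test_that("Welch ANOVA tracks classical one-way ANOVA when variances are equal", {
  set.seed(23)
  ratio <- replicate(50, {
    g <- lapply(1:3, function(i) stats::rnorm(15, i * 0.3, 1))
    y <- unlist(g); f <- factor(rep(1:3, each = 15))
    welch_anova(g)$statistic / summary(stats::aov(y ~ f))[[1]]$`F value`[1]
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("type-II two-way ANOVA isolates the acting factor", {
  set.seed(4)
  d <- expand.grid(species = paste0("s", 1:5), site = c("A", "B", "C"),
                   rep = 1:6)
  mu <- stats::setNames(stats::rnorm(5, 0, 2), paste0("s", 1:5))
  d$rgr <- mu[d$species] + stats::rnorm(nrow(d), 0, 1e-3)
  tab <- two_way_anova(d$rgr, d$species, d$site)
  expect_lt(tab["species", "Pr(>F)"], 1e-10)
  expect_gt(tab["site", "Pr(>F)"], 0.1)
})

test_that("type-II equals sequential sums of squares on balanced data", {
  set.seed(6)
  d <- expand.grid(species = paste0("s", 1:4), site = c("A", "B"), rep = 1:5)
  d$rgr <- stats::rnorm(nrow(d))
  t2 <- two_way_anova(d$rgr, d$species, d$site)
  t1 <- stats::anova(stats::lm(rgr ~ species * site, data = d))
  expect_equal(t2["species", "Sum Sq"], t1["species", "Sum Sq"], tolerance = 1e-10)
  expect_equal(t2["site", "Sum Sq"], t1["site", "Sum Sq"], tolerance = 1e-10)
  expect_equal(t2["species:site", "Sum Sq"], t1["species:site", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("two-way ANOVA p-values are uniform under permutation of the response", {
  set.seed(90)
  d <- expand.grid(species = paste0("s", 1:3), site = c("A", "B", "C"), rep = 1:5)
  d$rgr <- 0.5 * (d$species == "s1") + stats::rnorm(nrow(d))
  p <- replicate(500, {
    two_way_anova(sample(d$rgr), d$species, d$site,
                  interaction = FALSE)["species", "Pr(>F)"]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("two-way ANOVA drops inestimable terms with a warning", {
  d <- expand.grid(species = c("a", "b"), site = c("X", "Y"), rep = 1:4)
  d <- d[!(d$species == "a" & d$site == "X"), ]
  set.seed(1); d$rgr <- stats::rnorm(nrow(d))
  expect_warning(two_way_anova(d$rgr, d$species, d$site), "interaction term dropped")
})

test_that("Tukey HSD honours its identities and its thresholds", {
  g <- list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(1, 2, 3, 4))
  tk <- tukey_hsd(g)
  expect_true(all(tk$p_adj > 0.999))
  expect_true(all(tk$stars == ""))
  # two groups: studentized-range p equals the pooled two-sample t p
  set.seed(13)
  a <- stats::rnorm(10); b <- stats::rnorm(12, 1)
  tk2 <- tukey_hsd(list(A = a, B = b))
  pt2 <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(tk2$p_adj, pt2, tolerance = 1e-8)
  expect_warning(tk3 <- tukey_hsd(list(A = a, B = b, C = 1)), "excluded")
  expect_equal(nrow(tk3), 1L)
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})

test_that("the mixed model collapses to OLS when family variance is absent", {
  d <- sim_lmm_data(55, fam_sd = 0, res_sd = 0.08)
  fit <- lmm_fit(d)
  X <- stats::model.matrix(~ 0 + group + group:tdi, data = d)
  ols <- stats::lm.fit(X, d$sgr)
  expect_equal(unname(coef(fit)), unname(ols$coefficients), tolerance = 1e-4)
  # single family: random term dropped with warning, exact OLS
  d2 <- d
  d2$family <- "one"
  expect_warning(fit2 <- lmm_fit(d2), "fewer than two families")
  expect_equal(unname(coef(fit2)), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("the mixed model agrees with lme4 REML on simulated data", {
  for (seed in c(301, 302)) {
    d <- sim_lmm_data(seed)
    fit <- lmm_fit(d)
    lf <- lme4::lmer(sgr ~ 0 + group + group:tdi + (1 | family), data = d,
                     REML = TRUE)
    expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(unname(fit$variance_components[["family"]]),
                 vc$vcov[vc$grp == "family"], tolerance = 1e-3)
    expect_equal(unname(fit$variance_components[["residual"]]),
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
    expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
    se_lmer <- sqrt(diag(as.matrix(stats::vcov(lf))))
    expect_equal(unname(fit$fixed_effects$se), unname(se_lmer), tolerance = 1e-3)
  }
})

test_that("the REML profile is maximised at the reported variance ratio", {
  d <- sim_lmm_data(77)
  fit <- lmm_fit(d)
  ratios <- fit$lambda * exp(seq(-2, 2, length.out = 25))
  lls <- vapply(ratios, function(l) lmm_fit(d, lambda = l)$reml_loglik, numeric(1))
  expect_true(all(fit$reml_loglik >= lls - 1e-7))
})

test_that("variance-partition R2 follows its closed form and ordering", {
  r2 <- nakagawa_r2(list(var_fixed = 1, var_random = 1, var_residual = 2))
  expect_equal(unname(r2), c(0.25, 0.50))
  r2b <- nakagawa_r2(list(var_fixed = 3, var_random = 0, var_residual = 1))
  expect_equal(r2b[["marginal"]], r2b[["conditional"]])
  expect_error(nakagawa_r2(list(var_fixed = 0, var_random = 0, var_residual = 0)),
               "zero")
  # noiseless linear data, no random effect: marginal R2 tends to 1
  d <- sim_lmm_data(88, fam_sd = 0, res_sd = 1e-8)
  fit <- lmm_fit(d)
  expect_gt(fit$r2_marginal, 0.999)
  # ordering holds on stochastic fits too
  for (seed in 401:405) {
    f <- lmm_fit(sim_lmm_data(seed))
    expect_lte(f$r2_marginal, f$r2_conditional)
    expect_lte(f$r2_conditional, 1)
  }
})

test_that("Welch t holds its nominal size under strong heteroscedasticity", {
  set.seed(60)
  rejections <- mean(replicate(5000, {
    welch_t_test(stats::rnorm(10, 0, 4), stats::rnorm(40, 0, 1))$p_value < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
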