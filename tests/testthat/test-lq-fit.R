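test_that("surviving fraction normalises counts by plating efficiency", {
  expect_equal(surviving_fraction(150, 5000, 0.6), 0.05)
  # control identity: colonies = plated * PE gives SF = 1
  expect_equal(surviving_fraction(0.6 * 2000, 2000, 0.6), 1)
  expect_equal(surviving_fraction(0, 5000, 0.6), 0)
  expect_error(surviving_fraction(10, 0, 0.6))
  expect_error(surviving_fraction(10, 100, 0))
})

test_that("plating efficiency comes from same-set controls, so control SF averages 1", {
  rec <- exact_records(0.2, 0.02)
  rec$colonies[rec$replicate_set == "R2"] <-
    rec$colonies[rec$replicate_set == "R2"] * 0.8  # set-specific efficiency
  pe <- plating_efficiency(rec)
  expect_equal(unname(pe), c(0.6, 0.48))
  dat <- prepare_survival_data(rec)
  ctrl <- dat[dat$dose_Gy == 0, ]
  expect_equal(unname(c(tapply(ctrl$sf, ctrl$replicate_set, mean))), c(1, 1))
})

test_that("zero-colony wells are flagged and excluded with a warning", {
  rec <- exact_records(0.2, 0.02)
  rec$colonies[nrow(rec)] <- 0
  dat <- prepare_survival_data(rec)
  expect_equal(sum(dat$excluded), 1L)
  expect_true(is.na(dat$y[dat$excluded]))
  expect_warning(fit <- fit_lqm(rec), "non-positive surviving fraction")
  expect_equal(nrow(fit$excluded), 1L)
  expect_equal(fit$n_obs, nrow(rec) - 1L)
})

test_that("noise-free data recover the generating coefficients exactly", {
  fit <- fit_lqm(exact_records(alpha = 0.2, beta = 0.02))
  expect_equal(fit$alpha, 0.2, tolerance = 1e-8)
  expect_equal(fit$beta, 0.02, tolerance = 1e-8)
  expect_lt(fit$sigma_e, 1e-8)

  fit1 <- fit_lqm(exact_records(alpha = 0.25, beta = 0), alpha_only = TRUE)
  expect_equal(fit1$alpha, 0.25, tolerance = 1e-8)
  expect_identical(fit1$beta, 0)
  expect_true(fit1$alpha_only)
})

test_that("REML fit matches nlme::lme on stochastic data", {
  skip_if_not_installed("nlme")
  spec <- simulation_spec(0.273, 0.0189, sigma_b = 0.1, seed = 99)
  dat <- prepare_survival_data(simulate_clonogenic(spec))
  dat <- dat[!dat$excluded, ]
  dat$D <- dat$dose_Gy
  dat$D2 <- dat$dose_Gy^2
  ours <- fit_lqm(dat)
  ref <- nlme::lme(y ~ D + D2 - 1, random = ~ 1 | replicate_set,
                   data = dat, method = "REML")
  expect_equal(ours$alpha, unname(nlme::fixef(ref)[1]), tolerance = 1e-6)
  expect_equal(ours$beta, unname(nlme::fixef(ref)[2]), tolerance = 1e-6)
  expect_equal(ours$sigma_e, ref$sigma, tolerance = 1e-5)
  expect_equal(ours$sigma_b,
               as.numeric(nlme::VarCorr(ref)[1, 2]), tolerance = 1e-4)
  expect_equal(unname(ours$vcov[1:2, 1:2]), unname(as.matrix(vcov(ref))),
               tolerance = 1e-5)
})

test_that("with no replicate heterogeneity the fit collapses to least squares", {
  # with sigma_b = 0 in the generator the REML profile resolves to the
  # sigma_b = 0 boundary for most datasets, and there the mixed-model
  # estimates equal OLS through the origin
  n_boundary <- 0L
  for (s in 1:10) {
    spec <- simulation_spec(0.273, 0.0189, sigma_b = 0, seed = s,
                            cells_plated = 100000L)
    dat <- prepare_survival_data(simulate_clonogenic(spec))
    fit <- fit_lqm(dat)
    if (fit$sigma_b == 0) {
      n_boundary <- n_boundary + 1L
      ols <- lm(y ~ I(dose_Gy) + I(dose_Gy^2) - 1, data = dat)
      expect_equal(fit$alpha, unname(coef(ols)[1]), tolerance = 1e-6)
      expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-6)
    }
  }
  expect_gte(n_boundary, 3L)
})

test_that("a single replicate set degrades to fixed-effects least squares", {
  rec <- exact_records(0.2, 0.02, sets = "R1")
  expect_warning(fit <- fit_lqm(rec), "one replicate set")
  expect_equal(fit$alpha, 0.2, tolerance = 1e-8)
  expect_equal(fit$sigma_b, 0)
})

test_that("degenerate designs are rejected", {
  rec <- exact_records(0.2, 0.02, doses = c(0, 4))
  expect_error(fit_lqm(rec), "distinct positive dose")
  expect_error(fit_lqm(exact_records(0.2, 0.02, doses = 0)), "control|dose")
})

test_that("delta-method alpha/beta SE matches Monte-Carlo propagation", {
  # build an lq_fit shell with a controlled covariance, then compare the
  # delta-method SE with the SD of the ratio over bivariate-normal draws
  # the first-order delta SE tracks the exact ratio SD while the
  # parameter uncertainties are moderate (CV(beta) up to ~12%); the
  # cases mirror covariance shapes the fitter produces
  set.seed(303)
  cases <- list(
    list(a = 0.273, b = 0.0189, sa = 0.02, sb = 0.0019, rho = -0.9),
    list(a = 0.050, b = 0.0276, sa = 0.005, sb = 0.0022, rho = -0.3),
    list(a = 0.300, b = 0.0300, sa = 0.015, sb = 0.0030, rho = 0.2)
  )
  for (cs in cases) {
    stopifnot(cs$sb / cs$b < 0.2)  # delta method valid regime
    fit <- structure(list(alpha = cs$a, beta = cs$b,
                          var_alpha = cs$sa^2, var_beta = cs$sb^2,
                          cov_alpha_beta = cs$rho * cs$sa * cs$sb,
                          alpha_only = FALSE), class = "lq_fit")
    est <- alpha_beta_ratio(fit)
    expect_equal(est$value, cs$a / cs$b)
    z <- matrix(rnorm(2 * 1e5), ncol = 2)
    a_draw <- cs$a + cs$sa * z[, 1]
    b_draw <- cs$b + cs$sb * (cs$rho * z[, 1] + sqrt(1 - cs$rho^2) * z[, 2])
    expect_equal(est$se, sd(a_draw / b_draw), tolerance = 0.05)
    expect_true(est$ci_low <= est$value && est$value <= est$ci_high)
  }
})

test_that("alpha/beta is undefined for an alpha-only fit", {
  fit <- suppressWarnings(
    fit_lqm(exact_records(0.25, 0, sets = "R1"), alpha_only = TRUE))
  expect_error(alpha_beta_ratio(fit), "alpha-only")
})

test_that("zero covariance gives zero ratio SE", {
  fit <- structure(list(alpha = 0.273, beta = 0.0189, var_alpha = 0,
                        var_beta = 0, cov_alpha_beta = 0,
                        alpha_only = FALSE), class = "lq_fit")
  expect_equal(alpha_beta_ratio(fit)$se, 0)
})

test_that("Wald test has the normal-quantile identities", {
  expect_equal(wald_test(0, 1), 1)
  expect_equal(wald_test(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_test(1, 0), 0)
  expect_equal(wald_test(0, 0), 1)
  # a beta whose 95% CI spans zero is not significant
  expect_gt(wald_test(0.00109, 0.00062), 0.05)
})
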