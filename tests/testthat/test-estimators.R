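test_that("Cox fits agree with a brute-force partial-likelihood oracle", {
  cases <- list(
    list(time = c(1, 2, 3), event = c(1, 1, 1), x = c(1, 0, 1)),
    list(time = c(0.5, 1.3, 2.2, 3.1, 4.0),
         event = c(1, 1, 0, 1, 1), x = c(1, 0, 1, 0, 1)),
    list(time = c(0.2, 0.9, 1.4, 2.5, 3.3, 4.8),
         event = c(1, 0, 1, 1, 1, 0), x = c(0.3, -1.2, 0.8, 0.1, -0.5, 1.7))
  )
  for (cs in cases) {
    ds <- tiny_dataset(cs$time, cs$event, cs$x)
    fit <- fit_cox_ph(ds, covariates = "trt")
    expect_equal(fit$log_hr, oracle_cox_fit(cs$time, cs$event, cs$x),
                 tolerance = 1e-6)
    expect_equal(fit$loglik,
                 oracle_cox_loglik(fit$log_hr, cs$time, cs$event, cs$x),
                 tolerance = 1e-8)
  }
})

test_that("Cox fit handles degenerate inputs as specified", {
  ds <- tiny_dataset(c(1, 2, 3), c(1, 1, 0), c(0, 0, 0))
  fit <- fit_cox_ph(ds, covariates = "trt")
  expect_identical(fit$log_hr, 0)
  expect_identical(fit$se, Inf)
  expect_false(fit$converged)

  none <- tiny_dataset(c(1, 2), c(0, 0), c(1, 0))
  expect_error(fit_cox_ph(none), "no events")

  ok <- tiny_dataset(c(1, 2, 3, 4), c(1, 1, 1, 0), c(1, 0, 1, 0))
  f <- fit_cox_ph(ok, covariates = "trt")
  expect_equal(f$ci95, c(f$log_hr - 1.96 * f$se, f$log_hr + 1.96 * f$se))
  expect_lte(f$n_events, f$n_at_risk)
})

test_that("year-specific fits use the (t-1, t] risk window", {
  # subject 2 has the event at 2.5: event in year 3, censored in years 1-2,
  # absent from year 4 on
  ds <- tiny_dataset(c(5, 2.5, 4.5, 5, 5, 5), c(0, 1, 1, 0, 0, 0),
                     c(1, 1, 0, 0, 1, 0))
  y3 <- fit_year_specific_cox(ds, 3, covariates = "trt")
  expect_identical(y3$n_events, 1L)
  expect_identical(y3$n_at_risk, 6L)
  y4 <- fit_year_specific_cox(ds, 4, covariates = "trt")
  expect_identical(y4$n_at_risk, 5L)   # subject 2 gone
  y1 <- fit_year_specific_cox(ds, 1, covariates = "trt")
  expect_identical(y1$n_events, 0L)
  expect_true(is.na(y1$log_hr))

  # year-1 fit equals an ordinary fit on data censored at 1 year
  scen <- quick_scenario(n = 600, surv = 0.7)
  big <- simulate_trial(scen, seed = 31)
  a <- fit_year_specific_cox(big, 1)
  cens1 <- big
  cens1$event <- as.integer(cens1$event == 1 & cens1$exit <= 1)
  cens1$exit <- pmin(cens1$exit, 1)
  b <- fit_cox_ph(cens1)
  expect_equal(a$log_hr, b$log_hr, tolerance = 1e-8)
  expect_equal(a$se, b$se, tolerance = 1e-8)
})

test_that("year-specific fits recover piecewise-constant true effects", {
  # strong effect in years 1-2, none afterwards; no susceptibility, so each
  # year's fit must recover that year's truth within Monte-Carlo error
  eff <- treatment_effect_spec(
    "piecewise_linear_log_hr",
    anchors = data.frame(time = c(2, 2.000001), log_hr = c(log(2.5), 0)))
  scen <- scenario("pw", 3000, 0.8, susceptibility_spec("none"), eff,
                   censoring_rule("fixed_horizon", horizon = 5),
                   estimand_set = "year_specific")
  est2 <- est4 <- numeric(60)
  for (i in 1:60) {
    ds <- simulate_trial(scen, seed = 4000 + i)
    est2[i] <- fit_year_specific_cox(ds, 2)$log_hr
    est4[i] <- fit_year_specific_cox(ds, 4)$log_hr
  }
  expect_equal(mean(est2), log(2.5), tolerance = 3 * sd(est2) / sqrt(60) + 0.02)
  expect_equal(mean(est4), 0, tolerance = 3 * sd(est4) / sqrt(60) + 0.02)
})

test_that("last-period fits isolate the trailing events", {
  scen <- quick_scenario(n = 2000, surv = 0.7)
  ds <- simulate_trial(scen, seed = 41)
  total <- sum(ds$event)
  f30 <- fit_last_period_cox(ds, 30)
  expect_identical(f30$n_events, 30L)
  fall <- fit_last_period_cox(ds, total)
  whole <- fit_cox_ph(ds)
  expect_equal(fall$log_hr, whole$log_hr, tolerance = 1e-10)
  expect_error(fit_last_period_cox(ds, total + 1), "n_last_events")
})

test_that("quadratic spline basis is a partition of unity spanning constants", {
  spec0 <- spline_basis_spec(numeric(0), c(0, 10))
  tt <- c(0, 0.37, 2, 5.5, 9.99, 10)
  B0 <- quadratic_spline_basis(spec0, tt)
  expect_identical(ncol(B0), 3L)
  expect_equal(rowSums(B0), rep(1, length(tt)))

  spec2 <- spline_basis_spec(c(3, 7), c(0, 10))
  B2 <- quadratic_spline_basis(spec2, tt)
  expect_identical(ncol(B2), 5L)
  expect_equal(rowSums(B2), rep(1, length(tt)))
  # equal coefficients c give the constant curve log HR = c
  expect_equal(drop(B2 %*% rep(1.7, 5)), rep(1.7, length(tt)))

  expect_warning(quadratic_spline_basis(spec0, c(-1, 11)), "clamped")
  expect_error(spline_basis_spec(c(0, 5), c(0, 10)), "strictly inside")
})

test_that("TD spline fit nests the PH fit and both code paths agree", {
  scen <- quick_scenario(n = 400, surv = 0.7)
  ds <- simulate_trial(scen, seed = 51)
  basis <- spline_basis_spec(c(1.5, 3), c(0, max(ds$exit)))

  fast <- fit_td_spline_cox(ds, basis = basis, covariates = "trt")
  # the generic episode-split path with age and sex adjustment
  slow <- fit_td_spline_cox(ds, basis = basis, covariates = c("trt", "age", "sex"))

  expect_gte(fast$loglik, fast$ph_loglik - 1e-8)
  expect_gte(slow$loglik, slow$ph_loglik - 1e-8)
  expect_identical(fast$lrt_df, 4L)

  lrt <- lrt_ph(fast)
  expect_equal(lrt$stat, fast$lrt_stat)
  expect_equal(lrt$p,
               pchisq(lrt$stat, lrt$df, lower.tail = FALSE))

  basis0 <- spline_basis_spec(numeric(0), c(0, max(ds$exit)))
  f0 <- fit_td_spline_cox(ds, basis = basis0, covariates = "trt")
  expect_identical(f0$lrt_df, 2L)  # 3 basis functions - 1
})

test_that("collapsed and split TD representations give identical estimates", {
  scen <- quick_scenario(n = 250, surv = 0.6)
  ds <- simulate_trial(scen, seed = 52)
  basis <- spline_basis_spec(1.8, c(0, max(ds$exit)))
  fast <- fit_td_spline_cox(ds, basis = basis, covariates = "trt",
                            split_method = "collapsed")
  slow <- fit_td_spline_cox(ds, basis = basis, covariates = "trt",
                            split_method = "episodes")
  expect_equal(fast$coefficients, slow$coefficients, tolerance = 1e-7)
  expect_equal(fast$loglik, slow$loglik, tolerance = 1e-9)
  expect_equal(fast$ph_loglik, slow$ph_loglik, tolerance = 1e-9)
  expect_equal(fast$lrt_stat, slow$lrt_stat, tolerance = 1e-7)
  expect_equal(fast$ph_log_hr, fit_cox_ph(ds, covariates = "trt")$log_hr,
               tolerance = 1e-6)
})

test_that("fitted TD curves recover a decaying true effect without bias", {
  # true log HR decays linearly from log(1.81) to 0 over the second half of
  # follow-up; no susceptibility
  eff <- treatment_effect_spec(
    "piecewise_linear_log_hr",
    anchors = data.frame(time = c(2.5, 5), log_hr = c(log(1.81), 0)))
  scen <- scenario("decay", 2500, 0.8, susceptibility_spec("none"), eff,
                   censoring_rule("fixed_horizon", horizon = 5),
                   include_covariates = FALSE, estimand_set = "td_spline")
  grid <- c(1, 2.5, 3.75, 4.6)
  truth <- treatment_log_hr(eff, grid)
  curves <- t(sapply(1:50, function(i) {
    ds <- simulate_trial(scen, seed = 6000 + i)
    fit_td_spline_cox(ds)$curve(grid)$log_hr
  }))
  mc <- mean_td_curve(curves, grid)
  se <- apply(curves, 2, sd) / sqrt(nrow(curves))
  expect_true(all(abs(mc$mean - truth) < 3 * se + 0.06))
})
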