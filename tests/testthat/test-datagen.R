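test_that("baseline hazard calibration inverts 5-year exponential survival", {
  expect_equal(calibrate_baseline_hazard(0.9), 0.0210721, tolerance = 1e-5)
  expect_equal(calibrate_baseline_hazard(0.999), 0.0002001, tolerance = 1e-4)
  expect_equal(calibrate_baseline_hazard(0.7), 0.0713350, tolerance = 1e-5)
  expect_equal(exp(-5 * calibrate_baseline_hazard(0.85)), 0.85)
  expect_error(calibrate_baseline_hazard(0), "\\(0, 1\\)")
  expect_error(calibrate_baseline_hazard(1), "\\(0, 1\\)")
})

test_that("cohorts have the designed covariate distributions", {
  scen <- quick_scenario(n = 4000,
                         susc = susceptibility_spec("bernoulli",
                                                    prevalence = 0.25,
                                                    hr_per_unit = 10))
  ch <- generate_cohort(scen, seed = 11)
  se_half <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(ch$treatment) - 0.5), 3 * se_half)
  expect_lt(abs(mean(ch$sex) - 0.5), 3 * se_half)
  expect_lt(abs(mean(ch$susceptibility) - 0.25),
            3 * sqrt(0.25 * 0.75 / 4000))
  expect_true(all(ch$age >= 20 & ch$age <= 100))
  expect_lt(abs(mean(ch$age) - 60), 0.5)
  expect_true(all(is.na(ch$stop_time)))

  scen_n <- quick_scenario(n = 4000, susc = susceptibility_spec("normal",
                                                                hr_per_unit = 2))
  chn <- generate_cohort(scen_n, seed = 12)
  expect_lt(abs(mean(chn$susceptibility)), 0.05)
  expect_gt(sd(chn$susceptibility), 0.95)
  expect_lt(sd(chn$susceptibility), 1.05)
})

test_that("fixed treated-arm sizes are honoured exactly", {
  scen <- scenario("fixed", 1000, 0.9, susceptibility_spec("none"),
                   treatment_effect_spec("constant", hr = 2),
                   censoring_rule("fixed_horizon", horizon = 5),
                   n_treated = 630)
  ch <- generate_cohort(scen, seed = 1)
  expect_identical(sum(ch$treatment), 630L)
})

test_that("susceptibility families have the designed shape", {
  expect_identical(draw_susceptibility(susceptibility_spec("none"), 10), rep(0, 10))
  b <- draw_susceptibility(susceptibility_spec("bernoulli", prevalence = 1,
                                               hr_per_unit = 2), 50, seed = 1)
  expect_true(all(b == 1))

  # closed-form lognormal skewness (e^{s2}+2) * sqrt(e^{s2}-1)
  skew <- function(sigma) (exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)
  hi <- draw_susceptibility(susceptibility_spec("lognormal_high", hr_per_unit = 4),
                            1e5, seed = 2)
  mo <- draw_susceptibility(susceptibility_spec("lognormal_moderate", hr_per_unit = 4),
                            1e5, seed = 3)
  expect_lt(abs(mean(hi)), 0.05)
  expect_lt(abs(sd(hi) - 1), 0.05)
  expect_equal(sample_skewness(mo), skew(0.5), tolerance = 0.1)
  # heavy right tail: sample skewness of the sigma = 1 family is noisier
  expect_equal(sample_skewness(hi), skew(1.0), tolerance = 0.25)
  expect_gt(sample_skewness(hi), 2 * sample_skewness(mo))
})

test_that("latent event times follow the proportional-hazards model", {
  scen <- quick_scenario(n = 2e4, surv = 0.9)
  model <- hazard_model(scen)
  ref <- structure(data.frame(subject_id = 1:2e4, treatment = 0L,
                              susceptibility = 0, age = 60, sex = 0L,
                              stop_time = NA_real_),
                   class = c("fb_cohort", "data.frame"))
  tt <- simulate_event_times_ph(ref, model, seed = 4)
  lam <- calibrate_baseline_hazard(0.9)
  expect_equal(mean(tt), 1 / lam, tolerance = 0.03)

  # proportionality: doubling the treatment HR halves the treated median
  trt <- ref; trt$treatment <- 1L
  m2 <- hazard_model(quick_scenario(n = 2e4, surv = 0.9, hr_a = 2))
  m4 <- hazard_model(quick_scenario(n = 2e4, surv = 0.9, hr_a = 4))
  t2 <- simulate_event_times_ph(trt, m2, seed = 5)
  t4 <- simulate_event_times_ph(trt, m4, seed = 5)
  expect_equal(median(t2) / median(t4), 2, tolerance = 1e-9)

  tdm <- hazard_model(replication_scenarios()[[1]])
  expect_error(simulate_event_times_ph(ref, tdm), "permutational")
})

test_that("reference-stratum survival at 5 years matches the calibration target", {
  n <- 3e4
  ref <- structure(data.frame(subject_id = 1:n, treatment = 0L,
                              susceptibility = 0, age = 60, sex = 0L,
                              stop_time = NA_real_),
                   class = c("fb_cohort", "data.frame"))
  scen <- quick_scenario(n = n, surv = 0.9, horizon = 10)
  tt <- simulate_event_times_ph(ref, hazard_model(scen), seed = 6)
  ds <- apply_administrative_censoring(ref, tt, 10)
  km <- survival::survfit(survival::Surv(exit, event) ~ 1, data = ds)
  i <- max(which(km$time <= 5))
  half_band <- 1.96 * km$std.err[i] * km$surv[i]  # Greenwood, log scale approx
  expect_lt(abs(km$surv[i] - 0.9), max(half_band, 0.01))
})

test_that("administrative censoring keeps early events and censors the rest", {
  ch <- structure(data.frame(subject_id = 1:3, treatment = c(1L, 0L, 1L),
                             susceptibility = 0, age = 60, sex = 0L,
                             stop_time = NA_real_),
                  class = c("fb_cohort", "data.frame"))
  ds <- apply_administrative_censoring(ch, c(12, 3.2, 10.0001), horizon = 10)
  expect_equal(ds$exit, c(10, 3.2, 10))
  expect_equal(ds$event, c(0L, 1L, 0L))
  expect_true(all(ds$entry == 0))
  ds0 <- apply_administrative_censoring(ch, c(11, 12, 13), horizon = 10)
  expect_identical(sum(ds0$event), 0L)
})

test_that("event-count censoring stops the trial at the k-th event", {
  ch <- structure(data.frame(subject_id = 1:4, treatment = c(1L, 0L, 1L, 0L),
                             susceptibility = 0, age = 60, sex = 0L,
                             stop_time = NA_real_),
                  class = c("fb_cohort", "data.frame"))
  ds <- apply_event_count_censoring(ch, c(1, 2, 3, 4), max_events = 2)
  expect_equal(attr(ds, "stop_time_trial"), 2)
  expect_equal(ds$event, c(1L, 1L, 0L, 0L))
  expect_equal(ds$exit, c(1, 2, 2, 2))

  ds1 <- apply_event_count_censoring(ch, c(4, 1, 3, 2), max_events = 1)
  expect_equal(ds1$event, c(0L, 1L, 0L, 0L))
  expect_equal(attr(ds1, "stop_time_trial"), 1)

  expect_warning(apply_event_count_censoring(ch, 1:4, max_events = 9),
                 "latent events")
})

test_that("adherence quotas reproduce cumulative non-adherence exactly", {
  scen <- quick_scenario(n = 4000)
  ch <- generate_cohort(scen, seed = 21)
  spec <- adherence_spec(enabled = TRUE, annual_stop_fraction = 0.06, years = 7)
  ch2 <- generate_adherence_trajectories(ch, spec, seed = 22)
  n_trt <- sum(ch2$treatment)
  stopped <- !is.na(ch2$stop_time)
  expect_identical(sum(stopped), 7L * as.integer(round(0.06 * n_trt)))
  expect_equal(sum(stopped) / n_trt, 0.42, tolerance = 0.01)
  expect_true(all(ch2$treatment[stopped] == 1L))
  expect_true(all(ch2$stop_time[stopped] <= 7))
  for (y in 1:7) {
    in_year <- sum(stopped & ch2$stop_time > y - 1 & ch2$stop_time <= y)
    expect_identical(in_year, as.integer(round(0.06 * n_trt)))
  }
  ch0 <- generate_adherence_trajectories(
    ch, adherence_spec(enabled = TRUE, annual_stop_fraction = 0, years = 7))
  expect_true(all(is.na(ch0$stop_time)))
})

test_that("identical seeds reproduce a trial byte-for-byte", {
  scen <- quick_scenario(n = 500, susc = susceptibility_spec("normal",
                                                             hr_per_unit = 3),
                         estimands = c("overall"))
  a <- simulate_trial(scen, seed = 77)
  b <- simulate_trial(scen, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_trial(scen, seed = 78)
  expect_false(identical(a$exit, c2$exit))
})

test_that("survival datasets round-trip through CSV", {
  scen <- quick_scenario(n = 120)
  ds <- simulate_trial(scen, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(ds, path)
  back <- read_survival_csv(path)
  expect_equal(back$exit, ds$exit)
  expect_equal(back$event, ds$event)
  expect_equal(back$trt, ds$trt)
  expect_error(read_survival_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "missing column")
})
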