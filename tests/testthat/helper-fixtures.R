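# Shared fixtures: tiny hand-built survival datasets and an independent
# brute-force partial-likelihood oracle used to validate the Cox fits.

# One-episode dataset from vectors of times/event flags/covariate values.
tiny_dataset <- function(time, event, x, entry = 0) {
  n <- length(time)
  structure(
    data.frame(subject_id = seq_len(n), entry = rep(entry, length.out = n),
               exit = time, event = as.integer(event), trt = x,
               trt_assigned = x, age = rep(60, n), sex = rep(0L, n),
               s = rep(0, n)),
    stop_time_trial = max(time),
    covariates = "trt",
    class = c("fb_survival_dataset", "data.frame"))
}

# Exact Cox partial log-likelihood for a single binary/continuous covariate,
# one episode per subject, no ties: enumerated risk sets, maximized by
# golden-section search. Independent of the survival package.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

oracle_cox_fit <- function(time, event, x) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  c(-15, 15), maximum = TRUE, tol = 1e-10)$maximum
}

# Small scenario builder for fast simulation tests.
quick_scenario <- function(n = 800, surv = 0.9, hr_a = 2,
                           susc = susceptibility_spec("none"),
                           horizon = 5, estimands = "overall", ...) {
  scenario(
    label = "quick", n_subjects = n, baseline_survival_5y = surv,
    susceptibility = susc,
    treatment_effect = treatment_effect_spec("constant", hr = hr_a),
    censoring = censoring_rule("fixed_horizon", horizon = horizon),
    estimand_set = estimands, ...)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
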