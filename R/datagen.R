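# Cohort and event-time generation under a constant-baseline proportional
# hazards model, plus administrative censoring. The generating hazard is
#   lambda(t | A, S, age, sex) =
#     lambda0 * exp[ bA(t) A(t) + bS S + log(1.04)(age - 60) + log(0.8) sex ]
# with all covariates mutually independent at randomization.

#' Baseline hazard from a target 5-year survival probability
#'
#' The constant baseline hazard is fixed so that exponential survival in the
#' reference stratum (untreated, S = 0, age 60, male) equals the target at 5
#' years: `lambda0 = -log(survival) / 5`.
#'
#' @param baseline_survival_5y Survival probability in (0, 1).
#' @return Baseline rate in events/year.
#' @export
calibrate_baseline_hazard <- function(baseline_survival_5y) {
  s <- as.numeric(baseline_survival_5y)
  if (length(s) != 1 || is.na(s) || s <= 0 || s >= 1) {
    stop("calibrate_baseline_hazard: survival must lie in (0, 1)")
  }
  -log(s) / 5
}

#' Draw susceptibility values
#'
#' Bernoulli draws for the binary family; standard normal for the normal
#' family; for the lognormal families, `exp(sigma * Z)` standardized by its
#' theoretical mean and SD (so the per-SD hazard ratio applies directly), with
#' log-scale SD 0.5 (moderate skew, about 1.75) or 1.0 (high skew, about 6.2).
#' The `none` family returns zeros.
#'
#' @param spec An [susceptibility_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @return Numeric vector of length `n`.
#' @export
draw_susceptibility <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "fb_susceptibility"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  switch(spec$family,
    none = numeric(n),
    bernoulli = stats::rbinom(n, 1L, spec$prevalence),
    normal = stats::rnorm(n),
    lognormal_moderate = .std_lognormal(n, sigma = 0.5),
    lognormal_high = .std_lognormal(n, sigma = 1.0),
    stop("draw_susceptibility: unknown family '", spec$family, "'")
  )
}

.std_lognormal <- function(n, sigma) {
  x <- exp(sigma * stats::rnorm(n))
  m <- exp(sigma^2 / 2)
  s <- sqrt((exp(sigma^2) - 1) * exp(sigma^2))
  (x - m) / s
}

#' Generate a randomized cohort
#'
#' Baseline covariates for `n_subjects` subjects: treatment (Bernoulli 0.5, or
#' exactly `n_treated` when the scenario fixes the arm size), sex
#' (P(female) = 0.5), age (normal mean 60, SD `age_sd`, truncated to
#' `[20, 100]` by resampling), and susceptibility per the scenario's
#' specification — all mutually independent.
#'
#' @param scen A [scenario()].
#' @param seed Optional integer seed.
#' @param age_sd Pre-truncation SD of the age distribution (years).
#' @return A data frame of class `fb_cohort` with columns `subject_id`,
#'   `treatment`, `susceptibility`, `age`, `sex`, `stop_time` (NA unless
#'   adherence trajectories have been drawn).
#' @export
generate_cohort <- function(scen, seed = NULL, age_sd = 10) {
  stopifnot(inherits(scen, "fb_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scen$n_subjects
  treatment <- if (is.null(scen$n_treated)) {
    stats::rbinom(n, 1L, 0.5)
  } else {
    trt <- integer(n)
    trt[sample.int(n, scen$n_treated)] <- 1L
    trt
  }
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, 60, age_sd)
  bad <- which(age < 20 | age > 100)
  while (length(bad)) {
    age[bad] <- stats::rnorm(length(bad), 60, age_sd)
    bad <- bad[age[bad] < 20 | age[bad] > 100]
  }
  s <- draw_susceptibility(scen$susceptibility, n)
  structure(
    data.frame(subject_id = seq_len(n), treatment = treatment,
               susceptibility = s, age = age, sex = sex,
               stop_time = NA_real_),
    class = c("fb_cohort", "data.frame"))
}

#' Generating hazard model for a scenario
#'
#' @param scen A [scenario()].
#' @return A list of class `fb_hazard_model` with the baseline rate (NULL when
#'   the scenario calibrates a marginal rate from `target_events` instead),
#'   the treatment log-HR function of time, and the fixed susceptibility, age
#'   and sex log HRs.
#' @export
hazard_model <- function(scen) {
  stopifnot(inherits(scen, "fb_scenario"))
  eff <- scen$treatment_effect
  structure(list(
    baseline_rate = if (is.null(scen$baseline_survival_5y)) NULL else
      calibrate_baseline_hazard(scen$baseline_survival_5y),
    log_hr_treatment = function(t) treatment_log_hr(eff, t),
    constant_treatment_effect = eff$kind == "constant",
    log_hr_susceptibility = log(scen$susceptibility$hr_per_unit),
    log_hr_age = if (scen$include_covariates)
      log(scen$covariate_effects$hr_age_per_year) else 0,
    log_hr_sex = if (scen$include_covariates)
      log(scen$covariate_effects$hr_female_vs_male) else 0
  ), class = "fb_hazard_model")
}

# Time-fixed part of the linear predictor (everything except treatment).
.base_linear_predictor <- function(cohort, model) {
  model$log_hr_susceptibility * cohort$susceptibility +
    model$log_hr_age * (cohort$age - 60) +
    model$log_hr_sex * cohort$sex
}

#' Simulate latent event times under proportional hazards
#'
#' For a constant treatment effect, the hazard for each subject is constant in
#' time, so the latent event time is `E / (lambda0 * exp(lp))` with `E` a unit
#' exponential draw. Time-dependent treatment effects or exposures require the
#' permutational generator ([permutational_assignment()]).
#'
#' @param cohort An `fb_cohort`.
#' @param model An [hazard_model()].
#' @param seed Optional integer seed.
#' @return Numeric vector of latent event times (years), one per subject.
#' @export
simulate_event_times_ph <- function(cohort, model, seed = NULL) {
  stopifnot(inherits(model, "fb_hazard_model"))
  if (!model$constant_treatment_effect) {
    stop("simulate_event_times_ph: treatment effect is time-dependent; ",
         "use permutational_assignment()")
  }
  if (is.null(model$baseline_rate)) {
    stop("simulate_event_times_ph: scenario has no baseline_survival_5y; ",
         "use permutational_assignment() with a calibrated marginal rate")
  }
  if (!is.null(seed)) set.seed(seed)
  lp <- .base_linear_predictor(cohort, model) +
    model$log_hr_treatment(0) * cohort$treatment
  stats::rexp(nrow(cohort)) / (model$baseline_rate * exp(lp))
}

.new_survival_dataset <- function(df, stop_time_trial) {
  df <- df[order(df$subject_id, df$entry), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, stop_time_trial = stop_time_trial,
            class = c("fb_survival_dataset", "data.frame"))
}

.cohort_episode_frame <- function(cohort, exit, event) {
  data.frame(subject_id = cohort$subject_id, entry = 0, exit = exit,
             event = as.integer(event), trt = cohort$treatment,
             trt_assigned = cohort$treatment,
             age = cohort$age, sex = cohort$sex, s = cohort$susceptibility)
}

#' Censor latent event times at a fixed horizon
#'
#' @param cohort The `fb_cohort` the times belong to.
#' @param times Latent event times from [simulate_event_times_ph()].
#' @param horizon Administrative censoring time (years).
#' @return An `fb_survival_dataset`: counting-process episodes
#'   `(subject_id, entry, exit, event, trt, trt_assigned, age, sex, s)` with
#'   half-open risk intervals `(entry, exit]`, one episode per subject.
#' @export
apply_administrative_censoring <- function(cohort, times, horizon) {
  stopifnot(horizon > 0, length(times) == nrow(cohort))
  event <- times <= horizon
  .new_survival_dataset(
    .cohort_episode_frame(cohort, pmin(times, horizon), event), horizon)
}

#' Censor latent event times at an event-count trial stop
#'
#' The trial stops at the time of the `max_events`-th earliest event (latent
#' ties broken by subject id); subjects with later latent times are censored
#' at the stop time. When fewer than `max_events` latent events exist, all of
#' them are kept and a warning is issued.
#'
#' @param cohort The `fb_cohort` the times belong to.
#' @param times Latent event times.
#' @param max_events Event count triggering the stop.
#' @return An `fb_survival_dataset` (see [apply_administrative_censoring()]).
#' @export
apply_event_count_censoring <- function(cohort, times, max_events) {
  stopifnot(max_events >= 1, length(times) == nrow(cohort))
  n <- length(times)
  if (n < max_events) {
    warning("apply_event_count_censoring: only ", n, " latent events < ",
            max_events, "; keeping all")
    max_events <- n
  }
  ord <- order(times, cohort$subject_id)
  tau <- times[ord[max_events]]
  is_event <- logical(n)
  is_event[ord[seq_len(max_events)]] <- TRUE
  .new_survival_dataset(
    .cohort_episode_frame(cohort, ifelse(is_event, times, tau), is_event), tau)
}

#' Draw annual treatment-cessation trajectories
#'
#' Deterministic per-year quota model of non-adherence: in each trial year a
#' fraction `annual_stop_fraction` of the *initially treated* arm (rounded to
#' a whole count) is sampled without replacement and assigned a cessation time
#' uniform within that year. With 6% per year over 7 years this yields exactly
#' the 42% cumulative non-adherence it is meant to emulate. Untreated subjects
#' never receive a stop time.
#'
#' @param cohort An `fb_cohort`.
#' @param spec An [adherence_spec()] with `enabled = TRUE`.
#' @param horizon Number of years over which cessation occurs (defaults to
#'   `spec$years`).
#' @param seed Optional integer seed.
#' @return The cohort with `stop_time` filled in for ceasing subjects.
#' @export
generate_adherence_trajectories <- function(cohort, spec,
                                            horizon = spec$years, seed = NULL) {
  stopifnot(inherits(spec, "fb_adherence"))
  if (!spec$enabled) stop("generate_adherence_trajectories: spec not enabled")
  if (!is.null(seed)) set.seed(seed)
  treated <- which(cohort$treatment == 1L)
  n_trt <- length(treated)
  per_year <- round(spec$annual_stop_fraction * n_trt)
  n_years <- floor(horizon)
  if (per_year * n_years > n_trt) {
    stop("generate_adherence_trajectories: cumulative stop fraction exceeds 1 ",
         "before the horizon")
  }
  remaining <- treated
  for (y in seq_len(n_years)) {
    if (per_year == 0) break
    pick <- remaining[sample.int(length(remaining), per_year)]
    cohort$stop_time[pick] <- (y - 1) + stats::runif(per_year)
    remaining <- setdiff(remaining, pick)
  }
  cohort
}

#' Export / import survival datasets as CSV
#'
#' Columns `(id, entry, exit, event, trt, age, sex, s)` with the half-open
#' interval convention `(entry, exit]`.
#'
#' @param data An `fb_survival_dataset`.
#' @param path CSV file path.
#' @return `read_survival_csv()` returns an `fb_survival_dataset`.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "fb_survival_dataset"))
  out <- data.frame(id = data$subject_id, entry = data$entry, exit = data$exit,
                    event = data$event, trt = data$trt,
                    age = data$age, sex = data$sex, s = data$s)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("id", "entry", "exit", "event", "trt")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("read_survival_csv: missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(subject_id = x$id, entry = x$entry, exit = x$exit,
                   event = as.integer(x$event), trt = x$trt,
                   trt_assigned = if (is.null(x$trt_assigned)) x$trt else x$trt_assigned,
                   age = if (is.null(x$age)) 60 else x$age,
                   sex = if (is.null(x$sex)) 0L else x$sex,
                   s = if (is.null(x$s)) 0 else x$s)
  .new_survival_dataset(df, max(df$exit))
}
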