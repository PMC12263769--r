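# Scenario definitions: validated descriptions of one simulated trial design.
# A scenario bundles the generative model (sample size, baseline survival,
# susceptibility distribution and effect, treatment effect, censoring,
# adherence) with the estimands to compute on each simulated sample.

#' Susceptibility specification
#'
#' Describes the distribution of the unmeasured susceptibility (frailty) `S`
#' and its multiplicative effect on the hazard. `S` is generated independently
#' of treatment and of the measured covariates.
#'
#' @param family One of `"none"`, `"bernoulli"`, `"normal"`,
#'   `"lognormal_moderate"`, `"lognormal_high"`. The two lognormal families
#'   are standardized to mean 0 and SD 1 and differ in skewness
#'   (log-scale SD 0.5 vs 1.0).
#' @param prevalence `P(S = 1)`, required iff `family = "bernoulli"`.
#' @param hr_per_unit Hazard ratio per unit of `S`: `S = 1` vs `0` for the
#'   bernoulli family, per 1 SD for the (standardized) continuous families.
#' @return An object of class `fb_susceptibility`.
#' @export
susceptibility_spec <- function(family = c("none", "bernoulli", "normal",
                                           "lognormal_moderate", "lognormal_high"),
                                prevalence = NULL, hr_per_unit = 1) {
  family <- match.arg(family)
  if (family == "bernoulli") {
    if (is.null(prevalence)) {
      stop("susceptibility_spec: 'prevalence' is required when family = \"bernoulli\"")
    }
    prevalence <- as.numeric(prevalence)
    if (length(prevalence) != 1 || is.na(prevalence) || prevalence < 0 || prevalence > 1) {
      stop("susceptibility_spec: 'prevalence' must be a probability in [0, 1]")
    }
  } else if (!is.null(prevalence)) {
    stop("susceptibility_spec: 'prevalence' is only meaningful for family = \"bernoulli\"")
  }
  hr_per_unit <- as.numeric(hr_per_unit)
  if (length(hr_per_unit) != 1 || is.na(hr_per_unit) || hr_per_unit <= 0) {
    stop("susceptibility_spec: 'hr_per_unit' must be a positive number")
  }
  if (family == "none" && hr_per_unit != 1) {
    stop("susceptibility_spec: family = \"none\" forces hr_per_unit = 1")
  }
  structure(list(family = family, prevalence = prevalence,
                 hr_per_unit = hr_per_unit),
            class = "fb_susceptibility")
}

#' Treatment-effect specification
#'
#' The true treatment effect on the log-hazard scale, either constant over
#' follow-up or a piecewise-linear function of time interpolated between
#' anchors (constant extrapolation beyond the first/last anchor).
#'
#' @param kind `"constant"` or `"piecewise_linear_log_hr"`.
#' @param hr Constant hazard ratio (constant kind).
#' @param anchors Data frame with columns `time` (years, strictly increasing)
#'   and `log_hr` (piecewise kind).
#' @return An object of class `fb_treatment_effect`.
#' @export
treatment_effect_spec <- function(kind = c("constant", "piecewise_linear_log_hr"),
                                  hr = NULL, anchors = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(hr)) stop("treatment_effect_spec: 'hr' is required for kind = \"constant\"")
    hr <- as.numeric(hr)
    if (length(hr) != 1 || is.na(hr) || hr <= 0) {
      stop("treatment_effect_spec: 'hr' must be a positive number")
    }
    anchors <- NULL
  } else {
    if (is.null(anchors)) {
      stop("treatment_effect_spec: 'anchors' is required for kind = \"piecewise_linear_log_hr\"")
    }
    anchors <- as.data.frame(anchors)
    if (!all(c("time", "log_hr") %in% names(anchors))) {
      stop("treatment_effect_spec: 'anchors' needs columns 'time' and 'log_hr'")
    }
    anchors <- data.frame(time = as.numeric(anchors$time),
                          log_hr = as.numeric(anchors$log_hr))
    if (nrow(anchors) < 1 || any(is.na(anchors)) ||
        any(diff(anchors$time) <= 0) || any(anchors$time < 0)) {
      stop("treatment_effect_spec: 'anchors' times must be non-negative and strictly increasing")
    }
    hr <- NULL
  }
  structure(list(kind = kind, hr = hr, anchors = anchors),
            class = "fb_treatment_effect")
}

#' Evaluate the true treatment log hazard ratio at given times
#'
#' @param effect An `fb_treatment_effect`.
#' @param t Vector of times (years, `t >= 0`).
#' @return Numeric vector of true log HR values.
#' @export
treatment_log_hr <- function(effect, t) {
  stopifnot(inherits(effect, "fb_treatment_effect"))
  if (effect$kind == "constant") {
    return(rep(log(effect$hr), length(t)))
  }
  a <- effect$anchors
  if (nrow(a) == 1) return(rep(a$log_hr, length(t)))
  stats::approx(a$time, a$log_hr, xout = pmin(pmax(t, a$time[1]), a$time[nrow(a)]),
                rule = 2)$y
}

#' Censoring rule
#'
#' Administrative censoring either at a fixed horizon or when the cumulative
#' number of observed events reaches `max_events` (event-driven trial stop).
#'
#' @param kind `"fixed_horizon"` or `"event_count"`.
#' @param horizon Trial horizon in years (fixed-horizon kind).
#' @param max_events Positive integer event count triggering the stop.
#' @param expected_duration For the event-count kind only: the nominal trial
#'   duration (years) used to calibrate the marginal event rate when data are
#'   generated with the permutational algorithm. Default 7 years.
#' @return An object of class `fb_censoring`.
#' @export
censoring_rule <- function(kind = c("fixed_horizon", "event_count"),
                           horizon = NULL, max_events = NULL,
                           expected_duration = 7) {
  kind <- match.arg(kind)
  if (kind == "fixed_horizon") {
    if (is.null(horizon)) stop("censoring_rule: 'horizon' is required for kind = \"fixed_horizon\"")
    if (!is.null(max_events)) stop("censoring_rule: exactly one of 'horizon'/'max_events' may be set")
    horizon <- as.numeric(horizon)
    if (length(horizon) != 1 || is.na(horizon) || horizon <= 0) {
      stop("censoring_rule: 'horizon' must be a positive number of years")
    }
    max_events <- NULL
    expected_duration <- NULL
  } else {
    if (is.null(max_events)) stop("censoring_rule: 'max_events' is required for kind = \"event_count\"")
    if (!is.null(horizon)) stop("censoring_rule: exactly one of 'horizon'/'max_events' may be set")
    max_events <- as.integer(max_events)
    if (length(max_events) != 1 || is.na(max_events) || max_events < 1) {
      stop("censoring_rule: 'max_events' must be a positive integer")
    }
    horizon <- NULL
    expected_duration <- as.numeric(expected_duration)
  }
  structure(list(kind = kind, horizon = horizon, max_events = max_events,
                 expected_duration = expected_duration),
            class = "fb_censoring")
}

#' Adherence specification
#'
#' Non-adherence model for the initially treated arm: each trial year, a fixed
#' fraction of the arm stops treatment (cessation time uniform within the
#' year), so cumulative non-adherence after `years` years equals
#' `years * annual_stop_fraction`.
#'
#' @param enabled Logical flag.
#' @param annual_stop_fraction Fraction of the initially treated arm stopping
#'   per year.
#' @param years Number of trial years over which cessation occurs (default 7).
#' @return An object of class `fb_adherence`.
#' @export
adherence_spec <- function(enabled = FALSE, annual_stop_fraction = 0, years = 7) {
  annual_stop_fraction <- as.numeric(annual_stop_fraction)
  if (length(annual_stop_fraction) != 1 || is.na(annual_stop_fraction) ||
      annual_stop_fraction < 0 || annual_stop_fraction > 1) {
    stop("adherence_spec: 'annual_stop_fraction' must be a probability")
  }
  years <- as.numeric(years)
  if (enabled && annual_stop_fraction * years > 1) {
    stop("adherence_spec: cumulative stop fraction exceeds 1 before 'years'")
  }
  structure(list(enabled = isTRUE(enabled),
                 annual_stop_fraction = annual_stop_fraction,
                 years = years),
            class = "fb_adherence")
}

fb_estimands <- c("overall", "year_specific", "last_period", "td_spline")

#' Simulation scenario
#'
#' A complete, validated description of one simulated trial design: generative
#' parameters plus the estimands to compute on each replicate.
#'
#' @param label Scenario label (unique within a registry).
#' @param n_subjects Number of randomized subjects `N`.
#' @param baseline_survival_5y Survival probability at 5 years in the
#'   reference stratum (untreated, `S = 0`, age 60, male); determines the
#'   constant baseline hazard. May be `NULL` for scenarios whose marginal
#'   event rate is calibrated from `target_events` instead.
#' @param susceptibility An [susceptibility_spec()].
#' @param treatment_effect A [treatment_effect_spec()].
#' @param censoring A [censoring_rule()].
#' @param adherence An [adherence_spec()].
#' @param estimand_set Subset of `c("overall", "year_specific", "last_period",
#'   "td_spline")`.
#' @param n_treated Exact size of the treated arm; `NULL` (default) assigns
#'   treatment by independent Bernoulli(0.5) draws.
#' @param include_covariates If `TRUE` (default) age and sex enter the
#'   generating hazard (HR 1.04 per year, HR 0.8 female vs male) and are
#'   adjusted for in all fitted models. The replication series sets this to
#'   `FALSE` (hazard depends only on exposure and susceptibility).
#' @param followup_range Optional length-2 vector: per-subject administrative
#'   censoring times drawn uniformly on this range (staggered entry).
#' @param target_events Optional expected event yield used to calibrate the
#'   marginal event rate of the permutational generator.
#' @return An object of class `fb_scenario`.
#' @export
scenario <- function(label, n_subjects, baseline_survival_5y,
                     susceptibility, treatment_effect, censoring,
                     adherence = adherence_spec(),
                     estimand_set = "overall",
                     n_treated = NULL,
                     include_covariates = TRUE,
                     followup_range = NULL,
                     target_events = NULL) {
  label <- as.character(label)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2) {
    stop("scenario: 'n_subjects' must be an integer >= 2")
  }
  if (!is.null(baseline_survival_5y)) {
    baseline_survival_5y <- as.numeric(baseline_survival_5y)
    if (is.na(baseline_survival_5y) || baseline_survival_5y <= 0 ||
        baseline_survival_5y >= 1) {
      stop("scenario: 'baseline_survival_5y' must lie in (0, 1)")
    }
  }
  if (!inherits(susceptibility, "fb_susceptibility")) {
    stop("scenario: 'susceptibility' must be a susceptibility_spec()")
  }
  if (!inherits(treatment_effect, "fb_treatment_effect")) {
    stop("scenario: 'treatment_effect' must be a treatment_effect_spec()")
  }
  if (!inherits(censoring, "fb_censoring")) {
    stop("scenario: 'censoring' must be a censoring_rule()")
  }
  if (!inherits(adherence, "fb_adherence")) {
    stop("scenario: 'adherence' must be an adherence_spec()")
  }
  bad <- setdiff(estimand_set, fb_estimands)
  if (length(bad)) {
    stop("scenario: unknown estimand(s) in 'estimand_set': ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(n_treated)) {
    n_treated <- as.integer(n_treated)
    if (is.na(n_treated) || n_treated < 1 || n_treated >= n_subjects) {
      stop("scenario: 'n_treated' must be an integer in [1, n_subjects)")
    }
  }
  if (!is.null(followup_range)) {
    followup_range <- as.numeric(followup_range)
    if (length(followup_range) != 2 || any(is.na(followup_range)) ||
        followup_range[1] <= 0 || followup_range[2] < followup_range[1]) {
      stop("scenario: 'followup_range' must be an increasing positive pair")
    }
  }
  if (!is.null(target_events)) target_events <- as.integer(target_events)
  structure(list(
    label = label,
    n_subjects = n_subjects,
    n_treated = n_treated,
    baseline_survival_5y = baseline_survival_5y,
    susceptibility = susceptibility,
    treatment_effect = treatment_effect,
    censoring = censoring,
    adherence = adherence,
    covariate_effects = list(hr_age_per_year = 1.04, hr_female_vs_male = 0.8),
    include_covariates = isTRUE(include_covariates),
    followup_range = followup_range,
    target_events = target_events,
    estimand_set = as.character(estimand_set)
  ), class = "fb_scenario")
}

#' @export
print.fb_scenario <- function(x, ...) {
  cat("<fb_scenario>", x$label, "\n")
  cat("  N =", x$n_subjects,
      if (!is.null(x$n_treated)) paste0("(", x$n_treated, " treated)") else "",
      "\n")
  if (!is.null(x$baseline_survival_5y)) {
    cat("  baseline 5-year survival:", x$baseline_survival_5y, "\n")
  }
  s <- x$susceptibility
  cat("  susceptibility:", s$family,
      if (s$family == "bernoulli") paste0("P(S=1)=", s$prevalence) else "",
      if (s$family != "none") paste0("HR(S)=", s$hr_per_unit) else "", "\n")
  te <- x$treatment_effect
  if (te$kind == "constant") {
    cat("  treatment effect: constant HR", te$hr, "\n")
  } else {
    cat("  treatment effect: piecewise-linear log HR,",
        nrow(te$anchors), "anchors\n")
  }
  cz <- x$censoring
  if (cz$kind == "fixed_horizon") {
    cat("  censoring: fixed horizon", cz$horizon, "years\n")
  } else {
    cat("  censoring: stop at", cz$max_events, "events\n")
  }
  if (x$adherence$enabled) {
    cat("  adherence:", x$adherence$annual_stop_fraction * 100,
        "% of treated arm stop per year\n")
  }
  cat("  estimands:", paste(x$estimand_set, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Built-in registries

# scenario, N, surv5, P(S=1), HR(S), HR(A)
.table1_params <- matrix(c(
  1, 4000, 0.90, 0.500, 2, 2.0,
  2, 4000, 0.90, 0.500, 3, 2.0,
  3, 4000, 0.90, 0.500, 4, 2.0,
  4, 4000, 0.90, 0.500, 5, 2.0,
  5, 4000, 0.90, 0.500, 10, 2.0,
  6, 4000, 0.90, 0.500, 15, 2.0,
  7, 4000, 0.90, 0.500, 20, 2.0,
  8, 4000, 0.90, 0.500, 25, 2.0,
  9, 16000, 0.90, 0.500, 25, 2.0,
  10, 4000, 0.90, 0.500, 10, 1.3,
  11, 4000, 0.90, 0.500, 10, 1.5,
  12, 4000, 0.90, 0.500, 10, 4.0,
  13, 4000, 0.90, 0.500, 10, 6.0,
  14, 4000, 0.90, 0.250, 10, 2.0,
  15, 4000, 0.90, 0.100, 10, 2.0,
  16, 4000, 0.90, 0.025, 10, 2.0,
  17, 4000, 0.97, 0.500, 10, 2.0,
  18, 4000, 0.97, 0.250, 10, 2.0,
  19, 4000, 0.97, 0.100, 10, 2.0,
  20, 4000, 0.97, 0.025, 10, 2.0,
  21, 4000, 0.70, 0.500, 10, 2.0,
  22, 4000, 0.70, 0.250, 10, 2.0,
  23, 4000, 0.70, 0.100, 10, 2.0,
  24, 4000, 0.70, 0.025, 10, 2.0,
  25, 4000, 0.99, 0.500, 10, 2.0,
  26, 4000, 0.99, 0.250, 10, 2.0
), ncol = 6, byrow = TRUE,
dimnames = list(NULL, c("scenario", "n", "surv", "prev", "hr_s", "hr_a")))

# scenario, N, surv5, HR(S) per SD, HR(A)
.table2_params <- matrix(c(
  27, 4000, 0.70, 3.0, 2.0,
  28, 4000, 0.70, 2.5, 2.0,
  29, 4000, 0.70, 2.0, 2.0,
  30, 4000, 0.70, 1.5, 2.0,
  31, 4000, 0.70, 1.2, 2.0,
  32, 4000, 0.90, 3.0, 2.0,
  33, 4000, 0.90, 2.5, 2.0,
  34, 4000, 0.90, 2.0, 2.0,
  35, 4000, 0.97, 3.0, 2.0,
  36, 4000, 0.97, 2.5, 2.0,
  37, 4000, 0.97, 2.0, 2.0,
  38, 4000, 0.70, 3.0, 1.5,
  39, 4000, 0.70, 2.5, 1.5,
  40, 4000, 0.70, 2.0, 1.5,
  41, 4000, 0.70, 3.0, 1.3,
  42, 4000, 0.70, 2.5, 1.3,
  43, 4000, 0.70, 2.0, 1.3
), ncol = 5, byrow = TRUE,
dimnames = list(NULL, c("scenario", "n", "surv", "hr_s", "hr_a")))

#' Binary-susceptibility scenario grid
#'
#' The 26 built-in scenarios crossing sample size, baseline survival,
#' susceptibility prevalence, susceptibility effect and treatment effect for
#' a binary unmeasured susceptibility, with 10-year administrative censoring.
#'
#' @return List of 26 [scenario()] objects labelled `"1"`..`"26"`.
#' @export
table1_scenarios <- function() {
  apply(.table1_params, 1, function(p) {
    scenario(
      label = as.character(as.integer(p["scenario"])),
      n_subjects = p["n"],
      baseline_survival_5y = p["surv"],
      susceptibility = susceptibility_spec("bernoulli", prevalence = p["prev"],
                                           hr_per_unit = p["hr_s"]),
      treatment_effect = treatment_effect_spec("constant", hr = p["hr_a"]),
      censoring = censoring_rule("fixed_horizon", horizon = 10),
      estimand_set = c("overall", "year_specific")
    )
  })
}

#' Continuous-susceptibility scenario grid
#'
#' The 17 built-in scenarios (labels 27-43) with a standard-normal unmeasured
#' susceptibility acting linearly on the log hazard, 10-year administrative
#' censoring.
#'
#' @return List of 17 [scenario()] objects.
#' @export
table2_scenarios <- function() {
  apply(.table2_params, 1, function(p) {
    scenario(
      label = as.character(as.integer(p["scenario"])),
      n_subjects = p["n"],
      baseline_survival_5y = p["surv"],
      susceptibility = susceptibility_spec("normal", hr_per_unit = p["hr_s"]),
      treatment_effect = treatment_effect_spec("constant", hr = p["hr_a"]),
      censoring = censoring_rule("fixed_horizon", horizon = 10),
      estimand_set = c("overall", "year_specific")
    )
  })
}

#' Trial-mimicking (targeted) scenario grid
#'
#' Scenarios designed to mimic a large hormone-therapy trial: N = 16,600,
#' constant true treatment HR 1.81, reference-stratum 5-year survival 0.999,
#' trial stop once 335 events have occurred. The susceptibility grids cover a
#' very strong binary frailty (HR 25) at several prevalences (prevalence 0
#' meaning no frailty at all) and three standardized continuous families
#' (normal, moderately and highly skewed lognormal) over a grid of per-SD
#' hazard ratios.
#'
#' @param prevalences Prevalence grid for the binary family (0 allowed).
#' @param hr_grid Per-SD hazard-ratio grid for the continuous families.
#' @return List of [scenario()] objects.
#' @export
targeted_scenarios <- function(prevalences = c(0, 0.05, 0.1, 0.25, 0.5),
                               hr_grid = c(2, 2.5, 3, 4)) {
  base <- function(label, susc) {
    scenario(
      label = label, n_subjects = 16600, baseline_survival_5y = 0.999,
      susceptibility = susc,
      treatment_effect = treatment_effect_spec("constant", hr = 1.81),
      censoring = censoring_rule("event_count", max_events = 335,
                                 expected_duration = 7),
      estimand_set = c("overall", "last_period", "td_spline")
    )
  }
  out <- list()
  for (p in prevalences) {
    susc <- if (p == 0) susceptibility_spec("none") else
      susceptibility_spec("bernoulli", prevalence = p, hr_per_unit = 25)
    out[[length(out) + 1L]] <- base(sprintf("targeted_binary_p%g", p), susc)
  }
  for (fam in c("normal", "lognormal_moderate", "lognormal_high")) {
    for (h in hr_grid) {
      out[[length(out) + 1L]] <-
        base(sprintf("targeted_%s_hr%g", fam, h),
             susceptibility_spec(fam, hr_per_unit = h))
    }
  }
  out
}

#' Trial-mimicking scenario with annual treatment cessation
#'
#' The non-adherence variant of the targeted design: no unmeasured
#' susceptibility, but 6% of the initially treated arm stop treatment in each
#' trial year (42% cumulative by year 7). Event times conditional on the
#' time-dependent exposure must be generated with the permutational algorithm
#' ([permutational_assignment()]); [simulate_trial()] does this automatically.
#'
#' @param annual_stop_fraction Fraction of the treated arm stopping per year.
#' @return A [scenario()] object.
#' @export
nonadherence_scenario <- function(annual_stop_fraction = 0.06) {
  scenario(
    label = "targeted_nonadherence",
    n_subjects = 16600, baseline_survival_5y = 0.999,
    susceptibility = susceptibility_spec("none"),
    treatment_effect = treatment_effect_spec("constant", hr = 1.81),
    censoring = censoring_rule("event_count", max_events = 335,
                               expected_duration = 7),
    adherence = adherence_spec(enabled = TRUE,
                               annual_stop_fraction = annual_stop_fraction,
                               years = 7),
    estimand_set = c("overall", "td_spline")
  )
}

#' Replication scenario series based on published time-dependent effects
#'
#' Six scenarios forming two series that mimic published studies with
#' clinically plausible time-dependent exposure effects. The kidney-transplant
#' series uses N = 41,146 dialysis patients (23,275 transplanted), about 4,340
#' deaths over 1.5 years, and a true log HR declining piecewise-linearly from
#' log(2.84) at one month through 0 at 3.5 months to log(0.32) at 12 months
#' (constant after). The aspirin series uses N = 1,860 (940 on aspirin), about
#' 520 events over up to 4 years with staggered per-subject follow-up, and a
#' true log HR rising from log(0.5) at baseline to 0 at 1 year. Each series
#' has three variants: true TD effect without susceptibility, true TD effect
#' plus a strong binary susceptibility (HR 10, prevalence 0.5), and a constant
#' effect (the first-month HR) plus the same susceptibility. The hazard
#' depends only on exposure (and susceptibility); age and sex are omitted.
#'
#' @return List of 6 [scenario()] objects labelled `kidney_1..3`,
#'   `aspirin_1..3`.
#' @export
replication_scenarios <- function() {
  strong_s <- susceptibility_spec("bernoulli", prevalence = 0.5, hr_per_unit = 10)
  no_s <- susceptibility_spec("none")
  kidney_td <- treatment_effect_spec(
    "piecewise_linear_log_hr",
    anchors = data.frame(time = c(1 / 12, 3.5 / 12, 1),
                         log_hr = c(log(2.84), 0, log(0.32))))
  aspirin_td <- treatment_effect_spec(
    "piecewise_linear_log_hr",
    anchors = data.frame(time = c(0, 1), log_hr = c(log(0.5), 0)))
  kidney <- function(label, susc, eff) {
    scenario(label = label, n_subjects = 41146, n_treated = 23275,
             baseline_survival_5y = NULL,
             susceptibility = susc, treatment_effect = eff,
             censoring = censoring_rule("fixed_horizon", horizon = 1.5),
             include_covariates = FALSE, target_events = 4340,
             estimand_set = "td_spline")
  }
  aspirin <- function(label, susc, eff) {
    scenario(label = label, n_subjects = 1860, n_treated = 940,
             baseline_survival_5y = NULL,
             susceptibility = susc, treatment_effect = eff,
             censoring = censoring_rule("fixed_horizon", horizon = 4),
             include_covariates = FALSE, target_events = 520,
             followup_range = c(0.5, 4),
             estimand_set = "td_spline")
  }
  list(
    kidney(("kidney_1"), no_s, kidney_td),
    kidney(("kidney_2"), strong_s, kidney_td),
    kidney(("kidney_3"), strong_s, treatment_effect_spec("constant", hr = 2.84)),
    aspirin("aspirin_1", no_s, aspirin_td),
    aspirin("aspirin_2", strong_s, aspirin_td),
    aspirin("aspirin_3", strong_s, treatment_effect_spec("constant", hr = 0.5))
  )
}

# ---------------------------------------------------------------------------
# Serialization

scenario_to_list <- function(s) {
  stopifnot(inherits(s, "fb_scenario"))
  te <- s$treatment_effect
  list(
    label = s$label,
    n_subjects = s$n_subjects,
    n_treated = s$n_treated,
    baseline_survival_5y = s$baseline_survival_5y,
    susceptibility = list(family = s$susceptibility$family,
                          prevalence = s$susceptibility$prevalence,
                          hr_per_unit = s$susceptibility$hr_per_unit),
    treatment_effect = list(kind = te$kind, hr = te$hr,
                            anchor_times = te$anchors$time,
                            anchor_log_hrs = te$anchors$log_hr),
    censoring = list(kind = s$censoring$kind, horizon = s$censoring$horizon,
                     max_events = s$censoring$max_events,
                     expected_duration = s$censoring$expected_duration),
    adherence = list(enabled = s$adherence$enabled,
                     annual_stop_fraction = s$adherence$annual_stop_fraction,
                     years = s$adherence$years),
    include_covariates = s$include_covariates,
    followup_range = s$followup_range,
    target_events = s$target_events,
    estimand_set = s$estimand_set
  )
}

list_to_scenario <- function(x) {
  req <- function(field) {
    if (is.null(x[[field]])) stop("scenario file: missing field '", field, "'")
    x[[field]]
  }
  susc <- req("susceptibility")
  te <- req("treatment_effect")
  cz <- req("censoring")
  ad <- x$adherence
  anchors <- NULL
  if (!is.null(te$anchor_times)) {
    anchors <- data.frame(time = unlist(te$anchor_times),
                          log_hr = unlist(te$anchor_log_hrs))
  }
  scenario(
    label = req("label"),
    n_subjects = req("n_subjects"),
    n_treated = x$n_treated,
    baseline_survival_5y = x$baseline_survival_5y,
    susceptibility = susceptibility_spec(susc$family,
                                         prevalence = susc$prevalence,
                                         hr_per_unit = susc$hr_per_unit),
    treatment_effect = treatment_effect_spec(te$kind, hr = te$hr,
                                             anchors = anchors),
    censoring = censoring_rule(cz$kind, horizon = cz$horizon,
                               max_events = cz$max_events,
                               expected_duration =
                                 if (is.null(cz$expected_duration)) 7
                                 else cz$expected_duration),
    adherence = if (is.null(ad)) adherence_spec() else
      adherence_spec(enabled = isTRUE(ad$enabled),
                     annual_stop_fraction = ad$annual_stop_fraction,
                     years = if (is.null(ad$years)) 7 else ad$years),
    include_covariates = if (is.null(x$include_covariates)) TRUE
                         else isTRUE(x$include_covariates),
    followup_range = if (is.null(x$followup_range)) NULL
                     else unlist(x$followup_range),
    target_events = x$target_events,
    estimand_set = unlist(req("estimand_set"))
  )
}

#' Save / load scenario lists
#'
#' Scenarios are stored as a versioned JSON or YAML document (format chosen
#' by file extension). `load_scenarios()` validates every entry through the
#' scenario constructors, so malformed files fail with a message naming the
#' offending field; a save/load round trip is the identity.
#'
#' @param scenarios List of [scenario()] objects (or a single scenario).
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `load_scenarios()` returns a list of scenarios;
#'   `save_scenarios()` returns `path` invisibly.
#' @export
save_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "fb_scenario")) scenarios <- list(scenarios)
  doc <- list(schema = "frailtybias/scenarios", version = 1L,
              scenarios = lapply(scenarios, scenario_to_list))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    stop("save_scenarios: unsupported extension '", ext,
         "' (use .json, .yaml or .yml)")
  }
  invisible(path)
}

#' @rdname save_scenarios
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) stop("load_scenarios: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("load_scenarios: unsupported extension '", ext, "'")
  }
  if (is.null(doc$schema) || doc$schema != "frailtybias/scenarios") {
    stop("load_scenarios: not a frailtybias scenario file (missing schema tag)")
  }
  lapply(doc$scenarios, list_to_scenario)
}
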