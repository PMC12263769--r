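# Estimators: overall Cox PH (adjusting for age and sex, never for the
# susceptibility), year-specific Cox models, last-period Cox, and the
# quadratic-spline time-dependent-coefficient Cox model with its
# likelihood-ratio test of proportional hazards. All partial-likelihood
# maximization is delegated to survival::coxph (Efron tie handling).

.fit_covariates <- function(data, covariates) {
  if (is.null(covariates)) covariates <- attr(data, "covariates")
  if (is.null(covariates)) {
    covariates <- c("trt", if (!is.null(data$age) && length(unique(data$age)) > 1)
      c("age", "sex"))
  }
  covariates[covariates %in% names(data)]
}

.coxfit <- function(log_hr, se, loglik, n_at_risk, n_events, converged,
                    coefficients = NULL, vcov = NULL) {
  structure(list(log_hr = log_hr, se = se,
                 ci95 = c(log_hr - 1.96 * se, log_hr + 1.96 * se),
                 loglik = loglik, n_at_risk = n_at_risk, n_events = n_events,
                 converged = converged, coefficients = coefficients,
                 vcov = vcov),
            class = "fb_coxfit")
}

#' @export
print.fb_coxfit <- function(x, ...) {
  cat("<fb_coxfit> log HR =", format(x$log_hr, digits = 4),
      " SE =", format(x$se, digits = 4),
      " 95% CI [", format(x$ci95[1], digits = 4), ",",
      format(x$ci95[2], digits = 4), "]\n")
  cat("  events:", x$n_events, "/", x$n_at_risk, "subjects; converged:",
      x$converged, "\n")
  invisible(x)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron ties) on counting-process
#' episodes. The reported `log_hr` / `se` / `ci95` are for the treatment
#' covariate; the fit deliberately never adjusts for the susceptibility.
#' A treatment column without contrast yields a log HR of 0 with infinite
#' variance and `converged = FALSE` rather than an error.
#'
#' @param data An `fb_survival_dataset` (or data frame with columns `entry`,
#'   `exit`, `event`, plus covariates).
#' @param covariates Covariate columns to include; default is treatment plus
#'   age and sex when present with variation. The first element is treated as
#'   the exposure of interest.
#' @param treatment_var Name of the treatment column (`"trt"` = current
#'   treatment; `"trt_assigned"` = as randomized).
#' @return An `fb_coxfit`: treatment `log_hr`, `se`, Wald `ci95` on the log
#'   scale, maximized partial log-likelihood, subject and event counts, a
#'   convergence flag and the full coefficient vector.
#' @export
fit_cox_ph <- function(data, covariates = NULL, treatment_var = "trt") {
  n_events <- sum(data$event)
  if (n_events < 1) stop("fit_cox_ph: no events in dataset")
  covariates <- .fit_covariates(data, covariates)
  covariates[covariates == "trt"] <- treatment_var
  if (length(unique(data[[treatment_var]])) < 2) {
    return(.coxfit(0, Inf, NA_real_, length(unique(data$subject_id)),
                   n_events, FALSE))
  }
  f <- stats::as.formula(paste("survival::Surv(entry, exit, event) ~",
                               paste(covariates, collapse = " + ")))
  # timefix = FALSE: times are exact doubles from the generator; the default
  # tie-rounding can collapse the very short intervals a strong frailty makes
  fit <- survival::coxph(f, data = data, ties = "efron",
                         control = survival::coxph.control(timefix = FALSE))
  conv <- !any(is.na(stats::coef(fit))) &&
    fit$iter < survival::coxph.control()$iter.max
  .coxfit(unname(stats::coef(fit)[treatment_var]),
          sqrt(diag(fit$var))[match(treatment_var, names(stats::coef(fit)))],
          fit$loglik[2], length(unique(data$subject_id)), n_events, conv,
          coefficients = stats::coef(fit), vcov = fit$var)
}

#' Year-specific Cox fit
#'
#' Fits the treatment effect within a single year of follow-up: the risk set
#' contains subjects event-free and uncensored at the year's start (left
#' truncation at `year - 1` on the original time scale); events are those in
#' `(year - 1, year]`; all other at-risk subjects are censored at the year's
#' end.
#'
#' @inheritParams fit_cox_ph
#' @param year Trial year `t >= 1` (the window `(t-1, t]`).
#' @return An `fb_coxfit`. When the year contains no events the estimate is
#'   `NA` with `n_events = 0` (to be dropped from aggregation).
#' @export
fit_year_specific_cox <- function(data, year, covariates = NULL,
                                  treatment_var = "trt") {
  stopifnot(year >= 1)
  covariates <- .fit_covariates(data, covariates)
  t0 <- year - 1
  t1 <- year
  keep <- data$exit > t0 & data$entry < t1
  w <- data[keep, , drop = FALSE]
  if (nrow(w) == 0 || sum(w$event == 1 & w$exit <= t1) == 0) {
    return(.coxfit(NA_real_, NA_real_, NA_real_,
                   length(unique(w$subject_id)), 0L, FALSE))
  }
  w$event <- as.integer(w$event == 1 & w$exit <= t1)
  w$entry <- pmax(w$entry, t0)
  w$exit <- pmin(w$exit, t1)
  fit_cox_ph(w, covariates, treatment_var)
}

#' Last-period Cox fit
#'
#' Treatment effect in the trailing window containing exactly the last
#' `n_last_events` events of the trial: the window starts at the time of
#' event number `total_events - n_last_events` and runs to the trial stop;
#' subjects event-free and uncensored at the window start form the risk set
#' (left truncation at the window start).
#'
#' @inheritParams fit_cox_ph
#' @param n_last_events Number of trailing events defining the period
#'   (default 65).
#' @return An `fb_coxfit`.
#' @export
fit_last_period_cox <- function(data, n_last_events = 65, covariates = NULL,
                                treatment_var = "trt") {
  covariates <- .fit_covariates(data, covariates)
  ev_times <- sort(data$exit[data$event == 1])
  m <- length(ev_times)
  if (m < n_last_events) {
    stop("fit_last_period_cox: dataset has ", m, " events < n_last_events = ",
         n_last_events)
  }
  start <- if (m == n_last_events) 0 else ev_times[m - n_last_events]
  keep <- data$exit > start
  w <- data[keep, , drop = FALSE]
  w$entry <- pmax(w$entry, start)
  fit_cox_ph(w, covariates, treatment_var)
}

# ---------------------------------------------------------------------------
# Quadratic-spline time-dependent-coefficient model

#' Quadratic B-spline basis specification
#'
#' @param interior_knots Interior knot locations (years), strictly inside the
#'   boundary.
#' @param boundary Length-2 boundary knots, typically `c(0, max follow-up)`.
#' @return An object of class `fb_spline_basis` with `degree = 2`; the basis
#'   has `3 + length(interior_knots)` functions and spans constants, so the
#'   proportional-hazards model is nested within the time-dependent one.
#' @export
spline_basis_spec <- function(interior_knots = numeric(0), boundary) {
  boundary <- as.numeric(boundary)
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2])
  interior_knots <- as.numeric(interior_knots)
  if (length(interior_knots) &&
      (any(interior_knots <= boundary[1]) || any(interior_knots >= boundary[2]))) {
    stop("spline_basis_spec: interior knots must lie strictly inside the boundary")
  }
  structure(list(degree = 2L, interior_knots = sort(interior_knots),
                 boundary = boundary),
            class = "fb_spline_basis")
}

#' Evaluate the quadratic B-spline basis
#'
#' B-spline basis of degree 2 on the specification's knots; the functions are
#' a partition of unity (they sum to 1 at every `t`). Times outside the
#' boundary are clamped to it with a warning.
#'
#' @param spec An [spline_basis_spec()].
#' @param t Evaluation times.
#' @return Matrix with `length(t)` rows and `3 + length(interior_knots)`
#'   columns.
#' @export
quadratic_spline_basis <- function(spec, t) {
  stopifnot(inherits(spec, "fb_spline_basis"))
  if (any(t < spec$boundary[1] | t > spec$boundary[2])) {
    warning("quadratic_spline_basis: times outside the boundary clamped")
    t <- pmin(pmax(t, spec$boundary[1]), spec$boundary[2])
  }
  knots <- c(rep(spec$boundary[1], 3), spec$interior_knots,
             rep(spec$boundary[2], 3))
  splines::splineDesign(knots, t, ord = 3L, outer.ok = FALSE)
}

default_spline_basis <- function(event_times, max_time,
                                 probs = c(1 / 3, 2 / 3)) {
  k <- unname(stats::quantile(event_times, probs, type = 7))
  k <- k[k > 0 & k < max_time]
  spline_basis_spec(unique(k), c(0, max_time))
}

#' @export
print.fb_tdfit <- function(x, ...) {
  cat("<fb_tdfit> quadratic-spline time-dependent log HR(t),",
      length(x$coefficients), "basis functions\n")
  cat("  LRT vs PH: stat =", format(x$lrt_stat, digits = 4),
      "df =", x$lrt_df, "p =", format(x$lrt_p, digits = 3), "\n")
  invisible(x)
}

# Exact collapsed risk-set representation when treatment is the only
# covariate: the partial-likelihood contribution of the event at t_k depends
# only on the case's arm and the at-risk counts (n1_k, n0_k), so each event
# time contributes at most three weighted rows. Intervals use the event rank
# as an artificial time scale (Cox fits depend on risk sets only); the basis
# is evaluated at the true event time.
.collapsed_td_frame <- function(data, basis_mat, ev_times) {
  d <- length(ev_times)
  ord <- order(data$exit)
  exit_s <- data$exit[ord]
  trt_s <- data$trt[ord]
  # number of subjects (treated / total) still at risk at each event time
  n_total <- nrow(data) - findInterval(ev_times, exit_s, left.open = TRUE)
  cum_trt <- cumsum(trt_s)
  n_trt <- sum(trt_s) - cum_trt[pmax(findInterval(ev_times, exit_s,
                                                  left.open = TRUE), 1L)]
  n_trt[findInterval(ev_times, exit_s, left.open = TRUE) == 0L] <- sum(trt_s)
  case_trt <- data$trt[data$event == 1][order(data$exit[data$event == 1])]
  n_ctl1 <- n_trt - case_trt
  n_ctl0 <- (n_total - n_trt) - (1L - case_trt)
  rows <- data.frame(
    entry = rep(seq_len(d) - 1L, 3),
    exit = rep(seq_len(d), 3),
    event = rep(c(1L, 0L, 0L), each = d),
    trt = c(case_trt, rep(1L, d), rep(0L, d)),
    w = c(rep(1L, d), n_ctl1, n_ctl0)
  )
  rows <- cbind(rows, basis_mat[rep(seq_len(d), 3), , drop = FALSE])
  rows[rows$w > 0, , drop = FALSE]
}

# Generic episode split at event times (needed when the fit adjusts for
# age/sex); assumes one episode per subject starting at entry = 0.
.split_td_frame <- function(data, basis_mat, ev_times, covariates) {
  n <- nrow(data)
  idx <- findInterval(data$exit, ev_times, left.open = TRUE) + 1L
  # subject i contributes episodes ending at ev_times[1..(idx-1)] plus its own
  reps <- idx
  sid <- rep(seq_len(n), reps)
  pos <- sequence(reps)
  last <- pos == reps[sid]
  exit <- ifelse(last, data$exit[sid], ev_times[pos])
  entry <- c(0, ev_times)[pos]            # pos = 1 starts at 0
  event <- ifelse(last, data$event[sid], 0L)
  out <- data.frame(entry = entry, exit = exit, event = as.integer(event),
                    trt = data$trt[sid], w = 1L)
  for (v in setdiff(covariates, "trt")) out[[v]] <- data[[v]][sid]
  bm <- matrix(0, nrow(out), ncol(basis_mat),
               dimnames = list(NULL, colnames(basis_mat)))
  at_event <- match(round(out$exit, 12), round(ev_times, 12))
  has <- !is.na(at_event)
  bm[has, ] <- basis_mat[at_event[has], , drop = FALSE]
  # basis only matters on rows that can be events or risk-set members at an
  # event time; rows ending at a censoring time sit in no risk set's endpoint,
  # evaluate at the last event time before exit for completeness
  if (any(!has)) {
    prev <- findInterval(out$exit[!has], ev_times)
    prev[prev == 0L] <- 1L
    bm[!has, ] <- basis_mat[prev, , drop = FALSE]
  }
  cbind(out, bm)
}

#' Cox model with a quadratic-spline time-dependent treatment effect
#'
#' Models the treatment log hazard ratio as a smooth function of follow-up
#' time, `beta(t) = sum_j gamma_j B_j(t)` with an unpenalized quadratic
#' B-spline basis, by maximizing the partial likelihood with the
#' basis-by-treatment interactions evaluated at each event time (episodes
#' split at event times). Also fits the nested proportional-hazards model on
#' the same risk sets and carries the likelihood-ratio test of PH.
#'
#' @inheritParams fit_cox_ph
#' @param basis An [spline_basis_spec()]; default places two interior knots at
#'   the 33rd and 67th percentiles of observed event times with boundary
#'   `(0, max follow-up)`.
#' @param treatment_var Treatment column used for the time-dependent effect.
#' @param split_method Risk-set representation: `"collapsed"` (exact weighted
#'   collapse, available when treatment is the only covariate),
#'   `"episodes"` (generic episode splitting at event times), or `"auto"`
#'   (default: collapsed when applicable). Both give identical fits.
#' @return An object of class `fb_tdfit`: basis, spline `coefficients` for
#'   treatment, `other_log_hrs`, log-likelihoods of the TD and PH fits,
#'   `lrt_stat`/`lrt_df`/`lrt_p`, and `curve(t)` returning the fitted log
#'   HR(t) with pointwise Wald bands.
#' @export
fit_td_spline_cox <- function(data, basis = NULL, covariates = NULL,
                              treatment_var = "trt",
                              split_method = c("auto", "collapsed", "episodes")) {
  split_method <- match.arg(split_method)
  covariates <- .fit_covariates(data, covariates)
  covariates[covariates == "trt"] <- treatment_var
  if (anyDuplicated(data$subject_id)) {
    if (treatment_var == "trt" && any(data$trt != data$trt_assigned)) {
      stop("fit_td_spline_cox: time-varying current treatment is not ",
           "supported; fit on 'trt_assigned' instead")
    }
    # all fitted covariates are time-fixed: collapse to one episode/subject
    o <- order(data$subject_id, data$exit)
    d <- data[o, , drop = FALSE]
    last <- !duplicated(d$subject_id, fromLast = TRUE)
    first <- !duplicated(d$subject_id)
    stopifnot(all(d$entry[first] == 0))
    data <- d[last, , drop = FALSE]
    data$entry <- 0
  }
  ev_times <- sort(data$exit[data$event == 1])
  if (anyDuplicated(ev_times)) {
    ev_times <- unique(ev_times)  # ties: risk sets evaluated at unique times
  }
  if (is.null(basis)) {
    basis <- default_spline_basis(ev_times, max(data$exit))
  }
  nb <- 3L + length(basis$interior_knots)
  if (length(ev_times) < nb + 1) {
    stop("fit_td_spline_cox: need more events than spline parameters")
  }
  bm <- quadratic_spline_basis(basis, ev_times)
  colnames(bm) <- paste0("B", seq_len(ncol(bm)))

  only_trt <- identical(covariates, treatment_var) &&
    length(unique(data$subject_id)) == nrow(data) && all(data$entry == 0) &&
    !anyDuplicated(data$exit[data$event == 1])
  if (split_method == "collapsed" && !only_trt) {
    stop("fit_td_spline_cox: the collapsed representation needs single-episode ",
         "data with treatment as the only covariate")
  }
  use_collapsed <- only_trt && split_method != "episodes"
  frame <- if (use_collapsed) {
    .collapsed_td_frame(
      data.frame(exit = data$exit, event = data$event,
                 trt = data[[treatment_var]]), bm, ev_times)
  } else {
    d2 <- data
    d2$trt <- data[[treatment_var]]
    .split_td_frame(d2, bm, ev_times, c("trt", setdiff(covariates, treatment_var)))
  }

  bnames <- colnames(bm)
  others <- setdiff(covariates, treatment_var)
  td_terms <- paste0("trt:", bnames)
  f_td <- stats::as.formula(paste(
    "survival::Surv(entry, exit, event) ~",
    paste(c(td_terms, others), collapse = " + ")))
  f_ph <- stats::as.formula(paste(
    "survival::Surv(entry, exit, event) ~",
    paste(c("trt", others), collapse = " + ")))
  ctl <- survival::coxph.control(timefix = FALSE)
  td <- survival::coxph(f_td, data = frame, weights = frame$w,
                        ties = "breslow", control = ctl)
  ph <- survival::coxph(f_ph, data = frame, weights = frame$w,
                        ties = "breslow", control = ctl)

  gamma_idx <- grep("^trt:B", names(stats::coef(td)))
  gamma <- stats::coef(td)[gamma_idx]
  vg <- td$var[gamma_idx, gamma_idx, drop = FALSE]
  singular <- any(is.na(gamma))
  if (singular) {
    warning("fit_td_spline_cox: singular information; consider fewer knots")
    gamma[is.na(gamma)] <- 0
  }
  lrt_stat <- 2 * (td$loglik[2] - ph$loglik[2])
  lrt_df <- nb - 1L
  if (lrt_stat < -1e-6) {
    stop("fit_td_spline_cox: negative LRT statistic beyond tolerance (",
         format(lrt_stat), "); convergence failure")
  }
  lrt_stat <- max(lrt_stat, 0)

  curve <- function(t) {
    B <- quadratic_spline_basis(basis, t)
    log_hr <- drop(B %*% gamma)
    se <- sqrt(pmax(rowSums((B %*% vg) * B), 0))
    data.frame(t = t, log_hr = log_hr, se = se,
               low = log_hr - 1.96 * se, high = log_hr + 1.96 * se)
  }
  structure(list(
    basis = basis, coefficients = gamma, vcov_coefficients = vg,
    other_log_hrs = stats::coef(td)[setdiff(seq_along(stats::coef(td)), gamma_idx)],
    loglik = td$loglik[2], ph_loglik = ph$loglik[2],
    ph_log_hr = unname(stats::coef(ph)["trt"]),
    lrt_stat = lrt_stat, lrt_df = lrt_df,
    lrt_p = stats::pchisq(lrt_stat, lrt_df, lower.tail = FALSE),
    n_events = length(ev_times), curve = curve, singular = singular
  ), class = "fb_tdfit")
}

#' Likelihood-ratio test of proportional hazards
#'
#' Compares the spline time-dependent fit against the nested
#' constant-coefficient (PH) fit on the same data: `stat = 2 * (loglik_TD -
#' loglik_PH)`, chi-square with df equal to the number of extra treatment
#' parameters.
#'
#' @param td_fit An `fb_tdfit`.
#' @param ph_fit Optional `fb_coxfit` fitted to the same data; defaults to the
#'   nested PH fit stored in `td_fit`.
#' @return List with `stat`, `df`, `p`.
#' @export
lrt_ph <- function(td_fit, ph_fit = NULL) {
  stopifnot(inherits(td_fit, "fb_tdfit"))
  ph_ll <- if (is.null(ph_fit)) td_fit$ph_loglik else ph_fit$loglik
  stat <- 2 * (td_fit$loglik - ph_ll)
  if (stat < -1e-6) {
    stop("lrt_ph: negative statistic beyond tolerance; convergence failure")
  }
  stat <- max(stat, 0)
  df <- td_fit$lrt_df
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
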