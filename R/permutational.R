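# Permutational algorithm: generates event times conditional on
# time-dependent exposures (and time-dependent true effects). Marginal event
# times are drawn from a constant-rate exponential calibrated to the
# scenario's target event yield; each time is then assigned, earliest first,
# to one still-at-risk unassigned subject with probability proportional to
# the covariate multiplier of that subject's hazard evaluated at that time.

#' Assign exponential event times to subjects by hazard-proportional sampling
#'
#' @param cohort An `fb_cohort`, possibly with adherence `stop_time`s.
#' @param model An [hazard_model()].
#' @param censoring A [censoring_rule()]. For the event-count kind the trial
#'   stops when `max_events` have been assigned; the marginal rate is
#'   calibrated so the expected yield over `expected_duration` years equals
#'   `max_events`. For the fixed-horizon kind all unassigned subjects are
#'   censored at the horizon (or at their own follow-up time, see
#'   `followup_range`).
#' @param seed Optional integer seed.
#' @param target_events Expected event yield used to calibrate the marginal
#'   rate under fixed-horizon censoring. When `NULL`, the yield implied by
#'   the scenario's own hazard model at the horizon is used.
#' @param followup_range Optional range for per-subject uniform administrative
#'   censoring times (staggered entry); fixed-horizon censoring only.
#' @return An `fb_survival_dataset` in counting-process form, episodes split
#'   at each subject's treatment-cessation time.
#' @export
permutational_assignment <- function(cohort, model, censoring, seed = NULL,
                                     target_events = NULL,
                                     followup_range = NULL) {
  stopifnot(inherits(model, "fb_hazard_model"),
            inherits(censoring, "fb_censoring"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  b <- exp(.base_linear_predictor(cohort, model))
  trt <- cohort$treatment
  stop_time <- cohort$stop_time

  # Per-subject administrative censoring times and the marginal rate.
  if (censoring$kind == "fixed_horizon") {
    horizon <- censoring$horizon
    cens <- if (is.null(followup_range)) rep(horizon, n) else
      stats::runif(n, followup_range[1], followup_range[2])
    if (is.null(target_events)) {
      if (is.null(model$baseline_rate)) {
        stop("permutational_assignment: need target_events or a baseline rate")
      }
      m0 <- b * exp(model$log_hr_treatment(0) * trt)
      target_events <- sum(1 - exp(-model$baseline_rate * m0 * cens))
    }
    if (target_events >= n) {
      stop("permutational_assignment: target_events must be < n_subjects")
    }
    rate <- if (is.null(followup_range)) {
      -log(1 - target_events / n) / horizon
    } else {
      stats::uniroot(function(l) sum(1 - exp(-l * cens)) - target_events,
                     c(1e-10, 1e4), tol = 1e-10)$root
    }
    max_events <- Inf
  } else {
    cens <- rep(Inf, n)
    max_events <- censoring$max_events
    if (max_events > n) {
      warning("permutational_assignment: max_events > n_subjects; capping")
      max_events <- n
    }
    rate <- -log(1 - max_events / n) / censoring$expected_duration
  }

  # Marginal observation sequence: latent exponential time vs censoring time,
  # whichever comes first; sorted ascending. Event entries are assigned to one
  # still-unassigned subject with probability proportional to the covariate
  # multiplier of the hazard at that time; censoring entries are assigned to a
  # uniformly chosen unassigned subject.
  latent <- stats::rexp(n, rate)
  obs_time <- pmin(latent, cens)
  obs_event <- latent <= cens
  ord <- order(obs_time)
  tm <- obs_time[ord]
  dm <- obs_event[ord]
  # With a common administrative horizon every censoring sorts after every
  # event and its subject composition is irrelevant: loop over events only
  # and bulk-censor the leftovers.
  n_loop <- if (length(unique(cens)) == 1L && is.finite(cens[1])) sum(dm) else n
  log_hr_t <- model$log_hr_treatment(tm)

  assigned_subj <- integer(n)
  assigned_time <- numeric(n)
  assigned_event <- integer(n)
  n_assigned <- 0L
  n_events <- 0L

  no_stops <- all(is.na(stop_time))
  key <- paste(trt, signif(b, 12))
  use_groups <- no_stops && length(unique(key)) <= 32L

  if (use_groups) {
    # Few distinct covariate multipliers (e.g. binary S, no age/sex): sample a
    # group with probability count * weight, then a uniform member (swap-pop).
    groups <- split(seq_len(n), key)
    g_ids <- lapply(groups, function(i) if (length(i) == 1L) i else sample(i))
    g_count <- vapply(g_ids, length, 1L)
    g_trt <- vapply(groups, function(i) trt[i[1]], 1L)
    g_b <- vapply(groups, function(i) b[i[1]], 1)
    for (k in seq_len(n_loop)) {
      if (n_events >= max_events) break
      if (sum(g_count) == 0L) break
      w <- if (dm[k]) g_count * g_b * exp(log_hr_t[k] * g_trt) else g_count
      g <- sample.int(length(g_ids), 1L, prob = w)
      j <- g_ids[[g]][g_count[g]]          # last slot of the shuffled group
      g_count[g] <- g_count[g] - 1L
      g_ids[[g]] <- g_ids[[g]][seq_len(g_count[g])]
      n_assigned <- n_assigned + 1L
      assigned_subj[n_assigned] <- j
      assigned_time[n_assigned] <- tm[k]
      assigned_event[n_assigned] <- as.integer(dm[k])
      if (dm[k]) n_events <- n_events + 1L
    }
  } else {
    risk <- seq_len(n)
    trt1 <- trt == 1L
    stop_inf <- ifelse(is.na(stop_time), Inf, stop_time)
    for (k in seq_len(n_loop)) {
      if (n_events >= max_events) break
      if (!length(risk)) break
      t <- tm[k]
      if (dm[k]) {
        w <- b[risk]
        a_now <- trt1[risk] & stop_inf[risk] > t
        w[a_now] <- w[a_now] * exp(log_hr_t[k])
        cs <- cumsum(w)  # inverse-CDF draw; avoids per-call weight sorting
        pos <- if (length(risk) == 1L) 1L else
          findInterval(stats::runif(1) * cs[length(cs)], cs) + 1L
      } else {
        pos <- if (length(risk) == 1L) 1L else sample.int(length(risk), 1L)
      }
      j <- risk[pos]
      risk <- risk[-pos]
      n_assigned <- n_assigned + 1L
      assigned_subj[n_assigned] <- j
      assigned_time[n_assigned] <- t
      assigned_event[n_assigned] <- as.integer(dm[k])
      if (dm[k]) n_events <- n_events + 1L
    }
  }

  if (is.finite(max_events) && n_events < max_events) {
    warning("permutational_assignment: only ", n_events,
            " events assigned (< max_events)")
  }

  # Exit time and event flag per subject; under the event-count rule the
  # trial stops at the last assigned event and everyone else is censored then.
  keep <- seq_len(n_assigned)
  exit <- numeric(n)
  event <- integer(n)
  if (is.finite(max_events)) {
    tau <- if (n_events > 0) max(assigned_time[keep][assigned_event[keep] == 1L]) else 0
    exit[] <- tau
    sel <- keep[assigned_event[keep] == 1L]
    exit[assigned_subj[sel]] <- assigned_time[sel]
    event[assigned_subj[sel]] <- 1L
    stop_trial <- tau
  } else {
    exit <- pmin(cens, censoring$horizon)  # default for bulk-censored leftovers
    exit[assigned_subj[keep]] <- assigned_time[keep]
    event[assigned_subj[keep]] <- assigned_event[keep]
    stop_trial <- censoring$horizon
  }

  # Counting-process episodes, split at treatment-cessation times.
  split_needed <- !is.na(stop_time) & stop_time < exit & trt == 1L
  base <- data.frame(subject_id = cohort$subject_id, entry = 0, exit = exit,
                     event = event, trt = trt, trt_assigned = trt,
                     age = cohort$age, sex = cohort$sex,
                     s = cohort$susceptibility)
  if (any(split_needed)) {
    pre <- base[split_needed, , drop = FALSE]
    post <- pre
    pre$exit <- stop_time[split_needed]
    pre$event <- 0L
    post$entry <- stop_time[split_needed]
    post$trt <- 0L
    base <- rbind(base[!split_needed, , drop = FALSE], pre, post)
  }
  .new_survival_dataset(base, stop_trial)
}

#' Simulate one complete trial replicate
#'
#' Runs the full generation pipeline for a scenario: draw the cohort (and
#' adherence trajectories when enabled), generate event times — through the
#' closed-form proportional-hazards sampler when the exposure and its effect
#' are time-fixed, otherwise through the permutational algorithm — and apply
#' the scenario's censoring rule.
#'
#' @param scen A [scenario()].
#' @param seed Integer seed; the whole replicate is a deterministic function
#'   of it.
#' @param age_sd Pre-truncation SD of the age distribution.
#' @return An `fb_survival_dataset`.
#' @export
simulate_trial <- function(scen, seed = NULL, age_sd = 10) {
  stopifnot(inherits(scen, "fb_scenario"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(scen, age_sd = age_sd)
  model <- hazard_model(scen)
  if (scen$adherence$enabled && scen$adherence$annual_stop_fraction > 0) {
    cohort <- generate_adherence_trajectories(cohort, scen$adherence)
  }
  needs_perm <- !model$constant_treatment_effect ||
    any(!is.na(cohort$stop_time)) ||
    is.null(model$baseline_rate) || !is.null(scen$target_events)
  ds <- if (needs_perm) {
    permutational_assignment(cohort, model, scen$censoring,
                             target_events = scen$target_events,
                             followup_range = scen$followup_range)
  } else {
    times <- simulate_event_times_ph(cohort, model)
    if (scen$censoring$kind == "fixed_horizon") {
      apply_administrative_censoring(cohort, times, scen$censoring$horizon)
    } else {
      apply_event_count_censoring(cohort, times, scen$censoring$max_events)
    }
  }
  attr(ds, "covariates") <- if (scen$include_covariates) {
    c("trt", "age", "sex")
  } else {
    "trt"
  }
  ds
}
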