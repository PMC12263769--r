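# Scenario execution: deterministic seeding, replication, optional forking,
# persistence/resume, and table reproduction in the layout of the built-in
# scenario grids.

#' Deterministic per-replicate seed
#'
#' Derives the seed of replicate `rep` of a labelled scenario from the master
#' seed via a counter-based hash, so results do not depend on scheduling or
#' worker count.
#'
#' @param master_seed Integer master seed.
#' @param label Scenario label.
#' @param rep Replicate index (1-based).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, label, rep) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 1000003
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 +
    h * 16807 + as.numeric(rep) * 69621
  as.integer(s %% 2147483646) + 1L
}

.replicate_once <- function(scen, r, master_seed, n_last_events, years,
                            basis, curve_grid, age_sd) {
  seed <- derive_seed(master_seed, scen$label, r)
  ds <- simulate_trial(scen, seed = seed, age_sd = age_sd)
  n_events <- sum(ds$event)
  rows <- list(data.frame(rep = r, seed = seed, estimand = "incidence",
                          year = NA_real_, log_hr = NA_real_, se = NA_real_,
                          stat = 100 * n_events / scen$n_subjects,
                          p = NA_real_))
  add <- function(estimand, year, log_hr, se, stat = NA_real_, p = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      rep = r, seed = seed, estimand = estimand, year = year,
      log_hr = log_hr, se = se, stat = stat, p = p)
  }
  if ("overall" %in% scen$estimand_set) {
    f <- fit_cox_ph(ds)
    add("overall", NA_real_, f$log_hr, f$se)
  }
  if ("year_specific" %in% scen$estimand_set) {
    for (y in years) {
      f <- fit_year_specific_cox(ds, y)
      add("year_specific", y,
          if (f$n_events > 0) f$log_hr else NA_real_,
          if (f$n_events > 0) f$se else NA_real_)
    }
  }
  if ("last_period" %in% scen$estimand_set) {
    f <- fit_last_period_cox(ds, n_last_events)
    add("last_period", NA_real_, f$log_hr, f$se)
  }
  if ("td_spline" %in% scen$estimand_set) {
    f <- fit_td_spline_cox(ds, basis = basis,
                           treatment_var = if (scen$adherence$enabled)
                             "trt_assigned" else "trt")
    add("td_spline", NA_real_, f$ph_log_hr, NA_real_, f$lrt_stat, f$lrt_p)
    if (!is.null(curve_grid)) {
      cv <- f$curve(curve_grid)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, seed = seed, estimand = "td_curve", year = curve_grid,
        log_hr = cv$log_hr, se = cv$se, stat = NA_real_, p = NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Run all replicates of a scenario
#'
#' Executes generate - censor - fit - aggregate for `replicates` independent
#' samples of a scenario. Replicate `r` uses the seed
#' `derive_seed(master_seed, label, r)`, so results are identical regardless
#' of worker count, and runs persisted to `out_dir` can be resumed (completed
#' replicates found on disk are skipped). A failing replicate is logged with
#' its seed and skipped; the failure count is reported in the summary.
#'
#' @param scen A [scenario()].
#' @param replicates Number of Monte-Carlo replicates (default 1000).
#' @param master_seed Integer master seed.
#' @param workers Number of forked workers (1 = sequential).
#' @param out_dir Optional directory for per-replicate CSV persistence.
#' @param n_last_events Number of trailing events defining the last period.
#' @param basis Optional [spline_basis_spec()] override for TD fits.
#' @param curve_grid Optional time grid at which each replicate's fitted TD
#'   curve is stored.
#' @param age_sd Pre-truncation age SD passed to the generator.
#' @return List of class `fb_replicate_set`: `scenario`, `replicates` (long
#'   data frame: rep, seed, estimand, year, log_hr, se, stat, p), `failures`,
#'   and `summary` (see [performance_summary()]).
#' @export
run_scenario <- function(scen, replicates = 1000, master_seed = 1,
                         workers = 1, out_dir = NULL, n_last_events = 65,
                         basis = NULL, curve_grid = NULL, age_sd = 10) {
  stopifnot(inherits(scen, "fb_scenario"))
  if (replicates < 1) stop("run_scenario: 'replicates' must be >= 1")
  years <- if ("year_specific" %in% scen$estimand_set) {
    seq_len(floor(if (scen$censoring$kind == "fixed_horizon")
      scen$censoring$horizon else scen$censoring$expected_duration))
  } else {
    integer(0)
  }
  cache_file <- function(r) {
    file.path(out_dir, sprintf("%s_rep%05d.csv", scen$label, r))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  one <- function(r) {
    if (!is.null(out_dir) && file.exists(cache_file(r))) {
      return(utils::read.csv(cache_file(r)))
    }
    res <- tryCatch(
      .replicate_once(scen, r, master_seed, n_last_events, years, basis,
                      curve_grid, age_sd),
      error = function(e) {
        warning("replicate ", r, " (seed ",
                derive_seed(master_seed, scen$label, r), ") failed: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res) && !is.null(out_dir)) {
      utils::write.csv(res, cache_file(r), row.names = FALSE)
    }
    res
  }
  results <- if (workers > 1) {
    parallel::mclapply(seq_len(replicates), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(replicates), one)
  }
  failures <- sum(vapply(results, is.null, TRUE))
  reps <- do.call(rbind, results[!vapply(results, is.null, TRUE)])
  structure(list(scenario = scen, replicates = reps, failures = failures,
                 summary = performance_summary(reps, scen)),
            class = "fb_replicate_set")
}

#' Aggregate replicate estimates into performance measures
#'
#' @param reps Long replicate data frame from [run_scenario()].
#' @param scen The scenario the replicates came from.
#' @return List with mean cumulative incidence (%), per-estimand summaries:
#'   overall and last-period mean / bias / relative bias (%) and HR-scale
#'   distribution summaries, year-specific relative biases, and the LRT
#'   PH-rejection percentage, where available.
#' @export
performance_summary <- function(reps, scen) {
  true_lhr <- if (scen$treatment_effect$kind == "constant") {
    log(scen$treatment_effect$hr)
  } else {
    NA_real_
  }
  out <- list(label = scen$label, n_replicates = length(unique(reps$rep)),
              true_log_hr = true_lhr)
  out$mean_cumulative_incidence <-
    mean(reps$stat[reps$estimand == "incidence"])
  cox_summary <- function(est) {
    est <- est[!is.na(est)]
    if (!length(est)) return(NULL)
    s <- list(mean_log_hr = mean(est),
              hr = unname(summarize_distribution(exp(est))))
    if (!is.na(true_lhr)) {
      s$bias <- mean(est) - true_lhr
      s$relative_bias_pct <- relative_bias(est, true_lhr)
    }
    s
  }
  if (any(reps$estimand == "overall")) {
    out$overall <- cox_summary(reps$log_hr[reps$estimand == "overall"])
  }
  if (any(reps$estimand == "last_period")) {
    out$last_period <- cox_summary(reps$log_hr[reps$estimand == "last_period"])
  }
  if (any(reps$estimand == "year_specific")) {
    ys <- reps[reps$estimand == "year_specific", ]
    years <- sort(unique(ys$year))
    rb <- vapply(years, function(y) {
      e <- ys$log_hr[ys$year == y]
      if (all(is.na(e)) || is.na(true_lhr)) NA_real_
      else relative_bias(e, true_lhr)
    }, 1)
    out$year_specific_relative_bias_pct <- stats::setNames(rb, years)
  }
  if (any(reps$estimand == "td_spline")) {
    td <- reps[reps$estimand == "td_spline", ]
    out$lrt_rejection_pct <- 100 * mean(td$p < 0.05, na.rm = TRUE)
  }
  out
}

#' Reproduce a built-in results table
#'
#' Runs every scenario of a registry and emits a table in the layout of the
#' corresponding built-in grid: `"table1"` / `"table2"` give one row per
#' scenario with mean cumulative incidence, overall relative bias and
#' year-specific relative biases at even years (plus Monte-Carlo standard
#' errors of the overall estimate); `"fig2"` gives mean / 5th percentile /
#' minimum of the overall and last-period HR estimates per targeted scenario;
#' `"fig6"` gives the LRT PH-rejection percentage per replication scenario.
#'
#' @param name One of `"table1"`, `"table2"`, `"fig2"`, `"fig6"`.
#' @param replicates Replicates per scenario (full scale: 1000; reduced
#'   presets such as 50 or 200 are appropriate for quick runs).
#' @param master_seed Integer master seed.
#' @param out Optional CSV path.
#' @param workers Forked workers per scenario run.
#' @param scenarios Optional subset of scenario labels.
#' @return The table as a data frame (invisibly written to `out` if given).
#' @export
reproduce_table <- function(name = c("table1", "table2", "fig2", "fig6"),
                            replicates = 1000, master_seed = 1, out = NULL,
                            workers = 1, scenarios = NULL) {
  name <- match.arg(name)
  if (replicates < 1) stop("reproduce_table: 'replicates' must be >= 1")
  registry <- switch(name,
    table1 = table1_scenarios(),
    table2 = table2_scenarios(),
    fig2 = targeted_scenarios(),
    fig6 = replication_scenarios())
  if (!is.null(scenarios)) {
    registry <- Filter(function(s) s$label %in% scenarios, registry)
  }
  rows <- lapply(registry, function(scen) {
    rs <- run_scenario(scen, replicates = replicates,
                       master_seed = master_seed, workers = workers)
    sm <- rs$summary
    susc <- scen$susceptibility
    base <- data.frame(
      scenario = scen$label,
      n = scen$n_subjects,
      baseline_survival_5y = if (is.null(scen$baseline_survival_5y))
        NA_real_ else scen$baseline_survival_5y,
      susceptibility_family = susc$family,
      prevalence = if (is.null(susc$prevalence)) NA_real_ else susc$prevalence,
      hr_s = susc$hr_per_unit,
      hr_a = if (scen$treatment_effect$kind == "constant")
        scen$treatment_effect$hr else NA_real_,
      incidence_pct = sm$mean_cumulative_incidence,
      failures = rs$failures)
    if (name %in% c("table1", "table2")) {
      est <- rs$replicates$log_hr[rs$replicates$estimand == "overall"]
      base$overall_rb_pct <- sm$overall$relative_bias_pct
      base$overall_rb_mcse_pct <-
        100 * stats::sd(est, na.rm = TRUE) /
        sqrt(sum(!is.na(est))) / abs(sm$true_log_hr)
      for (y in c(2, 4, 6, 8, 10)) {
        base[[paste0("rb_year", y)]] <-
          unname(sm$year_specific_relative_bias_pct[as.character(y)])
      }
    } else if (name == "fig2") {
      base$overall_mean_hr <- sm$overall$hr[1]
      base$overall_p5_hr <- sm$overall$hr[2]
      base$overall_min_hr <- sm$overall$hr[3]
      base$last_mean_hr <- sm$last_period$hr[1]
      base$last_p5_hr <- sm$last_period$hr[2]
      base$last_min_hr <- sm$last_period$hr[3]
    } else {
      base$lrt_rejection_pct <- sm$lrt_rejection_pct
    }
    base
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
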