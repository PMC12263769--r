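# Replicate-level performance measures: bias, relative bias, distribution
# summaries, depletion curves, sign/CI statistics, LRT rejection rates and
# mean time-dependent curves.

.drop_na <- function(x, what) {
  bad <- sum(is.na(x))
  if (bad) message(what, ": dropping ", bad, " undefined estimate(s)")
  x[!is.na(x)]
}

#' Relative bias of log hazard-ratio estimates
#'
#' `100 * (mean(estimates) - true_log_hr) / true_log_hr`. Undefined estimates
#' (e.g. years without events) are dropped with a message.
#'
#' @param estimates Vector of log HR estimates across replicates.
#' @param true_log_hr True log HR (non-zero).
#' @return Relative bias in percent.
#' @export
relative_bias <- function(estimates, true_log_hr) {
  if (true_log_hr == 0) {
    stop("relative_bias: true log HR is 0; use absolute bias instead")
  }
  estimates <- .drop_na(estimates, "relative_bias")
  if (!length(estimates)) stop("relative_bias: no defined estimates")
  100 * (mean(estimates) - true_log_hr) / true_log_hr
}

#' Distribution summary of hazard-ratio estimates
#'
#' Empirical mean, 5th percentile (nearest-rank convention) and minimum.
#'
#' @param estimates Vector of estimates (HR scale).
#' @return Named vector `(mean, p5, min)`.
#' @export
summarize_distribution <- function(estimates) {
  estimates <- .drop_na(estimates, "summarize_distribution")
  if (!length(estimates)) stop("summarize_distribution: no estimates")
  s <- sort(estimates)
  p5 <- s[max(1L, ceiling(0.05 * length(s)))]
  c(mean = mean(s), p5 = p5, min = s[1])
}

#' Proportion of estimates strictly below a threshold
#'
#' @param estimates Vector of estimates (HR scale).
#' @param threshold Threshold value.
#' @return Percentage in \[0, 100\].
#' @export
proportion_below <- function(estimates, threshold) {
  estimates <- .drop_na(estimates, "proportion_below")
  if (!length(estimates)) return(0)
  100 * mean(estimates < threshold)
}

#' Depletion of susceptibles by arm and year
#'
#' For each year start `t = 0, 1, ...`, the susceptibility composition of the
#' subjects still at risk (no event and not censored by `t`), separately in
#' the treated and untreated arms, averaged over replicates: `P(S = 1 | A = a,
#' at risk at t)` for a binary susceptibility, or the arm-wise mean of `S`
#' otherwise.
#'
#' @param replicates List of `fb_survival_dataset` objects (one per
#'   replicate), each carrying the per-subject susceptibility column `s`.
#' @param years Year starts to evaluate (default `0:9`).
#' @return Data frame with columns `year_start`, `arm` (0/1), `value`
#'   (averaged over the replicates in which the risk set was non-empty) and
#'   `n_replicates`.
#' @export
depletion_proportions <- function(replicates, years = 0:9) {
  if (inherits(replicates, "fb_survival_dataset")) replicates <- list(replicates)
  acc <- array(NA_real_, dim = c(length(replicates), length(years), 2))
  for (r in seq_along(replicates)) {
    d <- replicates[[r]]
    # last episode per subject gives time under observation
    last <- d[!duplicated(d$subject_id, fromLast = TRUE), , drop = FALSE]
    for (y in seq_along(years)) {
      at_risk <- last$exit > years[y]
      for (a in 0:1) {
        sel <- at_risk & last$trt_assigned == a
        if (any(sel)) acc[r, y, a + 1] <- mean(last$s[sel])
      }
    }
  }
  out <- expand.grid(year_start = years, arm = 0:1)
  out$value <- c(colMeans(acc[, , 1, drop = FALSE], na.rm = TRUE),
                 colMeans(acc[, , 2, drop = FALSE], na.rm = TRUE))
  out$n_replicates <- c(colSums(!is.na(acc[, , 1, drop = FALSE])),
                        colSums(!is.na(acc[, , 2, drop = FALSE])))
  out$value[out$n_replicates == 0] <- NA_real_
  out
}

#' Sign and confidence-interval rates of year-specific estimates
#'
#' Across replicates, for the given years: the percentage of negative
#' year-specific log HR point estimates; the percentage whose Wald 95% CI lies
#' entirely below 0; and the percentage of replicates with negative point
#' estimates in *all* the listed years simultaneously.
#'
#' @param estimates Matrix of year-specific log HR estimates, replicates in
#'   rows, with columns named by year.
#' @param ses Matching matrix of standard errors.
#' @param years Years to evaluate (must match column names).
#' @return List with `negative_pct` (per year), `ci_excludes_zero_pct` (per
#'   year) and `all_negative_pct` (scalar).
#' @export
sign_and_ci_rates <- function(estimates, ses, years = c(8, 9, 10)) {
  cols <- match(as.character(years), colnames(estimates))
  if (anyNA(cols)) stop("sign_and_ci_rates: missing year column(s)")
  est <- estimates[, cols, drop = FALSE]
  se <- ses[, cols, drop = FALSE]
  neg <- est < 0
  excl <- est + 1.96 * se < 0
  list(
    negative_pct = 100 * colMeans(neg, na.rm = TRUE),
    ci_excludes_zero_pct = 100 * colMeans(excl, na.rm = TRUE),
    all_negative_pct = 100 * mean(apply(neg, 1, function(z) all(!is.na(z)) && all(z)))
  )
}

#' Pointwise mean and interquartile band of time-dependent curves
#'
#' @param fits List of `fb_tdfit` objects (or a numeric matrix of curves with
#'   replicates in rows).
#' @param grid Evaluation times.
#' @return Data frame with columns `t`, `mean`, `q1`, `q3`.
#' @export
mean_td_curve <- function(fits, grid) {
  curves <- if (is.matrix(fits)) fits else
    t(vapply(fits, function(f) f$curve(grid)$log_hr, numeric(length(grid))))
  stopifnot(ncol(curves) == length(grid))
  data.frame(
    t = grid,
    mean = colMeans(curves),
    q1 = apply(curves, 2, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(curves, 2, stats::quantile, probs = 0.75, names = FALSE)
  )
}
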