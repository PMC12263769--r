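---
title: "Simulating depletion-of-susceptibles bias in Cox hazard-ratio estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating depletion-of-susceptibles bias in Cox hazard-ratio estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtybias)
```

## The problem

When a risk factor that multiplies each subject's hazard is *not* included in
a Cox proportional-hazards model, the model's treatment-effect estimate is a
population-averaged quantity that differs from the subject-level effect.
In a randomized trial the omitted factor — an unmeasured *susceptibility* or
*frailty* $S$ — is balanced between arms at baseline, but high-$S$ subjects
have events earlier, and they are removed from the risk set *faster in the
higher-hazard arm*. Over follow-up, $S$ therefore becomes associated with
treatment among subjects still at risk: it turns into an induced confounder.
The familiar consequences are (i) attenuation toward the null of the overall
Cox hazard ratio (HR), (ii) period-specific HRs that drift toward (and can
cross) 1 with longer follow-up even when the true effect is constant, and
(iii) an induced violation of the proportional-hazards (PH) assumption.

This package provides the simulation and estimation machinery to quantify
those phenomena: how large the bias actually gets as a function of the
distribution of $S$, its effect size, and the event incidence; whether
realistic frailty can reproduce published trial results that have been
attributed to it; and whether flexible time-dependent (TD) effect estimators
can distinguish genuine effect decay from the frailty artefact.

## Generative model

Event times are drawn from a proportional-hazards model with constant
baseline hazard

$$
\lambda(t \mid A, S, \text{age}, \text{sex}) \;=\;
\lambda_0 \exp\!\big[\beta_A(t)\,A(t) + \beta_S S +
\log(1.04)(\text{age}-60) + \log(0.8)\,\text{sex}\big].
$$

* **Treatment** $A$: Bernoulli(0.5) at randomization (or an exact arm size
  where a scenario fixes it). Under non-adherence, $A(t)$ switches from 1 to
  0 at the subject's cessation time.
* **Susceptibility** $S$: independent of everything else; binary with a given
  prevalence, standard normal, or standardized lognormal (log-scale SD 0.5
  for moderate skewness $\approx 1.75$, or 1.0 for high skewness
  $\approx 6.2$). Continuous families are standardized to mean 0, SD 1, so
  `hr_per_unit` is the hazard ratio per SD.
* **Age and sex**: nuisance covariates with fixed effects (HR 1.04 per year,
  HR 0.8 female vs male). Age is normal with mean 60, truncated to
  [20, 100] by resampling. The pre-truncation SD is not dictated by the
  designs being emulated; the default of 10 years is a typical trial
  population and is configurable (`age_sd`). Because the age effect is fixed
  and age is balanced by randomization, the bias results are insensitive to
  this choice.
* **Baseline hazard** $\lambda_0$: calibrated so that exponential survival at
  the *reference covariate pattern* (untreated, $S=0$, age 60, male) hits a
  target 5-year survival: $\lambda_0 = -\log(s_5)/5$. This reading makes the
  calibration closed-form, and the mean cumulative incidences it implies
  match the values the scenario grids are designed to reproduce (e.g. the
  binary-susceptibility grid's 57.4% for its strong-frailty scenario).

With a time-fixed exposure and effect, latent event times are drawn in
closed form as $T_i = E_i / (\lambda_0 e^{\text{lp}_i})$ with $E_i$ unit
exponential.

### Censoring

Two administrative rules are supported: a fixed horizon (10 years in the
scenario grids), and an event-count stop — the trial ends at the time of the
`max_events`-th event (335 in the trial-mimicking designs), everyone else
being censored then. Latent ties are broken by subject id; with continuous
times they have probability zero. No random dropout is modelled, because the
emulated designs use none.

### Non-adherence

The non-adherence design assumes a fixed *fraction* of the initially treated
arm stops treatment each year (cessation time uniform within the year,
subjects drawn without replacement). The quota reading — rather than a 6%
per-year hazard of stopping — is used because it reproduces the emulated
trial's reported 42% cumulative non-adherence at seven years exactly
($7 \times 6\%$). Cessation is drawn over the first 7 trial years and the
fraction is constant thereafter.

### The permutational algorithm

When the hazard depends on a time-dependent exposure $A(t)$ (or the true
effect $\beta_A(t)$ varies in time), inverting the subject-specific
cumulative hazard is no longer convenient. The package instead uses the
permutational algorithm:

1. draw a *marginal* observation sequence — latent times from a constant-rate
   exponential, censoring times from the administrative rule — and sort it;
2. walk through the sequence: an event entry is assigned to one
   still-unassigned subject with probability proportional to the covariate
   multiplier of its hazard *evaluated at that time* (so a subject who has
   stopped treatment contributes $e^{\beta_S S}$ rather than
   $e^{\beta_A + \beta_S S}$); a censoring entry is assigned uniformly;
3. under the event-count rule, assignment stops at `max_events` and all
   remaining subjects are censored at the trial stop.

The marginal rate is calibrated to the scenario's target event yield: with a
horizon $h$ and target $D$ events among $N$ subjects the rate solves
$N(1 - e^{-\text{rate}\,h}) = D$ (with per-subject follow-up times, the
analogous sum is solved numerically). Under the event-count rule there is no
intrinsic horizon, so the rule carries an `expected_duration` (default 7
years, the span of the emulated trial) that fixes the time scale; only the
calendar interpretation of "per year" quantities depends on it, not the Cox
estimates, because the assignment probabilities match the Cox partial
likelihood at any time scale. This is also why the algorithm is validated by
an unbiasedness property: fitting the Cox model with the current-treatment
covariate on data generated under non-adherence recovers the true log HR
(the acceptance suite measures exactly this).

Assignment is implemented two ways with identical distributions: a grouped
swap-pop sampler used when the covariate multiplier takes few distinct
values (e.g. binary $S$ without age/sex — the 41,146-subject replication
series), and a generic inverse-CDF sampler over the full risk set otherwise.

### Staggered follow-up

One replication series has per-subject follow-up between 0.5 and 4 years
("staggered entry", median 2.25 years). It is modelled as per-subject
administrative censoring times drawn uniformly on that range, with the
marginal event rate calibrated against those times to the series' target
event count; both the range and the target are scenario fields.

## Estimands

All fitted models deliberately **omit** $S$ — that is the point.

* **Overall Cox PH fit** (`fit_cox_ph`): treatment plus age and sex (Efron
  ties, counting-process input). Datasets whose generating hazard omits age
  and sex are fitted with treatment only.
* **Year-specific fits** (`fit_year_specific_cox`): for year $t$, subjects
  event-free and uncensored at $t-1$, left-truncated at $t-1$ on the
  original time scale, events in $(t-1, t]$, everyone else censored at $t$.
  Left truncation (rather than resetting the time origin) keeps one code
  path; within a one-year window the risk sets are identical either way.
  Years without events return an undefined estimate and are dropped from
  aggregation with a logged count.
* **Last-period fit** (`fit_last_period_cox`): the trailing window holding
  exactly the last `n_last_events` (default 65) of the trial's events,
  left-truncated at the window start. This operationalizes "the last period
  with about 65 events" as a deterministic window; the event-count design
  (335 events) then always leaves 65 events in the period.
* **Time-dependent effect** (`fit_td_spline_cox`): the treatment log HR is
  modelled as $\beta(t) = \sum_j \gamma_j B_j(t)$ with an unpenalized
  quadratic B-spline basis. The basis spans constants, so the PH model is
  nested and the likelihood-ratio test of PH has
  $\text{df} = (\text{basis functions}) - 1$. Default knots: two interior
  knots at the 33rd and 67th percentiles of observed event times (boundary
  at 0 and the maximum follow-up); percentile placement adapts the basis to
  the incidence pattern and is configurable through `spline_basis_spec()`.
* **Metrics** (`relative_bias`, `summarize_distribution`,
  `proportion_below`, `depletion_proportions`, `sign_and_ci_rates`,
  `mean_td_curve`): relative bias is
  $100(\bar{\hat\beta} - \beta)/\beta$ on the log-HR scale; distribution
  summaries report the mean, 5th percentile and minimum on the HR scale with
  the nearest-rank percentile convention (deterministic, no interpolation
  ambiguity); "CI excludes zero" counts replicates whose Wald 95% CI lies
  entirely below zero.

## Fitting machinery

All partial-likelihood maximization is delegated to `survival::coxph`.
Because the spline coefficients enter through treatment-by-basis
interactions evaluated at event times, the TD model is fitted on a
risk-set representation built by episode splitting at event times. When
treatment is the only covariate the representation is collapsed exactly:
each event time contributes one case row and (at most) two weighted control
rows holding the at-risk counts by arm, which reproduces the partial
likelihood term for term and keeps the largest replication series (about
4,300 events among 41,146 subjects) tractable. The two representations are
verified to give identical fits. `timefix` is disabled because event times
are exact doubles from the generator; the default tie-rounding would
collapse the very short intervals that a strong frailty induces.

Wald confidence intervals on the log scale are used throughout. A treatment
column with no contrast yields a log HR of 0 with infinite variance and a
convergence flag instead of an error, so replicate loops degrade gracefully.

## Scenario registries

* `table1_scenarios()` — 26 designs crossing binary-susceptibility
  prevalence (0.025–0.5), effect (HR 2–25), baseline survival (0.7–0.99),
  sample size (4,000 / 16,000) and treatment effect (HR 1.3–6), 10-year
  horizon.
* `table2_scenarios()` — 17 designs with standard-normal $S$ (HR 1.2–3 per
  SD).
* `targeted_scenarios()` — trial-mimicking designs: $N = 16{,}600$, true
  HR 1.81, reference survival 0.999, stop at 335 events; binary $S$ with
  HR 25 over a prevalence grid (including 0 = no frailty), and three
  continuous families over a per-SD HR grid. The grids beyond the values
  fixed by the emulated designs default to prevalences
  $\{0, 0.05, 0.1, 0.25, 0.5\}$ and HRs $\{2, 2.5, 3, 4\}$ and are
  arguments, not constants.
* `nonadherence_scenario()` — the targeted design with no frailty and a 6%
  annual cessation quota.
* `replication_scenarios()` — two series with published time-dependent
  effects: a kidney-transplant cohort ($N = 41{,}146$, 23,275 exposed,
  about 4,340 deaths in 1.5 years; log HR declining piecewise-linearly
  from $\log 2.84$ at 1 month through 0 at 3.5 months to $\log 0.32$ at 12
  months) and an aspirin trial scaled fivefold ($N = 1{,}860$, 940 exposed,
  about 520 events over up to 4 years; log HR rising linearly from
  $\log 0.5$ at baseline to 0 at 1 year). Each series has three variants:
  TD effect alone, TD effect plus strong binary frailty (HR 10, prevalence
  0.5), and constant effect (the first-month HR) plus the same frailty.
  True TD curves are encoded as piecewise-linear interpolation in the log
  HR between the quoted anchors with constant extrapolation outside them —
  the minimal assumption consistent with the anchor values; the sources
  publish the full shapes only as figures.

## Worked example

A desk-scale run of the strongest binary-frailty design from the first
grid (`label "5"`: prevalence 0.5, HR(S) = 10, true treatment HR 2):

```{r example, eval = FALSE}
scen <- table1_scenarios()[[5]]
rs <- run_scenario(scen, replicates = 200, master_seed = 1)
rs$summary$mean_cumulative_incidence   # ~57% of subjects have events
rs$summary$overall$relative_bias_pct   # ~ -38%: strong attenuation
rs$summary$year_specific_relative_bias_pct
# year-specific attenuation deepens with follow-up (~ -20% in year 2,
# ~ -66% by year 6): the induced PH violation
```

`run_scenario()` derives every replicate's seed from
`(master_seed, label, replicate)`, so results are identical for any worker
count and persisted runs resume exactly.

## What passing tests do and do not show

The generator emulates randomized designs with administrative censoring,
multiplicative frailty that is independent of treatment and covariates, and
a constant baseline hazard. Real data differ in ways that are out of scope
here: non-exponential baseline risk, informative or random dropout,
frailty correlated with measured covariates, measurement error, and
non-multiplicative effect modification. Conclusions from the test suite are
statements about estimator behaviour *under this generative family*, not
about any particular trial.

Monte-Carlo sizes in the test suite are chosen to keep each check's
Monte-Carlo error well inside its assertion tolerance while remaining
desk-scale: the scenario-grid bias checks use 1,000 replicates (200 for the
$N = 16{,}000$ design, whose per-replicate variance is small), the
permutational validation 200, the LRT power/size checks 100–600, and the
parameter-recovery properties 50–120 at reduced $N$. Full-scale (1,000
replicate) runs of every registry are available through `reproduce_table()`.

## Numerical and degenerate-input choices

* Tie-breaking everywhere is stable by subject id.
* Percentiles use the nearest-rank convention.
* The LRT statistic is clipped at 0; a value below $-10^{-6}$ raises a
  convergence error rather than being silently clipped.
* Times outside a spline basis boundary are clamped to it with a warning.
* A singular TD information matrix flags the fit and zeroes the offending
  coefficients rather than failing the replicate loop.
* Replicate failures inside `run_scenario()` are logged with their seed and
  skipped; the failure count is part of the summary.

## Known limitations

* The power of the PH likelihood-ratio test against a *decaying* true
  effect depends strongly on the shape of the decay between the encoded
  anchors and on the spline dimension; with the linear-interpolation
  encoding and the default two-knot basis, the aspirin-series power comes
  out noticeably higher than the published estimate it emulates, while the
  near-null variants of both replication series match. The anchor values
  are the only published quantities, so the shape between them is a
  modelling choice, not an estimate.
* The last-period window is a deterministic trailing-65-events construction;
  the emulated analysis defined its periods clinically, so small
  differences in period boundaries are possible.
* Lognormal susceptibility log-scale SDs (0.5 / 1.0) are package defaults
  chosen to give clearly separated skewness regimes; the emulated designs
  state only "moderate" and "high" skewness.
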