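# Screening-strategy evaluation: policy sweeps, budgeted allocation across
# risk groups with the equal-prevalence optimality criterion, and the
# geometric fit to follow-up data for evolving vs nonevolving MGUS.

#' Sweep screening policies
#'
#' Evaluates the analytic relative MM prevalence (percent of the r = 1
#' baseline) over a grid of start ages, screening intervals, and risk
#' reduction factors.
#'
#' @param models An [mgus_models()] bundle.
#' @param a0 Vector of screening start ages.
#' @param delta_a Vector of mean screening intervals (years).
#' @param r Vector of risk-reduction factors.
#' @return Data frame with columns `a0`, `delta_a`, `r`,
#'   `relative_mm_prevalence` (percent).
#' @examples
#' m <- mgus_models(n = 1000)
#' sweep_policies(m, a0 = c(50, 60), delta_a = c(1, 4), r = c(0.61, 1))
#' @export
sweep_policies <- function(models, a0 = c(45, 55, 65), delta_a = c(1, 2, 4, 8),
                           r = c(0.1, 0.61, 1)) {
  grid <- expand.grid(a0 = a0, delta_a = delta_a, r = r,
                      KEEP.OUT.ATTRS = FALSE)
  grid$relative_mm_prevalence <- mapply(function(a, d, rr) {
    relative_mm_prevalence(screening_policy(a, d, rr), models)
  }, grid$a0, grid$delta_a, grid$r)
  grid
}

# Screening budget and per-group probabilities for an allocation fraction y.
# The budget C covers the whole screen-eligible population (living, non-MM,
# age >= a0, evaluated on the unscreened stationary population) once every
# delta_a years; a fraction y of it goes to the high-risk group. Excess
# screens in a saturated group are discarded, so per-group probabilities are
# capped at 1.
allocation_probs <- function(models, policy, y) {
  stopifnot(y >= 0, y <= 1)
  f <- models$population$f_high
  a0 <- policy$a0
  lo <- evolve_cohort(models, no_screening(), "low")
  hi <- evolve_cohort(models, no_screening(), "high")
  i <- lo$age >= a0
  elig_low <- (1 - f) * sum(lo$alive[i] - lo$M[i])
  elig_high <- f * sum(hi$alive[i] - hi$M[i])
  C <- (elig_low + elig_high) / policy$delta_a
  list(low = min(1, (1 - y) * C / elig_low),
       high = min(1, y * C / elig_high))
}

#' Within-group MM fractions under a budgeted allocation
#'
#' A fraction `y` of the total screening budget (one screen per eligible
#' individual per `delta_a` years) is directed to the high-risk group and
#' `1 - y` to the low-risk group; each group is then screened annually with
#' the induced probability (capped at 1). Returns the MM population fraction
#' within each risk group.
#'
#' @param models An [mgus_models()] bundle.
#' @param policy Base [screening_policy()] supplying `a0`, `delta_a`, `r`.
#' @param y Fraction of screens allocated to the high-risk group, in `[0, 1]`.
#' @return Named numeric vector `c(high = , low = )` of within-group MM
#'   population fractions.
#' @export
group_mm_fractions <- function(models, policy, y) {
  pr <- allocation_probs(models, policy, y)
  hi <- evolve_cohort(models, policy, "high", screen_prob = pr$high)
  lo <- evolve_cohort(models, policy, "low", screen_prob = pr$low)
  c(high = sum(hi$M) / sum(hi$alive), low = sum(lo$M) / sum(lo$alive))
}

#' Optimal high-risk screening allocation
#'
#' The allocation fraction `y*` at which the within-group MM fractions of the
#' high- and low-risk populations are equal — the equal-prevalence criterion
#' for distributing a fixed screening budget. When no crossing exists (the
#' high-risk fraction exceeds the low-risk fraction even with every screen
#' directed at high-risk individuals, as happens for weak interventions such
#' as `r = 1` or `r = 0.61`), all screens go to the high-risk group and
#' `y* = 1`.
#'
#' @param models An [mgus_models()] bundle.
#' @param policy Base [screening_policy()] (its `r`, `a0`, `delta_a` are
#'   used).
#' @param tol Bisection tolerance on `y`.
#' @return `y*` in `[0, 1]`.
#' @examples
#' m <- mgus_models(n = 1000)
#' optimal_allocation(m, screening_policy(50, 1, r = 1))    # 1: no crossing
#' @export
optimal_allocation <- function(models, policy, tol = 1e-3) {
  gap <- function(y) {
    fr <- group_mm_fractions(models, policy, y)
    fr[["high"]] - fr[["low"]]
  }
  if (gap(1) > 0) return(1)
  stats::uniroot(gap, interval = c(0, 1), tol = tol)$root
}

#' Packaged MGUS follow-up points
#'
#' Cumulative progression fractions by follow-up time for the nonevolving
#' (10% by 10 years, 13% by 20 years) and evolving (55% by 10 years, 80% by
#' 20 years) MGUS subtypes, as read from published long-term follow-up of 359
#' MGUS patients (92% nonevolving, 8% evolving).
#'
#' @param type `"evolving"`, `"nonevolving"`, or `"both"`.
#' @return Data frame with columns `type`, `time` (years), `fraction`.
#' @export
mgus_followup_points <- function(type = c("both", "evolving", "nonevolving")) {
  type <- match.arg(type)
  pts <- utils::read.csv(
    system.file("extdata", "mgus_followup.csv", package = "mgusscreen")
  )
  if (type != "both") pts <- pts[pts$type == type, , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Fit the geometric progression model to follow-up data
#'
#' Least-squares fit of the cumulative geometric curve `1 - (1 - beta)^T` to
#' observed (follow-up time, cumulative progression fraction) pairs, with the
#' origin `(0, 0)` included as a data point and `beta` constrained to
#' `[0, 1]`.
#'
#' @param points Data frame with columns `time` (years, > 0) and `fraction`
#'   (cumulative progression, in `[0, 1]`).
#' @return List with `beta` (fitted parameter), `r_squared`, and `fitted`
#'   (data frame of times, observed and fitted fractions).
#' @examples
#' fit_geometric_progression(mgus_followup_points("evolving"))$beta  # ~0.077
#' @export
fit_geometric_progression <- function(points) {
  stopifnot(is.data.frame(points), all(c("time", "fraction") %in% names(points)))
  if (nrow(points) < 1) stop("at least one follow-up point is required")
  stopifnot(all(points$time > 0), all(points$fraction >= 0),
            all(points$fraction <= 1))
  if (all(points$fraction == 0)) stop("all-zero progression fractions; fit degenerate")
  tt <- c(0, points$time)
  ff <- c(0, points$fraction)
  sse <- function(beta) sum((cumulative_progression(beta, tt) - ff)^2)
  opt <- stats::optimize(sse, interval = c(0, 1), tol = 1e-10)
  beta <- opt$minimum
  fit <- cumulative_progression(beta, tt)
  ss_tot <- sum((ff - mean(ff))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  list(beta = beta, r_squared = r2,
       fitted = data.frame(time = tt, observed = ff, fitted = fit))
}

#' Sensitivity to higher-than-two-fold lifetime risk
#'
#' Re-calibrates the high-risk incidence scale to each lifetime-risk
#' multiplier and evaluates, within the high-risk group under screening, the
#' MM population fraction and the expected MM-specific deaths per 100,000
#' (detected-MGUS prevalence at the reference age times the 10-year
#' post-detection MM mortality). Both the screening interval and the risk
#' reduction have larger absolute effects at larger multipliers.
#'
#' @param models An [mgus_models()] bundle (its low-risk calibration is kept).
#' @param multipliers Lifetime-risk multipliers (>= 1) for the high-risk
#'   group.
#' @param delta_a Vector of screening intervals to evaluate.
#' @param r Vector of risk-reduction factors.
#' @param a0 Screening start age.
#' @param reference_age Age at MGUS detection for the mortality product.
#' @param horizon Follow-up horizon in years.
#' @return Data frame with one row per (multiplier, delta_a, r): the
#'   within-group MM fraction, detected-MGUS prevalence at the reference
#'   age, 10-year MM mortality, and deaths per 100,000.
#' @export
higher_risk_sensitivity <- function(models, multipliers = c(2, 4),
                                    delta_a = c(1, 2, 4, 8),
                                    r = c(0.1, 0.61, 1), a0 = 50,
                                    reference_age = 60, horizon = 10) {
  stopifnot(all(multipliers >= 1))
  lt <- models$life_table
  rows <- list()
  for (m in multipliers) {
    inc <- calibrate_incidence(
      lt, targets = list(prevalence_50plus_lowrisk = NULL,
                         lifetime_risk_ratio = m),
      g = models$incidence$g, a_min = models$incidence$a_min,
      progression = models$progression, disease = models$disease
    )
    # keep the existing low-risk scale; only the high-risk scale moves
    inc2 <- incidence_model(
      k = c(low = unname(models$incidence$k["low"]),
            high = unname(inc$k["high"])),
      g = models$incidence$g, a_min = models$incidence$a_min,
      max_age = max(lt$age)
    )
    mods <- models
    mods$incidence <- inc2
    for (d in delta_a) for (rr in r) {
      pol <- screening_policy(a0, d, rr)
      hi <- evolve_cohort(mods, pol, "high")
      i_ref <- hi$age == reference_age
      prev_det <- sum(hi$D[i_ref, ]) / hi$alive[i_ref]
      fmm <- post_detection_survival(mods, reference_age, r = rr,
                                     horizon = horizon)$F_mm[horizon + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        multiplier = m, delta_a = d, r = rr,
        mm_fraction = sum(hi$M) / sum(hi$alive),
        prevalence_detected = prev_det, f_mm = fmm,
        deaths_per_100k = mm_deaths_per_100k(prev_det, fmm)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
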