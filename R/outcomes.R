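# Outcome statistics: medians, lead-time bias, diagnosis-age distributions,
# MM-specific mortality summaries. Each works from either the analytic
# survival curves or a simulation's agent table, using the same definitions:
# survival is indexed from MGUS *detection* in screened cohorts and from MM
# *diagnosis* in unscreened cohorts, and other-cause deaths count as events
# (overall survival) unless the cause-specific variant is requested.

#' Median survival
#'
#' For an analytic `survival_curve`, the smallest whole year at which
#' survival has dropped to one half or below (ties broken downward). For a
#' vector of observed event times, the empirical median.
#'
#' @param x A `survival_curve` (from [post_detection_survival()]) or a
#'   numeric vector of survival times in years.
#' @return Median survival in years.
#' @export
median_survival <- function(x) {
  if (inherits(x, "survival_curve")) {
    i <- which(x$S <= 0.5)
    if (!length(i)) stop("survival never reaches 0.5 within the curve's horizon")
    return(x$time[i[1]])
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop("no uncensored survival times; median undefined")
  stats::median(x)
}

#' Survival times from a simulation
#'
#' Years from the index event to death for every agent with both recorded.
#' The index event is MGUS detection (`from = "detection"`, the screened
#' reading) or MM diagnosis (`from = "mm"`, the unscreened reading).
#' Restricting `index_years` to a window well before the end of the run
#' avoids censoring the slow deaths (agents detected near the end of the
#' simulation and still alive are excluded, not treated as events).
#'
#' @param sim An `mgus_sim` object.
#' @param from `"detection"` or `"mm"`.
#' @param index_years Year window `c(from, to)` in which the index event must
#'   fall; defaults to `burn_in` .. `years - 60` so essentially every indexed
#'   agent's death is observed (no one survives past age 110).
#' @param cause `"any"` (overall survival) or `"mm"` (only MM deaths count;
#'   others return `NA` and are dropped by [median_survival()]).
#' @return Numeric vector of survival times in years.
#' @export
survival_times <- function(sim, from = c("detection", "mm"),
                           index_years = NULL, cause = c("any", "mm")) {
  stopifnot(inherits(sim, "mgus_sim"))
  from <- match.arg(from)
  cause <- match.arg(cause)
  if (is.null(index_years)) index_years <- c(sim$burn_in, max(sim$burn_in, sim$years - 60))
  ag <- sim$agents
  idx_year <- if (from == "detection") ag$detected_year else ag$mm_year
  keep <- !is.na(idx_year) & idx_year >= index_years[1] & idx_year <= index_years[2]
  t_death <- ag$death_year[keep] - idx_year[keep]
  if (cause == "mm") t_death[ag$death_cause[keep] != "mm"] <- NA
  t_death
}

#' Lead-time bias
#'
#' Difference between the median survival measured from MGUS detection in a
#' screened population and the median survival measured from MM diagnosis in
#' an unscreened population. Earlier (precursor) detection inflates apparent
#' survival by exactly this amount even when screening changes nothing
#' (`r = 1`).
#'
#' @param screened_median Median years from MGUS detection to death.
#' @param control_median Median years from MM diagnosis to death.
#' @return Lead-time bias in years.
#' @export
lead_time_bias <- function(screened_median, control_median) {
  stopifnot(is.finite(screened_median), is.finite(control_median))
  screened_median - control_median
}

#' Age distribution of MM diagnoses
#'
#' Normalised histogram of age at progression to MM, the quantity drawn as
#' violin widths in screening-strategy comparisons. Screening with effective
#' intervention (`r < 1`) carves a trough just above the start age `a0`,
#' deeper for smaller `r`.
#'
#' @param x An `mgus_sim`, an event-log data frame with `event == "progression"`
#'   rows, or a numeric vector of ages at MM diagnosis.
#' @param min_year Discard events before this year (defaults to the
#'   simulation's burn-in when available).
#' @return Data frame with columns `age` and `weight`; weights sum to 1.
#' @export
age_at_mm_distribution <- function(x, min_year = NULL) {
  ages <- if (inherits(x, "mgus_sim")) {
    if (is.null(min_year)) min_year <- x$burn_in
    ok <- !is.na(x$agents$mm_year) & x$agents$mm_year >= min_year
    x$agents$mm_year[ok] - x$agents$birth_year[ok]
  } else if (is.data.frame(x)) {
    x$age[x$event == "progression"]
  } else {
    x
  }
  ages <- ages[!is.na(ages)]
  if (!length(ages)) stop("no MM diagnosis events")
  tab <- table(factor(ages, levels = sort(unique(ages))))
  data.frame(age = as.integer(names(tab)),
             weight = as.numeric(tab) / sum(tab))
}

#' MM-specific deaths per 100,000 screened
#'
#' Product of the detected-MGUS prevalence at the reference age and the
#' 10-year (or other horizon) cumulative MM-specific mortality after
#' detection, scaled to deaths per 100,000 individuals.
#'
#' @param prevalence_detected Fraction of individuals at the reference age in
#'   the detected-MGUS state, in `[0, 1]`.
#' @param f_mm Cumulative MM-specific mortality over the follow-up horizon,
#'   in `[0, 1]`.
#' @param scale Population scale (default 100,000).
#' @return Expected MM-specific deaths per `scale` individuals.
#' @export
mm_deaths_per_100k <- function(prevalence_detected, f_mm, scale = 1e5) {
  stopifnot(all(prevalence_detected >= 0), all(prevalence_detected <= 1),
            all(f_mm >= 0), all(f_mm <= 1))
  prevalence_detected * f_mm * scale
}

#' Reduction of MM-specific mortality by progression-risk reduction
#'
#' Percentage by which the cumulative MM-specific mortality after MGUS
#' detection at a fixed age is reduced under intervention strength `r`,
#' relative to no intervention (`r = 1`). Because the post-detection dynamics
#' depend only on the detection age and `r` — not on when screening started
#' or how often it occurs — this is the policy-invariant mortality measure.
#' In the small-rate regime the reduction is approximately `100 * (1 - r)`.
#'
#' @param r Progression-risk reduction factor in `[0, 1]` (vectorised).
#' @param models An [mgus_models()] bundle.
#' @param age_at_detection Age at MGUS detection (default 60).
#' @param horizon Follow-up horizon in years (default 10).
#' @return Percentage reduction(s) of `F_mm(horizon)`.
#' @export
mortality_reduction <- function(r, models, age_at_detection = 60, horizon = 10) {
  stopifnot(all(r >= 0), all(r <= 1))
  f1 <- post_detection_survival(models, age_at_detection, r = 1, horizon = horizon)
  base <- f1$F_mm[horizon + 1L]
  vapply(r, function(ri) {
    fi <- post_detection_survival(models, age_at_detection, r = ri,
                                  horizon = horizon)
    100 * (1 - fi$F_mm[horizon + 1L] / base)
  }, numeric(1))
}
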