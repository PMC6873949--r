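#' Screening policy
#'
#' A screening scenario is specified by three parameters: the age at which an
#' individual receives the first screen (`a0`), the mean spacing between
#' follow-up screens (`delta_a`), and the multiplicative progression-risk
#' reduction `r` applied to the annual MGUS-to-MM progression probability once
#' MGUS has been detected. Each eligible individual is screened each year with
#' probability `1/delta_a`, so the mean inter-screen time is `delta_a` years.
#'
#' `r = 1` means detection has no effect on progression (the reference used for
#' all relative prevalence measures); `r = 0` blocks progression completely.
#'
#' @param a0 Age (integer years) at first screening eligibility. `Inf` encodes
#'   "no screening".
#' @param delta_a Mean inter-screen interval in years; must be `>= 1`.
#' @param r Progression-risk reduction factor in `[0, 1]` applied after a
#'   positive screen.
#' @return An object of class `screening_policy`.
#' @seealso [screen_probability()], [no_screening()]
#' @examples
#' pol <- screening_policy(a0 = 50, delta_a = 1, r = 0.61)
#' screen_probability(c(49, 50, 70), pol)
#' @export
screening_policy <- function(a0 = 50, delta_a = 1, r = 0.61) {
  stopifnot(length(a0) == 1, length(delta_a) == 1, length(r) == 1)
  if (!is.numeric(a0) || (is.finite(a0) && a0 < 0)) {
    stop("`a0` must be a nonnegative age in years (or Inf for no screening)")
  }
  if (!is.numeric(delta_a) || is.na(delta_a) || delta_a < 1) {
    stop("`delta_a` must be >= 1 year")
  }
  if (!is.numeric(r) || is.na(r) || r < 0 || r > 1) {
    stop("`r` must lie in [0, 1]")
  }
  structure(
    list(a0 = a0, delta_a = delta_a, r = r),
    class = "screening_policy"
  )
}

#' No-screening policy
#'
#' Convenience constructor for the unscreened scenario: nobody is ever
#' eligible, and `r` is irrelevant (kept at 1).
#'
#' @return A `screening_policy` with `a0 = Inf`.
#' @export
no_screening <- function() screening_policy(a0 = Inf, delta_a = 1, r = 1)

#' @export
print.screening_policy <- function(x, ...) {
  if (is.infinite(x$a0)) {
    cat("<screening_policy> no screening\n")
  } else {
    cat(sprintf(
      "<screening_policy> a0 = %g y, delta_a = %g y (annual screen prob %.4g), r = %g\n",
      x$a0, x$delta_a, 1 / x$delta_a, x$r
    ))
  }
  invisible(x)
}

#' Annual screening probability at a given age
#'
#' Returns `1/delta_a` for ages at or above the start age `a0` and 0 below it.
#'
#' @param age Vector of ages in years.
#' @param policy A [screening_policy()].
#' @return Vector of per-year screening probabilities.
#' @export
screen_probability <- function(age, policy) {
  stopifnot(inherits(policy, "screening_policy"), all(age >= 0))
  ifelse(age >= policy$a0, 1 / policy$delta_a, 0)
}

#' Progression model for MGUS to MM
#'
#' Two modes are supported. In `constant` mode every MGUS carrier progresses
#' to MM with the same annual probability `p` (default 0.01/year). In
#' `evolving` mode the unconditional probability of progressing after exactly
#' `t` years with MGUS is the geometric mass `beta * (1 - beta)^t`; its
#' conditional per-year hazard is constant and equal to `beta`, so constant
#' mode is recovered exactly by setting `beta = p`. An optional truncated
#' normal mixing distribution over `p` supports studies of between-individual
#' progression-rate variability.
#'
#' @param mode `"constant"` or `"evolving"`.
#' @param p Annual progression probability (constant mode), in `[0, 1]`.
#' @param beta Geometric parameter (evolving mode), in `[0, 1]`.
#' @param mixing Optional list with elements `mean` and `sd` describing a
#'   normal distribution for `p`, truncated to `[0, 1]`.
#' @return An object of class `progression_model`.
#' @examples
#' progression_model()                                  # constant, p = 0.01
#' progression_model("evolving", beta = 0.07)           # evolving MGUS
#' @export
progression_model <- function(mode = c("constant", "evolving"), p = 0.01,
                              beta = NULL, mixing = NULL) {
  mode <- match.arg(mode)
  if (mode == "evolving") {
    if (is.null(beta)) stop("evolving mode requires `beta`")
    if (!is.numeric(beta) || beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]")
  }
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (!is.null(mixing)) {
    if (!is.list(mixing) || is.null(mixing$mean) || is.null(mixing$sd)) {
      stop("`mixing` must be a list with elements `mean` and `sd`")
    }
    if (mixing$sd < 0) stop("`mixing$sd` must be >= 0")
  }
  structure(
    list(mode = mode, p = p, beta = beta, mixing = mixing),
    class = "progression_model"
  )
}

#' @export
print.progression_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<progression_model> constant, p = %g / year", x$p))
  } else {
    cat(sprintf("<progression_model> evolving, beta = %g", x$beta))
  }
  if (!is.null(x$mixing)) {
    cat(sprintf(" | mixing: truncated normal(mean %g, sd %g) on [0, 1]",
                x$mixing$mean, x$mixing$sd))
  }
  cat("\n")
  invisible(x)
}

#' Per-year conditional progression probability
#'
#' The annual probability that an MGUS carrier of the given disease duration
#' progresses to MM this year. For the geometric (evolving) family the
#' conditional hazard is constant in duration and equal to `beta`; for the
#' constant family it is `p`. Detected individuals progress at the reduced
#' rate `r * hazard`, where `r` comes from the screening policy.
#'
#' @param duration Integer years since MGUS onset (vectorised).
#' @param detected Logical; has this individual had a positive screen?
#' @param model A [progression_model()].
#' @param policy A [screening_policy()]; only its `r` is used. Defaults to
#'   `r = 1` (no intervention) when omitted.
#' @return Vector of per-year progression probabilities.
#' @export
progression_probability <- function(duration, detected = FALSE, model = progression_model(),
                                    policy = NULL) {
  stopifnot(inherits(model, "progression_model"), all(duration >= 0))
  hazard <- switch(model$mode,
    constant = rep(model$p, length(duration)),
    evolving = {
      # conditional hazard of the geometric mass beta*(1-beta)^t given survival
      # to duration t: beta*(1-beta)^t / (1-beta)^t = beta, for all t
      rep(model$beta, length(duration))
    }
  )
  r <- if (is.null(policy)) 1 else policy$r
  det <- rep_len(as.logical(detected), length(duration))
  hazard[det] <- r * hazard[det]
  hazard
}

#' Unconditional geometric progression mass
#'
#' Probability that an MGUS carrier progresses after exactly `t` years, under
#' the geometric (evolving) family: `beta * (1 - beta)^t`. Summed over all
#' durations this is 1 for any `beta` in (0, 1] (absent competing risks).
#'
#' @param beta Geometric parameter in `[0, 1]`.
#' @param t Integer duration(s) since onset, `>= 0`.
#' @return `beta * (1 - beta)^t`, vectorised over `t`.
#' @seealso [cumulative_progression()]
#' @export
geometric_progression_mass <- function(beta, t) {
  stopifnot(beta >= 0, beta <= 1, all(t >= 0))
  beta * (1 - beta)^t
}

#' Cumulative progression fraction by follow-up time
#'
#' Cumulative probability of having progressed by `T` years of follow-up under
#' the geometric family: `1 - (1 - beta)^T`, i.e. progression opportunities at
#' durations `0 .. T-1`.
#'
#' @param beta Geometric parameter in `[0, 1]`.
#' @param T Follow-up time(s) in whole years.
#' @return Cumulative progression fraction(s).
#' @export
cumulative_progression <- function(beta, T) {
  stopifnot(beta >= 0, beta <= 1, all(T >= 0))
  1 - (1 - beta)^T
}

#' Draw individual progression rates from a truncated normal
#'
#' Samples per-individual annual progression probabilities from a normal
#' distribution truncated to `[0, 1]`, used to study the effect of
#' between-individual variability in progression rate on MM-specific
#' mortality. Sampling is by inverse-CDF, so `sd = 0` returns the mean
#' exactly.
#'
#' @param mixing List with `mean` and `sd` (see [progression_model()]).
#' @param n Number of draws.
#' @return Vector of `n` progression probabilities in `[0, 1]`.
#' @export
sample_progression_rate <- function(mixing, n = 1) {
  stopifnot(is.list(mixing), !is.null(mixing$mean), !is.null(mixing$sd),
            mixing$sd >= 0)
  if (mixing$sd == 0) return(rep(mixing$mean, n))
  lo <- stats::pnorm(0, mixing$mean, mixing$sd)
  hi <- stats::pnorm(1, mixing$mean, mixing$sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mixing$mean, mixing$sd)
}

#' MM disease rates
#'
#' MM carries a fixed annual excess death probability `q_mm` on top of (by
#' default) the age-dependent background mortality, combined as competing
#' risks on the probability scale: an MM patient dies of MM with probability
#' `q_mm`, and otherwise of background causes with probability `mu(a)`.
#'
#' @param q_mm Fixed annual MM-specific death probability in `[0, 1]`.
#' @param combine_background If `TRUE` (default) MM patients are additionally
#'   exposed to background mortality; if `FALSE` the MM death rate replaces
#'   it.
#' @return An object of class `disease_rates`.
#' @seealso [calibrate_mm_death_rate()]
#' @export
disease_rates <- function(q_mm, combine_background = TRUE) {
  if (!is.numeric(q_mm) || q_mm < 0 || q_mm > 1) stop("`q_mm` must lie in [0, 1]")
  structure(
    list(q_mm = q_mm, combine_background = isTRUE(combine_background)),
    class = "disease_rates"
  )
}

#' @export
print.disease_rates <- function(x, ...) {
  cat(sprintf(
    "<disease_rates> q_mm = %.4f / year (%s background mortality)\n",
    x$q_mm, if (x$combine_background) "competing with" else "replacing"
  ))
  invisible(x)
}

# state codes shared by both engines (integer-coded for speed in the
# stochastic engine); exported as a named vector for users reading agent
# tables and event logs

#' Disease state labels
#'
#' Integer codes used for the Markov chain states: healthy, undetected MGUS,
#' detected MGUS, MM, death from other causes, death from MM. Transitions run
#' only forward along the chain (no reversion), and death is reachable from
#' every living state.
#'
#' @format Named integer vector.
#' @export
mgus_states <- c(
  HEALTHY = 0L, MGUS_UNDETECTED = 1L, MGUS_DETECTED = 2L,
  MM = 3L, DEAD_OTHER = 4L, DEAD_MM = 5L
)
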