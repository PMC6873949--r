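# Deterministic age- and duration-structured engine.
#
# The recursion is the exact expectation of the stochastic chain under the
# same within-year event order (death -> onset -> screening -> progression ->
# age/duration increment), so simulation-vs-analytic agreement is a
# correctness check of both engines rather than an approximation. One birth
# cohort is evolved from age 0 to 110; because the model population is
# stationary (constant annual births), population-level prevalences are
# cohort sums with equal age weights.

# Core recursion for a single risk group / sex stratum.
#   mu      : background death prob by age (length A+1)
#   lambda  : MGUS onset prob by age
#   s       : screening prob by age (already 0 below a0)
#   h_u/h_d : progression hazard by MGUS duration 0..A (undetected/detected)
#   q_mm    : annual MM death prob; combine: MM also exposed to mu
cohort_recursion <- function(mu, lambda, s, h_u, h_d, q_mm,
                             combine_background = TRUE) {
  A <- length(mu) - 1L
  nt <- A + 1L
  H <- numeric(A + 1L); M <- numeric(A + 1L)
  U <- matrix(0, A + 1L, nt); D <- matrix(0, A + 1L, nt)
  dead_other <- numeric(A + 1L); dead_mm <- numeric(A + 1L)
  onset_flow <- numeric(A + 1L); det_flow <- numeric(A + 1L)
  mm_flow <- numeric(A + 1L)
  h <- 1; u <- numeric(nt); d <- numeric(nt); m <- 0
  cum_do <- 0; cum_dm <- 0
  mu_mm <- if (combine_background) mu else rep(0, A + 1L)
  for (a in 0:A) {
    i <- a + 1L
    H[i] <- h; U[i, ] <- u; D[i, ] <- d; M[i] <- m
    dead_other[i] <- cum_do; dead_mm[i] <- cum_dm
    # 1. death: background for non-MM; for MM the MM cause fires first
    non_mm <- h + sum(u) + sum(d)
    cum_do <- cum_do + non_mm * mu[i] + m * (1 - q_mm) * mu_mm[i]
    cum_dm <- cum_dm + m * q_mm
    h <- h * (1 - mu[i]); u <- u * (1 - mu[i]); d <- d * (1 - mu[i])
    m <- m * (1 - q_mm) * (1 - mu_mm[i])
    # 2. MGUS onset (new carriers sit out screening/progression this year)
    new <- h * lambda[i]; h <- h - new
    onset_flow[i] <- new
    # 3. screening
    det <- u * s[i]; u <- u - det; d <- d + det
    det_flow[i] <- sum(det)
    # 4. progression
    prog <- sum(u * h_u) + sum(d * h_d)
    u <- u * (1 - h_u); d <- d * (1 - h_d)
    m <- m + prog
    mm_flow[i] <- prog
    # 5. age/duration shift; new onsets enter at duration 0
    u <- c(new, u[-nt]); d <- c(0, d[-nt])
  }
  mgus <- rowSums(U) + rowSums(D)
  list(age = 0:A, H = H, U = U, D = D, M = M,
       mgus = mgus, alive = H + mgus + M,
       dead_other = dead_other, dead_mm = dead_mm,
       onset_flow = onset_flow, det_flow = det_flow, mm_flow = mm_flow)
}

#' Evolve a birth cohort deterministically
#'
#' Runs the age- and duration-structured recursion for one risk group from
#' birth to the maximum age, applying the same annual probabilities and
#' within-year event order as the stochastic engine, in expectation. Duration
#' since MGUS onset is tracked explicitly so duration-dependent (evolving)
#' progression and detection bookkeeping are exact.
#'
#' @param models An [mgus_models()] bundle.
#' @param policy A [screening_policy()]; use [no_screening()] for the
#'   unscreened baseline.
#' @param group `"low"` or `"high"` risk.
#' @param screen_prob Optional override of the annual screening probability:
#'   a scalar (applied at ages `>= policy$a0`) or a full by-age vector. Used
#'   by the budgeted-allocation machinery.
#' @return An object of class `cohort_arrays`: per-age occupancy fractions of
#'   the birth cohort — `H` (healthy), duration-resolved matrices `U`
#'   (undetected MGUS) and `D` (detected MGUS), `M` (MM), `mgus = rowSums(U +
#'   D)`, `alive`, cumulative `dead_other`/`dead_mm`, and the per-year event
#'   flows `onset_flow`, `det_flow`, `mm_flow`. At every age `alive + dead = 1`
#'   up to floating-point error.
#' @examples
#' m <- mgus_models(n = 1000)
#' co <- evolve_cohort(m, screening_policy(50, 1, 0.61), group = "low")
#' max(abs(co$alive + co$dead_other + co$dead_mm - 1))
#' @export
evolve_cohort <- function(models, policy = no_screening(), group = "low",
                          screen_prob = NULL) {
  stopifnot(inherits(models, "mgus_models"), inherits(policy, "screening_policy"))
  lt <- models$life_table
  A <- max(lt$age)
  ages <- lt$age
  s <- if (is.null(screen_prob)) {
    screen_probability(ages, policy)
  } else if (length(screen_prob) == 1L) {
    ifelse(ages >= policy$a0, screen_prob, 0)
  } else {
    stopifnot(length(screen_prob) == A + 1L)
    screen_prob
  }
  h_u <- progression_probability(0:A, FALSE, models$progression)
  h_d <- progression_probability(0:A, TRUE, models$progression, policy)
  out <- cohort_recursion(
    mu = lt$mu, lambda = lambda_vector(models$incidence, group), s = s,
    h_u = h_u, h_d = h_d, q_mm = models$disease$q_mm,
    combine_background = models$disease$combine_background
  )
  structure(c(out, list(group = group, policy = policy)),
            class = "cohort_arrays")
}

#' @export
print.cohort_arrays <- function(x, ...) {
  cat(sprintf(
    "<cohort_arrays> %s risk, ages 0..%d; MGUS prevalence >=50: %.4f; MM fraction: %.3e\n",
    x$group, max(x$age), mgus_prevalence(x, 50), mm_population_fraction(x)
  ))
  invisible(x)
}

#' Population MM fraction
#'
#' Fraction of the (stationary) population in the MM state, all ages. For a
#' single `cohort_arrays` the stationary population is the superposition of
#' identical birth cohorts, so the fraction is `sum(w * M) / sum(w * alive)`
#' with equal age weights by default. For an [mgus_models()] bundle the
#' low- and high-risk groups are evolved and mixed by the high-risk fraction
#' `f_high`.
#'
#' @param x A `cohort_arrays` or an `mgus_models` bundle.
#' @param ... Passed on to methods.
#' @return MM population fraction (dimensionless).
#' @export
mm_population_fraction <- function(x, ...) UseMethod("mm_population_fraction")

#' @rdname mm_population_fraction
#' @param weights Optional per-age weights (default: equal, the stationary
#'   superposition of birth cohorts).
#' @export
mm_population_fraction.cohort_arrays <- function(x, weights = NULL, ...) {
  w <- if (is.null(weights)) rep(1, length(x$age)) else weights
  stopifnot(length(w) == length(x$age))
  sum(w * x$M) / sum(w * x$alive)
}

#' @rdname mm_population_fraction
#' @param policy A [screening_policy()] applied to both groups.
#' @export
mm_population_fraction.mgus_models <- function(x, policy = no_screening(), ...) {
  f <- x$population$f_high
  lo <- evolve_cohort(x, policy, "low")
  hi <- evolve_cohort(x, policy, "high")
  (f * sum(hi$M) + (1 - f) * sum(lo$M)) /
    (f * sum(hi$alive) + (1 - f) * sum(lo$alive))
}

#' MGUS prevalence above an age cutoff
#'
#' @param x A `cohort_arrays` or `mgus_models` object.
#' @param min_age Lower age cutoff (default 50, the standard reporting age).
#' @param ... Passed on to methods.
#' @return Fraction of living individuals aged `>= min_age` carrying MGUS
#'   (detected or not).
#' @export
mgus_prevalence <- function(x, min_age = 50, ...) UseMethod("mgus_prevalence")

#' @export
mgus_prevalence.cohort_arrays <- function(x, min_age = 50, ...) {
  i <- x$age >= min_age
  sum(x$mgus[i]) / sum(x$alive[i])
}

#' @rdname mgus_prevalence
#' @param policy Screening policy (default none).
#' @param group Risk group for which prevalence is reported.
#' @export
mgus_prevalence.mgus_models <- function(x, min_age = 50,
                                        policy = no_screening(),
                                        group = "low", ...) {
  mgus_prevalence(evolve_cohort(x, policy, group), min_age)
}

#' Relative MM prevalence of a screening policy
#'
#' Population MM fraction under `policy`, expressed as a percentage of the
#' fraction under the same policy with `r = 1` (screening without any effect
#' on progression — the baseline all results are reported against). 100 means
#' no change; lower is better.
#'
#' @param policy A [screening_policy()].
#' @param models An [mgus_models()] bundle.
#' @return Percentage in (0, 100].
#' @export
relative_mm_prevalence <- function(policy, models) {
  baseline <- screening_policy(policy$a0, policy$delta_a, r = 1)
  denom <- mm_population_fraction(models, baseline)
  if (denom <= 0) stop("baseline MM fraction is zero; relative prevalence undefined")
  100 * mm_population_fraction(models, policy) / denom
}

#' Competing-risk survival after MGUS detection
#'
#' Evolves a cohort of individuals all detected with MGUS at the same age:
#' each year they may die of background causes, progress to MM at the reduced
#' rate `r * hazard`, and once in MM die of MM (rate `q_mm`) or of other
#' causes. Returns overall survival together with the cause-specific
#' cumulative incidence functions. By construction the curves depend only on
#' the detection age and `r`, not on when or how often the population is
#' screened.
#'
#' @param models An [mgus_models()] bundle.
#' @param age_at_detection Age (years) at MGUS detection.
#' @param r Progression-risk reduction factor in `[0, 1]`.
#' @param horizon Number of years to follow the cohort.
#' @param duration_at_detection MGUS duration at detection (matters only for
#'   duration-dependent progression models).
#' @return A data frame of class `survival_curve` with columns `time`
#'   (0..horizon), `S` (overall survival), `F_mm` and `F_other` (cumulative
#'   incidence of MM death and other-cause death). `S + F_mm + F_other = 1`
#'   at every time.
#' @examples
#' m <- mgus_models(n = 1000)
#' sv <- post_detection_survival(m, 60, r = 1, horizon = 10)
#' sv$F_mm[sv$time == 10]    # 10-year MM-specific mortality
#' @export
post_detection_survival <- function(models, age_at_detection, r = 1,
                                    horizon = 40, duration_at_detection = 0) {
  stopifnot(inherits(models, "mgus_models"),
            age_at_detection >= 0, age_at_detection <= max(models$life_table$age),
            r >= 0, r <= 1, horizon >= 0)
  res <- fmm_recursion(models, age_at_detection, r, horizon,
                       duration_at_detection, p_values = NULL)
  structure(
    data.frame(time = 0:horizon, S = res$S, F_mm = res$F_mm, F_other = res$F_other),
    class = c("survival_curve", "data.frame")
  )
}

# Post-detection competing-risk recursion, vectorised over an optional vector
# of progression rates (used by mixed_mortality). With p_values = NULL the
# hazard comes from models$progression.
fmm_recursion <- function(models, age_at_detection, r, horizon,
                          duration_at_detection = 0, p_values = NULL) {
  lt <- models$life_table
  A <- max(lt$age)
  q <- models$disease$q_mm
  mu_mm_on <- models$disease$combine_background
  np <- if (is.null(p_values)) 1L else length(p_values)
  dfrac <- rep(1, np); m <- numeric(np)
  F_mm <- matrix(0, horizon + 1L, np); F_other <- matrix(0, horizon + 1L, np)
  S <- matrix(1, horizon + 1L, np)
  if (horizon > 0) {
    for (k in 1:horizon) {
      age <- min(age_at_detection + k - 1, A)
      i <- age + 1L
      mu <- lt$mu[i]
      mu_mm <- if (mu_mm_on) mu else 0
      t_dur <- duration_at_detection + k - 1
      haz <- if (is.null(p_values)) {
        progression_probability(min(t_dur, A), FALSE, models$progression)
      } else {
        p_values
      }
      # death
      fo <- dfrac * mu + m * (1 - q) * mu_mm
      fm <- m * q
      dfrac <- dfrac * (1 - mu)
      m <- m * (1 - q) * (1 - mu_mm)
      # progression at the reduced rate
      prog <- dfrac * r * haz
      dfrac <- dfrac - prog
      m <- m + prog
      F_mm[k + 1L, ] <- F_mm[k, ] + fm
      F_other[k + 1L, ] <- F_other[k, ] + fo
      S[k + 1L, ] <- dfrac + m
    }
  }
  if (is.null(p_values)) {
    list(S = S[, 1], F_mm = F_mm[, 1], F_other = F_other[, 1])
  } else {
    list(S = S, F_mm = F_mm, F_other = F_other)
  }
}

#' MM-specific mortality under progression-rate variability
#'
#' Distribution of the `horizon`-year cumulative MM-specific mortality
#' `F_mm(horizon)` when the per-individual progression rate `p` is drawn from
#' a truncated normal mixing distribution rather than fixed. Computed either
#' by quadrature over the truncated-normal density or by Monte Carlo using
#' [sample_progression_rate()]. Dispersion shrinks as the risk reduction `r`
#' decreases, because the intervention damps the rate differences.
#'
#' @param models An [mgus_models()] bundle.
#' @param mixing List with `mean` and `sd` of the (pre-truncation) normal.
#' @param age_at_detection Age at MGUS detection.
#' @param horizon Follow-up horizon in years.
#' @param r Progression-risk reduction factor.
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param n_grid Number of quadrature nodes on `[0, 1]`.
#' @param n_draws Number of Monte Carlo draws for `method = "mc"`.
#' @return List with `mean`, `sd`, and (quadrature only) a data frame
#'   `nodes` of progression rates, weights and `F_mm` values.
#' @export
mixed_mortality <- function(models, mixing, age_at_detection = 60, horizon = 10,
                            r = 1, method = c("quadrature", "mc"),
                            n_grid = 801, n_draws = 1e4) {
  method <- match.arg(method)
  stopifnot(is.list(mixing), mixing$sd >= 0)
  if (mixing$sd == 0) {
    f <- fmm_recursion(models, age_at_detection, r, horizon,
                       p_values = mixing$mean)
    return(list(mean = f$F_mm[horizon + 1L, 1], sd = 0, method = "degenerate"))
  }
  if (method == "quadrature") {
    p <- seq(0, 1, length.out = n_grid)
    w <- stats::dnorm(p, mixing$mean, mixing$sd)
    w <- w / sum(w)
    f <- fmm_recursion(models, age_at_detection, r, horizon, p_values = p)
    fT <- f$F_mm[horizon + 1L, ]
    mean_f <- sum(w * fT)
    sd_f <- sqrt(max(0, sum(w * fT^2) - mean_f^2))
    list(mean = mean_f, sd = sd_f, method = method,
         nodes = data.frame(p = p, weight = w, F_mm = fT))
  } else {
    p <- sample_progression_rate(mixing, n_draws)
    f <- fmm_recursion(models, age_at_detection, r, horizon, p_values = p)
    fT <- f$F_mm[horizon + 1L, ]
    list(mean = mean(fT), sd = stats::sd(fT), method = method)
  }
}
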