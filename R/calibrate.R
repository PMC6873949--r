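#' Calibrate the MM death rate to a target median survival
#'
#' Sets the fixed annual MM death probability `q_mm` so that median survival
#' after MM diagnosis matches a target (default 4.5 years, the middle of the
#' 4-to-5-year range used throughout). With no life table the calibration is
#' against the excess-only geometric survival, which has the closed form
#' `q_mm = 1 - 0.5^(1/target)`. If a life table is supplied, background
#' mortality at a representative diagnosis age is folded in as a competing
#' risk, so the combined median hits the target instead.
#'
#' @param target_median Target median post-diagnosis survival in years.
#' @param life_table Optional [build_life_table()]; if supplied, background
#'   mortality at `diagnosis_age` is included in the calibration.
#' @param diagnosis_age Representative age at MM diagnosis used when
#'   `life_table` is given.
#' @return A [disease_rates()] object.
#' @examples
#' calibrate_mm_death_rate(4.5)$q_mm   # 1 - 0.5^(1/4.5) = 0.1428
#' @export
calibrate_mm_death_rate <- function(target_median = 4.5, life_table = NULL,
                                    diagnosis_age = 70) {
  stopifnot(target_median > 0)
  mu_bg <- if (is.null(life_table)) 0 else life_table$mu[diagnosis_age + 1L]
  # continuous median of the combined geometric: ((1-q)(1-mu))^t = 1/2
  q <- 1 - 0.5^(1 / target_median) / (1 - mu_bg)
  if (q <= 0 || q >= 1) stop("target median incompatible with background mortality")
  disease_rates(q_mm = q, combine_background = TRUE)
}

#' Calibrate MGUS incidence to prevalence and lifetime-risk anchors
#'
#' Tunes the exponential-in-age incidence scales so that, in the stationary
#' unscreened population, (1) MGUS prevalence among low-risk individuals aged
#' 50 and over equals the target (default 2%), and (2) the high-risk lifetime
#' risk of developing MGUS is the target multiple (default two-fold) of the
#' low-risk lifetime risk. Each scale is found by 1-D root finding on the
#' deterministic cohort model; lifetime risk is the cumulative probability of
#' an MGUS onset event over a whole life, competing with death.
#'
#' @param life_table A [build_life_table()] object.
#' @param targets List with `prevalence_50plus_lowrisk` (default 0.02) and
#'   `lifetime_risk_ratio` (default 2.0).
#' @param g Exponential age slope of incidence (see [incidence_model()]).
#' @param a_min Onset floor age.
#' @param progression A [progression_model()] (outflow from MGUS affects
#'   prevalence).
#' @param disease A [disease_rates()] object.
#' @return A calibrated [incidence_model()].
#' @export
calibrate_incidence <- function(life_table,
                                targets = list(prevalence_50plus_lowrisk = 0.02,
                                               lifetime_risk_ratio = 2.0),
                                g = 0.035, a_min = 30,
                                progression = progression_model(),
                                disease = calibrate_mm_death_rate()) {
  stopifnot(inherits(life_table, "life_table"))
  prev_target <- targets$prevalence_50plus_lowrisk %||% 0.02
  ratio_target <- targets$lifetime_risk_ratio %||% 2.0
  A <- max(life_table$age)
  ages <- life_table$age
  h <- progression_probability(0:A, FALSE, progression)
  noscreen <- rep(0, A + 1L)
  lam_of <- function(k) ifelse(ages >= a_min, pmin(1, k * exp(g * ages)), 0)
  run <- function(k) {
    cohort_recursion(life_table$mu, lam_of(k), noscreen, h, h,
                     disease$q_mm, disease$combine_background)
  }
  prev50 <- function(k) {
    co <- run(k)
    i <- ages >= 50
    sum(co$mgus[i]) / sum(co$alive[i])
  }
  lifetime <- function(k) sum(run(k)$onset_flow)

  sol <- stats::uniroot(function(lk) prev50(exp(lk)) - prev_target,
                        interval = log(c(1e-12, 1e-2)), tol = 1e-12)
  if (abs(sol$f.root) > 1e-5) {
    stop(sprintf("incidence calibration did not converge: prevalence residual %.2e on bracket [1e-12, 1e-2]",
                 sol$f.root))
  }
  k_low <- exp(sol$root)
  lr_low <- lifetime(k_low)
  sol2 <- stats::uniroot(function(lk) lifetime(exp(lk)) / lr_low - ratio_target,
                         interval = log(c(k_low, min(1e-1, k_low * 50))), tol = 1e-12)
  if (abs(sol2$f.root) > 1e-4) {
    stop(sprintf("incidence calibration did not converge: lifetime-risk residual %.2e",
                 sol2$f.root))
  }
  k_high <- exp(sol2$root)
  incidence_model(k = c(low = k_low, high = k_high), g = g, a_min = a_min,
                  max_age = A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lifetime MGUS risk
#'
#' Cumulative probability that a newborn ever develops MGUS (sum of onset
#' events over all ages, competing with death), for one risk group under no
#' screening.
#'
#' @param models An [mgus_models()] bundle.
#' @param group `"low"` or `"high"`.
#' @return Lifetime risk (fraction).
#' @export
lifetime_mgus_risk <- function(models, group = "low") {
  sum(evolve_cohort(models, no_screening(), group)$onset_flow)
}

#' Assemble a calibrated model bundle
#'
#' Builds the complete parameter set shared by the stochastic and analytic
#' engines: life table, MGUS incidence (calibrated to the prevalence and
#' lifetime-risk anchors unless supplied), progression model, MM death rate
#' (calibrated to the median-survival anchor unless supplied), and the
#' population configuration. This is the single object every engine and
#' outcome function consumes.
#'
#' @param life_table A [build_life_table()] object (default: parametric).
#' @param incidence An [incidence_model()], or `NULL` to calibrate.
#' @param progression A [progression_model()].
#' @param disease A [disease_rates()], or `NULL` to calibrate.
#' @param n Initial population size for the stochastic engine.
#' @param f_high Fraction of high-risk individuals (default 0.20).
#' @param birth_rate Crude birth rate per capita per year; `NULL` derives the
#'   stationary rate `1 / sum(S(a))` from the life table, which keeps the
#'   simulated population approximately constant.
#' @param incidence_targets Calibration targets passed to
#'   [calibrate_incidence()].
#' @param mm_median_target Target median MM survival in years passed to
#'   [calibrate_mm_death_rate()].
#' @return An object of class `mgus_models`.
#' @examples
#' m <- mgus_models(n = 1000)
#' m
#' @export
mgus_models <- function(life_table = build_life_table(),
                        incidence = NULL,
                        progression = progression_model(),
                        disease = NULL,
                        n = 1e5, f_high = 0.2, birth_rate = NULL,
                        incidence_targets = list(prevalence_50plus_lowrisk = 0.02,
                                                 lifetime_risk_ratio = 2.0),
                        mm_median_target = 4.5) {
  stopifnot(inherits(life_table, "life_table"),
            inherits(progression, "progression_model"))
  if (is.null(disease)) disease <- calibrate_mm_death_rate(mm_median_target)
  stopifnot(inherits(disease, "disease_rates"))
  if (is.null(incidence)) {
    incidence <- calibrate_incidence(life_table, incidence_targets,
                                     progression = progression,
                                     disease = disease)
  }
  stopifnot(inherits(incidence, "incidence_model"))
  population <- population_config(n = n, f_high = f_high,
                                  birth_rate = birth_rate,
                                  life_table = life_table)
  structure(
    list(life_table = life_table, incidence = incidence,
         progression = progression, disease = disease,
         population = population),
    class = "mgus_models"
  )
}

#' @export
print.mgus_models <- function(x, ...) {
  cat("<mgus_models>\n")
  cat("  "); print(x$life_table)
  cat("  "); print(x$incidence)
  cat("  "); print(x$progression)
  cat("  "); print(x$disease)
  cat(sprintf("  population: n = %g, f_high = %g, birth rate = %.4f / capita / y\n",
              x$population$n, x$population$f_high, x$population$birth_rate))
  invisible(x)
}
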