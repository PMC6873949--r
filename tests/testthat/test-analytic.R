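# Deterministic cohort recursion and post-detection competing risks.

test_that("cohort mass is conserved to 1e-10 at every age", {
  m <- cached_models()
  policies <- list(no_screening(), screening_policy(50, 1, 0.61),
                   screening_policy(45, 8, 0))
  for (pol in policies) for (g in c("low", "high")) {
    co <- evolve_cohort(m, pol, g)
    total <- co$H + rowSums(co$U) + rowSums(co$D) + co$M +
      co$dead_other + co$dead_mm
    expect_lt(max(abs(total - 1)), 1e-10)
    expect_true(all(co$H >= 0 & co$U >= 0 & co$D >= 0 & co$M >= 0))
  }
  # evolving mode conserves too
  me <- with_progression(m, progression_model("evolving", beta = 0.07))
  co <- evolve_cohort(me, screening_policy(50, 2, 0.5), "low")
  total <- co$H + rowSums(co$U) + rowSums(co$D) + co$M + co$dead_other + co$dead_mm
  expect_lt(max(abs(total - 1)), 1e-10)
})

test_that("zero incidence means no MGUS and no MM ever", {
  m0 <- zero_incidence_models()
  co <- evolve_cohort(m0, screening_policy(50, 1, 0.1), "low")
  expect_equal(max(co$mgus), 0)
  expect_equal(max(co$M), 0)
})

test_that("screening with r = 1 is inert: occupancy equals no screening elementwise", {
  m <- cached_models()
  base <- evolve_cohort(m, no_screening(), "low")
  for (pol in list(screening_policy(45, 1, 1), screening_policy(65, 8, 1))) {
    co <- evolve_cohort(m, pol, "low")
    expect_lt(max(abs(co$M - base$M)), 1e-10)
    expect_lt(max(abs(co$mgus - base$mgus)), 1e-10)
    expect_lt(max(abs(co$alive - base$alive)), 1e-10)
  }
  expect_equal(relative_mm_prevalence(screening_policy(50, 1, 1), m), 100)
})

test_that("MM prevalence is monotone in p, r and delta_a", {
  m <- cached_models()
  # nondecreasing in progression rate
  fr <- vapply(c(0.005, 0.01, 0.02), function(p) {
    mm_population_fraction(with_progression(m, progression_model(p = p)))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # nonincreasing in r at fixed policy
  fr <- vapply(c(0, 0.3, 0.61, 1), function(r) {
    mm_population_fraction(m, screening_policy(50, 1, r))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # nondecreasing in delta_a for r < 1
  fr <- vapply(c(1, 2, 4, 8), function(d) {
    mm_population_fraction(m, screening_policy(50, d, 0.61))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("evolving mode with beta = p reproduces constant mode exactly", {
  m <- cached_models()
  me <- with_progression(m, progression_model("evolving", beta = m$progression$p))
  pol <- screening_policy(50, 2, 0.61)
  a <- evolve_cohort(m, pol, "high")
  b <- evolve_cohort(me, pol, "high")
  expect_identical(a$M, b$M)
  expect_identical(a$U, b$U)
  expect_identical(a$D, b$D)
})

test_that("post-detection survival is a proper competing-risk decomposition", {
  m <- cached_models()
  sv <- post_detection_survival(m, 60, r = 0.61, horizon = 30)
  expect_equal(sv$S[1], 1)
  expect_equal(sv$F_mm[1], 0)
  expect_true(all(diff(sv$S) <= 0))
  expect_true(all(diff(sv$F_mm) >= 0))
  expect_lt(max(abs(sv$S + sv$F_mm + sv$F_other - 1)), 1e-10)
  # blocked pathway: no MM deaths at r = 0
  sv0 <- post_detection_survival(m, 60, r = 0, horizon = 30)
  expect_equal(max(sv0$F_mm), 0)
  # F_mm decreases with r, increases with p
  f <- function(mod, r) post_detection_survival(mod, 60, r, 10)$F_mm[11]
  expect_gt(f(m, 1), f(m, 0.61))
  expect_gt(f(with_progression(m, progression_model(p = 0.02)), 1), f(m, 1))
})

test_that("post-detection mortality does not depend on how the cohort was screened", {
  # the curve is a function of detection age and r only; policies with
  # different a0/delta_a that detect someone at 60 imply the same mortality
  m <- cached_models()
  sv1 <- post_detection_survival(m, 60, r = 0.61, horizon = 10)
  sv2 <- post_detection_survival(m, 60, r = 0.61, horizon = 10,
                                 duration_at_detection = 0)
  expect_identical(sv1$F_mm, sv2$F_mm)
  # constant hazard: duration at detection is irrelevant as well
  sv3 <- post_detection_survival(m, 60, r = 0.61, horizon = 10,
                                 duration_at_detection = 12)
  expect_equal(sv1$F_mm, sv3$F_mm)
})

test_that("progression-rate mixing widens mortality, less so under intervention", {
  m <- cached_models()
  mx <- list(mean = 0.01, sd = 0.03)
  d0 <- mixed_mortality(m, list(mean = 0.01, sd = 0), r = 1)
  expect_equal(d0$sd, 0)
  expect_equal(d0$mean, post_detection_survival(m, 60, 1, 10)$F_mm[11])
  q1 <- mixed_mortality(m, mx, r = 1)
  q01 <- mixed_mortality(m, mx, r = 0.1)
  expect_gt(q1$sd, q01$sd)      # dispersion shrinks as r decreases
  # quadrature agrees with Monte Carlo within 3 SE
  set.seed(99)
  mc <- mixed_mortality(m, mx, r = 1, method = "mc", n_draws = 2e4)
  expect_lt(abs(q1$mean - mc$mean), 3 * mc$sd / sqrt(2e4))
})
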