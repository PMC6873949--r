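# Individual-based engine: determinism, degenerate dynamics, conservation,
# common-random-number structure, and agreement with the deterministic
# recursion.

test_that("simulation is reproducible under a fixed seed", {
  m <- cached_models()
  pol <- screening_policy(50, 2, 0.61)
  a <- simulate_population(m, pol, years = 30, seed = 17, n = 2000)
  b <- simulate_population(m, pol, years = 30, seed = 17, n = 2000)
  expect_identical(a$agents, b$agents)
  expect_identical(a$yearly, b$yearly)
  c_ <- simulate_population(m, pol, years = 30, seed = 18, n = 2000)
  expect_false(identical(a$agents, c_$agents))
})

test_that("with zero incidence nobody ever leaves HEALTHY except by death", {
  m0 <- zero_incidence_models()
  sim <- simulate_population(m0, screening_policy(50, 1, 0.1), years = 50,
                             seed = 3, n = 5000)
  expect_true(all(sim$agents$state %in%
                    mgus_states[c("HEALTHY", "DEAD_OTHER")]))
  expect_true(all(is.na(sim$agents$onset_year)))
  expect_equal(sum(sim$yearly$deaths_mm), 0)
})

test_that("an MGUS carrier with p = 1 progresses in exactly one surviving step", {
  m <- cached_models()
  # effectively immortal life table so survival is certain
  m$life_table <- build_life_table(makeham = list(A = 1e-15, G = 0.01, c = 1e-15))
  m <- with_progression(m, progression_model(p = 1))
  ag <- mgusscreen:::agent_table(1L, 60L, 0L, 0L)
  ag$state <- mgus_states[["MGUS_UNDETECTED"]]
  ag$duration <- 3L
  out <- step_year(ag, m, no_screening(), seed = 1, year = 1)
  expect_equal(out$agents$state[1], mgus_states[["MM"]])
  expect_equal(out$agents$mm_age[1], 60)
  expect_true("progression" %in% out$events$event)
})

test_that("population is conserved: initial + births = living + dead", {
  m <- cached_models()
  sim <- simulate_population(m, screening_policy(50, 1, 0.61), years = 60,
                             seed = 9, n = 10000)
  with(sim$yearly, {
    total <- n_alive + dead_other + dead_mm
    expect_equal(total, sim$n0 + cumsum(births))
  })
  # per-agent event ordering respects the chain
  ag <- sim$agents
  has <- function(x) !is.na(x)
  expect_true(all(ag$onset_age[has(ag$onset_age)] >= 30))
  i <- has(ag$onset_age) & has(ag$detected_age)
  expect_true(all(ag$detected_age[i] > ag$onset_age[i]))
  i <- has(ag$detected_age) & has(ag$mm_age)
  expect_true(all(ag$mm_age[i] >= ag$detected_age[i]))
  i <- has(ag$mm_age) & has(ag$death_age)
  expect_true(all(ag$death_age[i] > ag$mm_age[i]))
  # an MM death implies an MM diagnosis
  expect_true(all(has(ag$mm_age[ag$state == mgus_states[["DEAD_MM"]]])))
})

test_that("with r = 1, screening leaves disease trajectories exactly unchanged", {
  # shared per-process RNG streams make the screened and unscreened runs
  # agent-for-agent identical in onset, progression and death when r = 1
  m <- cached_models()
  scr <- simulate_population(m, screening_policy(50, 1, 1), years = 80,
                             seed = 23, n = 3e4)
  ctl <- simulate_population(m, no_screening(), years = 80, seed = 23, n = 3e4)
  expect_identical(scr$agents$onset_year, ctl$agents$onset_year)
  expect_identical(scr$agents$mm_year, ctl$agents$mm_year)
  expect_identical(scr$agents$death_year, ctl$agents$death_year)
  expect_identical(scr$agents$death_cause, ctl$agents$death_cause)
  # but the screened run does detect people
  expect_gt(sum(!is.na(scr$agents$detected_year)), 0)
  expect_equal(sum(!is.na(ctl$agents$detected_year)), 0)
})

test_that("simulated prevalences agree with the deterministic recursion", {
  m <- cached_models()
  sim <- simulate_population(m, no_screening(), years = 120, seed = 31, n = 1e5)
  last <- sim$yearly[sim$yearly$year == 120, ]
  # low-risk MGUS prevalence at ages 50+ near the 2% calibration anchor
  p_hat <- last$mgus50_low / last$alive50_low
  se <- sqrt(0.02 * 0.98 / last$alive50_low)
  expect_lt(abs(p_hat - 0.02), 3 * se)
  # cumulative incident MM events over the post-burn-in window vs the
  # stationary analytic rate (Poisson 3-sigma)
  lo <- evolve_cohort(m, no_screening(), "low")
  hi <- evolve_cohort(m, no_screening(), "high")
  f <- m$population$f_high
  rate <- (f * sum(hi$mm_flow) + (1 - f) * sum(lo$mm_flow)) /
    (f * sum(hi$alive) + (1 - f) * sum(lo$alive))
  window <- sim$yearly$year > 60
  expected <- rate * sum(sim$yearly$n_alive[window])
  observed <- sum(sim$yearly$progressions[window])
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("the event log is consistent with the agent table", {
  m <- cached_models()
  sim <- simulate_population(m, screening_policy(50, 1, 0.61), years = 70,
                             seed = 41, n = 5000)
  log <- event_log(sim)
  expect_setequal(unique(log$event),
                  c("birth", "mgus_onset", "detection", "progression",
                    "death_other", "death_mm"))
  expect_equal(sum(log$event == "birth"), sum(sim$yearly$births))
  expect_equal(sum(log$event == "detection"), sum(sim$yearly$detections))
  expect_equal(sum(log$event == "death_mm"), sum(sim$yearly$deaths_mm))
  # restriction by year window
  late <- event_log(sim, years = c(60, 70))
  expect_true(all(late$year >= 60 & late$year <= 70))
})
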