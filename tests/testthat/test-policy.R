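# Screening policy, progression hazards, and the geometric family.

test_that("screening probability is 1/delta_a above the start age and 0 below", {
  expect_equal(screen_probability(55, screening_policy(50, 1, 1)), 1.0)
  expect_equal(screen_probability(49, screening_policy(50, 1, 1)), 0.0)
  expect_equal(screen_probability(60, screening_policy(50, 4, 1)), 0.25)
  expect_equal(screen_probability(0:110, no_screening()), rep(0, 111))
})

test_that("policy construction rejects invalid parameters", {
  expect_error(screening_policy(delta_a = 0.5), "delta_a")
  expect_error(screening_policy(r = 1.5), "\\[0, 1\\]")
  expect_error(screening_policy(r = -0.1), "\\[0, 1\\]")
  expect_error(screening_policy(a0 = -5), "a0")
})

test_that("detected carriers progress at the reduced rate r * p", {
  pol <- screening_policy(50, 1, r = 0.61)
  expect_equal(progression_probability(5, TRUE, progression_model(p = 0.01), pol),
               0.0061)
  # r = 1 means detection changes nothing, at every duration
  pol1 <- screening_policy(50, 1, r = 1)
  for (mod in list(progression_model(p = 0.02),
                   progression_model("evolving", beta = 0.07))) {
    expect_equal(progression_probability(0:30, TRUE, mod, pol1),
                 progression_probability(0:30, FALSE, mod))
  }
})

test_that("constant-hazard survival matches the direct product oracle", {
  # probability of not progressing over 10 years of MGUS, no competing risk
  h <- progression_probability(0:9, FALSE, progression_model(p = 0.01))
  expect_equal(prod(1 - h), (1 - 0.01)^10)
  expect_equal(prod(1 - h), 0.9044, tolerance = 1e-4)
})

test_that("geometric mass behaves as the geometric distribution", {
  expect_equal(geometric_progression_mass(0.3, 0), 0.3)
  # total mass 1 for beta in (0, 1]
  for (b in c(0.01, 0.07, 0.5, 1)) {
    expect_equal(sum(geometric_progression_mass(b, 0:5000)), 1, tolerance = 1e-9)
  }
  # cumulative closed form vs iterated one-year products
  expect_equal(cumulative_progression(0.07, 20), 1 - 0.93^20)
  expect_equal(cumulative_progression(0.07, 20), 1 - prod(rep(1 - 0.07, 20)))
  expect_equal(cumulative_progression(0.07, 20), 0.7658, tolerance = 1e-4)
})

test_that("evolving mode has constant conditional hazard equal to beta", {
  mod <- progression_model("evolving", beta = 0.07)
  expect_equal(progression_probability(0:50, FALSE, mod), rep(0.07, 51))
  # and the implied unconditional mass is the geometric mass
  surv <- cumprod(c(1, 1 - progression_probability(0:49, FALSE, mod)))
  mass <- surv[1:50] * progression_probability(0:49, FALSE, mod)
  expect_equal(mass, geometric_progression_mass(0.07, 0:49))
})

test_that("truncated-normal progression rates match closed-form moments", {
  expect_equal(sample_progression_rate(list(mean = 0.01, sd = 0), 100),
               rep(0.01, 100))
  set.seed(42)
  x <- sample_progression_rate(list(mean = 0.01, sd = 0.03), 1e5)
  expect_true(all(x >= 0 & x <= 1))
  # closed-form mean of the normal truncated to [0, 1]
  m <- 0.01; s <- 0.03
  a <- (0 - m) / s; b <- (1 - m) / s
  mu_tr <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(x) - mu_tr), 3 * sd(x) / sqrt(length(x)))
})

test_that("all per-year transition probabilities lie in [0, 1]", {
  m <- cached_models()
  pol <- screening_policy(45, 1, 0.1)
  probs <- c(
    m$life_table$mu,
    lambda_low <- mgus_incidence(0:110, "low", model = m$incidence),
    mgus_incidence(0:110, "high", model = m$incidence),
    screen_probability(0:110, pol),
    progression_probability(0:110, FALSE, m$progression),
    progression_probability(0:110, TRUE, m$progression, pol),
    m$disease$q_mm
  )
  expect_true(all(probs >= 0 & probs <= 1))
})
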