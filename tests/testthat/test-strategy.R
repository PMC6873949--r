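# Policy sweeps, budgeted allocation, and the geometric follow-up fit.

test_that("the r = 1 column of a policy sweep is identically 100%", {
  m <- cached_models()
  tab <- sweep_policies(m, a0 = c(45, 65), delta_a = c(1, 8), r = 1)
  expect_equal(tab$relative_mm_prevalence, rep(100, 4), tolerance = 1e-9)
})

test_that("relative prevalence worsens with later start and wider spacing", {
  m <- cached_models()
  tab <- sweep_policies(m, a0 = c(45, 55, 65), delta_a = c(1, 4, 8), r = 0.61)
  for (d in unique(tab$delta_a)) {
    col <- tab[tab$delta_a == d, ]
    expect_true(all(diff(col$relative_mm_prevalence[order(col$a0)]) > 0))
  }
  for (a in unique(tab$a0)) {
    row <- tab[tab$a0 == a, ]
    expect_true(all(diff(row$relative_mm_prevalence[order(row$delta_a)]) > 0))
  }
})

test_that("geometric fit recovers noiseless parameters", {
  # self-consistency at one beta, and the spec'd 2% recovery across scales
  for (b in c(0.005, 0.05, 0.2)) {
    pts <- data.frame(time = c(5, 10, 20, 30),
                      fraction = cumulative_progression(b, c(5, 10, 20, 30)))
    fit <- fit_geometric_progression(pts)
    expect_lt(abs(fit$beta / b - 1), 0.02)
    expect_gt(fit$r_squared, 0.9999)
  }
})

test_that("single-point fit matches the closed-form inversion", {
  fit <- fit_geometric_progression(data.frame(time = 10, fraction = 0.55))
  expect_equal(fit$beta, 1 - 0.45^0.1, tolerance = 1e-6)
})

test_that("packaged follow-up points give the evolving and nonevolving rates", {
  pts <- mgus_followup_points()
  expect_equal(nrow(pts), 4)
  expect_true(all(pts$fraction >= 0 & pts$fraction <= 1))
  # cumulative fractions nondecreasing in time within each subtype
  for (ty in unique(pts$type)) {
    sub <- pts[pts$type == ty, ]
    expect_true(all(diff(sub$fraction[order(sub$time)]) >= 0))
  }
  ev <- fit_geometric_progression(mgus_followup_points("evolving"))
  expect_equal(ev$beta, 0.07, tolerance = 0.01 / 0.07)
  expect_gt(ev$r_squared, 0.97)
  ne <- fit_geometric_progression(mgus_followup_points("nonevolving"))
  # roughly ten-fold below the evolving rate, near the constant p = 0.01
  expect_gt(ne$beta, 0.004)
  expect_lt(ne$beta, 0.012)
})

test_that("degenerate follow-up data are rejected", {
  expect_error(fit_geometric_progression(data.frame(time = c(5, 10),
                                                    fraction = c(0, 0))),
               "degenerate")
  expect_error(fit_geometric_progression(data.frame(time = numeric(0),
                                                    fraction = numeric(0))),
               "at least one")
})

test_that("group MM fractions respond monotonically to the allocation", {
  m <- cached_models()
  pol <- screening_policy(50, 1, 0.1)
  ys <- seq(0, 1, by = 0.25)
  fr <- vapply(ys, function(y) group_mm_fractions(m, pol, y), numeric(2))
  expect_true(all(diff(fr["high", ]) <= 1e-12))  # high falls with y
  expect_true(all(diff(fr["low", ]) >= -1e-12))  # low rises with y
  # y = 0: the high-risk group is effectively unscreened
  noscr <- evolve_cohort(m, no_screening(), "high")
  expect_equal(unname(fr["high", 1]), sum(noscr$M) / sum(noscr$alive),
               tolerance = 1e-12)
  # r = 1: fractions do not depend on y at all
  pol1 <- screening_policy(50, 1, 1)
  f0 <- group_mm_fractions(m, pol1, 0)
  f1 <- group_mm_fractions(m, pol1, 1)
  expect_equal(f0, f1, tolerance = 1e-12)
})

test_that("no equal-prevalence crossing means all screens go to high risk", {
  m <- cached_models()
  expect_equal(optimal_allocation(m, screening_policy(50, 1, 1)), 1)
  expect_equal(optimal_allocation(m, screening_policy(50, 1, 0.61)), 1)
  # strong intervention: an interior crossing exists and equalizes fractions
  ystar <- optimal_allocation(m, screening_policy(50, 1, 0.1))
  expect_true(ystar > 0 && ystar < 1)
  fr <- group_mm_fractions(m, screening_policy(50, 1, 0.1), ystar)
  expect_equal(unname(fr["high"]), unname(fr["low"]), tolerance = 0.02)
  # y* falls further when progression is blocked completely
  expect_lt(optimal_allocation(m, screening_policy(50, 1, 0)), ystar)
})

test_that("higher-risk groups see larger screening effects", {
  m <- cached_models()
  tab <- higher_risk_sensitivity(m, multipliers = c(2, 4),
                                 delta_a = c(1, 8), r = c(0.1, 1), a0 = 50)
  # spread of MM fraction across delta_a (at r = 0.1) grows with risk
  spread <- function(mult) {
    sub <- tab[tab$multiplier == mult & tab$r == 0.1, ]
    diff(range(sub$mm_fraction))
  }
  expect_gt(spread(4), spread(2))
  # deaths per 100k rise with the risk multiplier
  d1 <- tab$deaths_per_100k[tab$multiplier == 2 & tab$delta_a == 1 & tab$r == 1]
  d4 <- tab$deaths_per_100k[tab$multiplier == 4 & tab$delta_a == 1 & tab$r == 1]
  expect_gt(d4, d1)
})
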