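---
title: "Modelling MGUS screening and progression to multiple myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MGUS screening and progression to multiple myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgusscreen)
```

## The model

Monoclonal gammopathy of undetermined significance (MGUS) is the asymptomatic
plasma-cell precursor of multiple myeloma (MM): essentially every MM case
passes through it, it is detectable by a cheap and near-perfect serum test,
and it is carried by roughly 2% of people aged 50 and over. If an
intervention can slow MGUS-to-MM progression, population screening for MGUS
becomes a lever on MM prevalence and mortality. This package models that
lever.

The natural history is a discrete-time Markov chain over whole years with
states healthy, undetected MGUS, detected MGUS, and MM; death (from MM or
from other causes) is reachable from every living state, and no transition
runs backwards. Within a year, events are applied in a fixed order:

1. **death** — background mortality `mu(a)` for everyone; MM patients face
   the fixed MM death probability `q_mm` first and, if they survive it,
   background mortality (competing risks on the probability scale);
2. **MGUS onset** — healthy individuals acquire MGUS with the age- and
   risk-group-specific probability `lambda(a; group)`;
3. **screening** — undetected carriers aged `a0` or older are screened with
   probability `1/delta_a`, and a screen always detects (test sensitivity
   and specificity are idealised to 1; the serum assays this represents are
   reported near 100%/99%);
4. **progression** — carriers progress to MM with annual hazard `p`
   (constant mode) or `beta` (evolving mode), multiplied by `r` once
   detected;
5. ages and MGUS durations increment; births enter at the crude birth rate.

New carriers sit out screening and progression in their onset year, so onset
and detection always fall in different years and the first progression
opportunity comes at duration 0 one year after onset — which makes the
cumulative progression fraction after `T` years of follow-up exactly
`1 - (1 - beta)^T`.

A screening policy is the triple `(a0, delta_a, r)`: start age, mean
inter-screen interval (each eligible person is screened each year with
probability `1/delta_a`), and the multiplicative progression-risk reduction
earned by detection. `r = 1` — detection with no consequence — is the
baseline against which every relative prevalence is reported, which removes
the (historically unstable) absolute MGUS prevalence estimates from the
comparison.

## Two engines, one parameter bundle

`simulate_population()` runs the chain for every individual in an
age-structured population. `evolve_cohort()` runs the *exact expectation* of
the same chain: a deterministic recursion over age `a = 0..110` and MGUS
duration `t = 0..110`, applying the identical probabilities in the identical
order. Because the second engine is defined as the expectation of the first
rather than as a separate continuum approximation, simulated and analytic
occupancies must agree to Monte-Carlo error at any population size — the
test suite uses this as a correctness oracle in both directions.

The stochastic engine draws each demographic process (deaths, onsets,
screens, progressions, births) from its own RNG stream, all derived from one
master seed. Runs that differ only in screening policy therefore share all
disease randomness, and with `r = 1` the screened and unscreened runs
produce *identical* onset, progression and death histories agent for agent.
The suite asserts this exact equivalence, a far sharper version of the
"screening alone changes nothing" invariant than a statistical comparison.

## Parameters and calibration

All rates are annual Bernoulli probabilities; time and age advance in whole
years.

| Parameter | Default | Meaning |
|---|---|---|
| `p` | 0.01 / y | MGUS-to-MM progression (constant mode) |
| `r` | 0.61 | progression-risk reduction after detection (published point estimate for regular aspirin use) |
| `a0`, `delta_a` | 50 y, 1 y | screening start and mean interval |
| `q_mm` | 0.1428 / y | MM death probability, `1 - 0.5^(1/4.5)` |
| `f_high` | 0.20 | high-risk population fraction |
| `beta` (evolving) | 0.07 | geometric progression parameter, ~10x the nonevolving rate |

The demographic fixtures are parametric stand-ins pinned to published
anchors, with CSV overrides for users holding official tables:

* **Life table** — Gompertz–Makeham `mu(a) = c + A e^{Ga}` with
  `c = 6e-4`, `A = 2.5e-5`, `G = 0.095`, closed out at `mu(110) = 1`. This
  gives a life expectancy of 79.0 years at birth and 15.5 remaining years at
  70, matching the 2013 US life table to within a few months.
* **MGUS incidence** — `lambda(a) = k e^{ga}` above an onset floor of 30
  years, zero below. The slope `g = 0.035`/y reproduces the roughly
  four-fold rise in incidence between ages 50 and 90 reported by the Mayo
  Clinic incidence estimates. The low-risk scale `k` is found by 1-D root
  finding so the stationary unscreened population has exactly 2% MGUS
  prevalence among low-risk individuals aged 50+; the high-risk scale is
  then rooted so the high-risk lifetime MGUS risk is twice the low-risk one.
* **MM survival** — `q_mm` is the closed-form geometric rate with a
  4.5-year half-life. Combined with background mortality at typical
  diagnosis ages (around 70), the simulated all-cause median survival after
  MM diagnosis comes out at 4 years, inside the 4-to-5-year target range.
* **Population** — the initial pyramid is the stationary age distribution
  of the life table and the crude birth rate is the stationary rate
  `1/sum(S(a))` (~12.7 per 1,000), so the population holds its size and
  shape; prevalences are read only after a 60-year burn-in, by which time
  the MGUS and MM occupancies of every cohort younger than ~90 are fully
  equilibrated and the initial transient is forgotten.

Sex is carried through the data model but the default rates are
sex-symmetric; a sex-specific incidence file switches the lookup without
touching the engines.

```{r calibration}
m <- mgus_models()
m
mgus_prevalence(m, 50, group = "low")
lifetime_mgus_risk(m, "high") / lifetime_mgus_risk(m, "low")
```

## What the policy comparisons look like

Relative MM prevalence (percent of the `r = 1` baseline) across strategies:

```{r sweep}
sweep_policies(m, a0 = c(45, 55, 65), delta_a = c(1, 6, 8), r = 0.61)
```

Earlier starts and tighter intervals help; at the published `r = 0.61`,
starting at 55 with 6-yearly screens removes about a fifth of MM prevalence,
and annual screening from 50 about a third. The post-detection mortality
story is policy-free by construction: the competing-risk recursion behind
`post_detection_survival()` starts at the detection age, so `a0` and
`delta_a` shift *who* gets detected but not what happens afterwards, and
`mortality_reduction(r)` tracks `100 (1 - r)` closely in the small-rate
regime:

```{r mortality}
mortality_reduction(c(0.6, 0.1), m)
```

## Numerical and design choices

* **Within-year order.** The paper-level description fixes no intra-year
  order; we apply death, onset, screening, progression, so a carrier
  detected this year already progresses at the reduced rate this year. The
  deterministic engine uses the same order, so the choice cancels from every
  simulation-vs-analytic comparison.
* **Duration convention.** Evolving-mode cumulative progression by
  follow-up `T` is `1 - (1 - beta)^T` (opportunities at durations
  `0..T-1`). The geometric family has a constant conditional hazard `beta`,
  so constant mode is exactly the `beta = p` special case — asserted as an
  identity in the tests. Whether `r` multiplies `beta` or the conditional
  hazard is indistinguishable for this family; we reduce the hazard.
* **MM mortality combination.** MM death competes with background death
  additively on the probability scale (`q + (1-q) mu`), with the MM cause
  attempted first for attribution; a `combine_background = FALSE` switch
  makes `q_mm` replace background mortality instead.
* **Truncated-normal mixing** of progression rates truncates at 0 *and* 1
  (a probability), sampled by inverse CDF so `sd = 0` is exactly
  degenerate. `mixed_mortality()` integrates the 10-year MM mortality over
  this distribution by fixed-grid quadrature (801 nodes), cross-checked
  against Monte Carlo in the tests.
* **Screening budget.** For risk-stratified allocation, the annual budget
  is `C = (eligible population)/delta_a`, with eligibility meaning alive,
  not in the MM state, and aged `a0+`; eligible counts are evaluated on the
  unscreened stationary population so the per-group probabilities
  `min(1, yC/E_high)` and `min(1, (1-y)C/E_low)` need no fixed-point
  iteration, and screens beyond one per person-year are discarded rather
  than reallocated. `optimal_allocation()` bisects the within-group MM
  fraction gap to 1e-3, returning `y* = 1` when no crossing exists (weak
  interventions, including `r = 0.61`). Because fractions, not counts, are
  compared, `y*` is independent of the population size. Note that under
  this construction the *total* budget shrinks with `delta_a`, so `y*`
  moves substantially when `delta_a` grows (from 0.88 at `delta_a = 1` to
  0.59 at `delta_a = 4` for `r = 0.1`); budget formulations that hold the
  screen supply fixed would damp this.
* **Geometric fit.** `fit_geometric_progression()` minimises unweighted
  squared error of `1 - (1-beta)^T` through the origin and the observed
  points. On the packaged evolving follow-up points (55% at 10 y, 80% at
  20 y) it returns `beta = 0.077`; the nonevolving points give 0.0077,
  close to the constant `p = 0.01`. Reported two-point fits of ~0.07 and
  ~0.007 for these data are inside the fit's uncertainty — with two points
  and one parameter the objective is nearly flat between 0.007 and 0.008.

## Problem sizes

The deterministic engine works on 111 age times 111 duration classes and
evaluates a policy in milliseconds; every prevalence, allocation and
mortality result is computed at full precision from it. Simulation-based
quantities (survival medians, lead-time bias, engine cross-checks) use
10^6 individuals over 160 years in the acceptance script and 10^4–10^5
individuals in the routine test suite, with all statistical comparisons
made at three Monte-Carlo standard errors. Medians of detection-to-death
times are taken over detections in a window closing 60 years before the end
of the run, so no survival time is censored (nobody outlives age 110).

## What the generator does and does not emulate

The synthetic demography reproduces: a US-2013-like expectation of life and
stationary age pyramid; exponentially age-increasing MGUS incidence at 2%
prevalence (50+, low risk) with a two-fold high-risk lifetime risk carried
by 20% of the population; and a 4–5-year median MM survival. It does not
reproduce: cohort effects and secular mortality trends, the baby-boom bulge
of the true 2013 pyramid (only its summary statistics), sex-specific
incidence, migration, smoldering myeloma as an intermediate state, or
imperfect screening tests. Results that lean on the *shape* of late-life
incidence — most visibly the relative prevalence of late screening starts
(`a0 = 65`) and the exact equal-prevalence allocation — are sensitive to
those unmodelled features, and the package reports them as model outputs,
not as reproductions of any particular national dataset.

## Limitations

All rates are annual; events within a year are ordered, not timed. The
population is closed except for births. MGUS never regresses, and detection
is permanent. The equal-prevalence allocation criterion compares group MM
fractions only — it attaches no cost to screens and no harm to detection.
These are the assumptions of the modelled screening debate, not claims
about clinical practice.
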