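# Individual-based annual-step engine.
#
# The per-year event order matches the deterministic recursion exactly:
# death -> MGUS onset -> screening -> progression -> age/duration increment
# -> births. Each demographic process draws from its own RNG stream, all
# seeded from one master seed, so two runs that differ only in the screening
# policy share the death/onset/progression randomness (common random
# numbers): with r = 1 the disease trajectories are then identical
# agent-for-agent, which is the sharpest available check that screening per
# se is inert.

# --- RNG streams -----------------------------------------------------------

rng_streams <- function(seed, names = c("init", "deaths", "onset",
                                        "screening", "progression", "births")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(names))
  env <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(subseeds[i])
    assign(names[i], get(".Random.seed", globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  env
}

stream_eval <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), globalenv())
  out <- force(expr)
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

# --- internal mutable population state ------------------------------------

new_sim_state <- function(agents, capacity, start_year = 0L) {
  n <- nrow(agents)
  capacity <- max(capacity, n)
  E <- new.env(parent = emptyenv())
  grow <- function(x, len, fill) { length(x) <- len; x[is.na(x) & seq_along(x) > n] <- fill; x }
  E$N <- n
  E$age <- c(agents$age, rep(NA_integer_, capacity - n))
  E$sex <- c(agents$sex, rep(NA_integer_, capacity - n))
  E$group <- c(agents$group, rep(NA_integer_, capacity - n))
  E$state <- c(agents$state, rep(NA_integer_, capacity - n))
  E$duration <- c(agents$duration, rep(NA_integer_, capacity - n))
  E$new_onset <- rep(FALSE, capacity)
  E$birth_year <- c(start_year - agents$age, rep(NA_integer_, capacity - n))
  blank <- rep(NA_integer_, capacity)
  E$onset_year <- blank; E$detected_year <- blank
  E$mm_year <- blank; E$death_year <- blank
  E$death_cause <- blank  # 0 other, 1 MM
  if (!all(is.na(agents$onset_age))) {
    E$onset_year[seq_len(n)] <- start_year - agents$age + agents$onset_age
  }
  E
}

ensure_capacity <- function(E, needed) {
  cap <- length(E$age)
  if (needed <= cap) return(invisible(E))
  newcap <- max(needed, ceiling(cap * 1.25))
  for (f in c("age", "sex", "group", "state", "duration", "birth_year",
              "onset_year", "detected_year", "mm_year", "death_year",
              "death_cause")) {
    v <- get(f, envir = E); length(v) <- newcap; assign(f, v, envir = E)
  }
  v <- E$new_onset; v2 <- rep(FALSE, newcap); v2[seq_along(v)] <- v
  E$new_onset <- v2
  invisible(E)
}

# one simulated year over the mutable state; returns per-year tallies
sim_year_core <- function(E, year, mu, lam_mat, s_mat, h_u, h_d, q_mm,
                          combine_bg, birth_rate, f_high, sex_ratio, streams) {
  A <- length(mu) - 1L
  n <- E$N
  live <- which(E$state[seq_len(n)] < 4L)

  # 1. death (MM cause fires first for MM patients)
  u <- stream_eval(streams, "deaths", stats::runif(length(live)))
  ai <- pmin(E$age[live], A) + 1L
  mu_i <- mu[ai]
  is_mm <- E$state[live] == 3L
  mu_mm <- if (combine_bg) mu_i else 0
  die_mm <- is_mm & u < q_mm
  die_other <- (!is_mm & u < mu_i) |
    (is_mm & !die_mm & u < q_mm + (1 - q_mm) * mu_mm)
  died <- die_mm | die_other
  if (any(died)) {
    ix <- live[died]
    E$state[ix] <- ifelse(die_mm[died], 5L, 4L)
    E$death_year[ix] <- year
    E$death_cause[ix] <- as.integer(die_mm[died])
  }
  live <- live[!died]

  # 2. MGUS onset for healthy survivors
  hlt <- live[E$state[live] == 0L]
  n_onset <- 0L
  if (length(hlt)) {
    u <- stream_eval(streams, "onset", stats::runif(length(hlt)))
    lam <- lam_mat[cbind(pmin(E$age[hlt], A) + 1L, E$group[hlt] + 1L)]
    on <- u < lam
    ix <- hlt[on]
    E$state[ix] <- 1L
    E$duration[ix] <- 0L
    E$new_onset[ix] <- TRUE
    E$onset_year[ix] <- year
    n_onset <- length(ix)
  }

  # 3. screening of undetected MGUS (carriers that onset this year sit out)
  und <- live[E$state[live] == 1L & !E$new_onset[live]]
  n_det <- 0L
  if (length(und)) {
    u <- stream_eval(streams, "screening", stats::runif(length(und)))
    s <- s_mat[cbind(pmin(E$age[und], A) + 1L, E$group[und] + 1L)]
    det <- u < s
    ix <- und[det]
    E$state[ix] <- 2L
    E$detected_year[ix] <- year
    n_det <- length(ix)
  }

  # 4. progression to MM at the (possibly reduced) duration hazard
  mg <- live[(E$state[live] == 1L | E$state[live] == 2L) & !E$new_onset[live]]
  n_prog <- 0L
  if (length(mg)) {
    u <- stream_eval(streams, "progression", stats::runif(length(mg)))
    ti <- pmin(E$duration[mg], A) + 1L
    haz <- ifelse(E$state[mg] == 2L, h_d[ti], h_u[ti])
    pr <- u < haz
    ix <- mg[pr]
    E$state[ix] <- 3L
    E$mm_year[ix] <- year
    n_prog <- length(ix)
  }

  # 5. age and duration increments
  E$age[live] <- E$age[live] + 1L
  mg_all <- live[(E$state[live] == 1L | E$state[live] == 2L) & !E$new_onset[live]]
  E$duration[mg_all] <- E$duration[mg_all] + 1L
  if (n_onset) E$new_onset[seq_len(n)] <- FALSE

  # 6. births at the crude birth rate
  nb <- stream_eval(streams, "births",
                    stats::rpois(1L, birth_rate * length(live)))
  if (nb > 0) {
    ensure_capacity(E, n + nb)
    ix <- n + seq_len(nb)
    E$N <- n + nb
    E$age[ix] <- 0L
    E$state[ix] <- 0L
    E$duration[ix] <- NA_integer_
    E$birth_year[ix] <- year
    sg <- stream_eval(streams, "births", stats::runif(2L * nb))
    E$sex[ix] <- as.integer(sg[seq_len(nb)] < sex_ratio)
    E$group[ix] <- as.integer(sg[nb + seq_len(nb)] < f_high)
  }
  c(births = nb, deaths_other = sum(die_other), deaths_mm = sum(die_mm),
    onsets = n_onset, detections = n_det, progressions = n_prog)
}

# per-group screening probability matrix (age x group)
screen_prob_matrix <- function(models, policy, screen_prob = NULL) {
  ages <- models$life_table$age
  if (is.null(screen_prob)) {
    s <- screen_probability(ages, policy)
    cbind(low = s, high = s)
  } else {
    stopifnot(is.list(screen_prob), !is.null(screen_prob$low),
              !is.null(screen_prob$high))
    cbind(low = ifelse(ages >= policy$a0, screen_prob$low, 0),
          high = ifelse(ages >= policy$a0, screen_prob$high, 0))
  }
}

yearly_snapshot <- function(E, year, tallies) {
  n <- E$N
  st <- E$state[seq_len(n)]
  gr <- E$group[seq_len(n)]
  ag <- E$age[seq_len(n)]
  live <- st < 4L
  cnt <- function(s, g) sum(st == s & gr == g)
  mgus50 <- function(g) sum(live & gr == g & ag >= 50 & (st == 1L | st == 2L))
  alive50 <- function(g) sum(live & gr == g & ag >= 50)
  data.frame(
    year = year, n_alive = sum(live),
    births = tallies[["births"]], deaths_other = tallies[["deaths_other"]],
    deaths_mm = tallies[["deaths_mm"]], onsets = tallies[["onsets"]],
    detections = tallies[["detections"]], progressions = tallies[["progressions"]],
    healthy_low = cnt(0L, 0L), healthy_high = cnt(0L, 1L),
    undet_low = cnt(1L, 0L), undet_high = cnt(1L, 1L),
    det_low = cnt(2L, 0L), det_high = cnt(2L, 1L),
    mm_low = cnt(3L, 0L), mm_high = cnt(3L, 1L),
    dead_other = sum(st == 4L), dead_mm = sum(st == 5L),
    mgus50_low = mgus50(0L), mgus50_high = mgus50(1L),
    alive50_low = alive50(0L), alive50_high = alive50(1L)
  )
}

state_to_agents <- function(E, start_year = 0L) {
  n <- E$N
  ix <- seq_len(n)
  by <- E$birth_year[ix]
  out <- data.frame(
    id = ix, age = E$age[ix], sex = E$sex[ix], group = E$group[ix],
    state = E$state[ix], duration = E$duration[ix],
    birth_year = by,
    onset_year = E$onset_year[ix], detected_year = E$detected_year[ix],
    mm_year = E$mm_year[ix], death_year = E$death_year[ix],
    # events in year y happen before that year's birthday, at age y - by - 1
    onset_age = E$onset_year[ix] - by - 1L,
    detected_age = E$detected_year[ix] - by - 1L,
    mm_age = E$mm_year[ix] - by - 1L,
    death_age = E$death_year[ix] - by - 1L,
    death_cause = c("other", "mm")[E$death_cause[ix] + 1L]
  )
  class(out) <- c("agent_table", "data.frame")
  out
}

#' Advance an agent table by one simulated year
#'
#' Applies, in order: death, MGUS onset, screening, progression, age and
#' duration increments, and births. Exposed mainly for inspection and
#' testing; [simulate_population()] runs the same core in a loop without the
#' per-year data-frame conversion.
#'
#' @param agents An agent table (see [build_initial_population()]).
#' @param models An [mgus_models()] bundle.
#' @param policy A [screening_policy()].
#' @param seed Integer seed (one master seed; the engine derives one RNG
#'   stream per demographic process from it).
#' @param year Calendar year recorded for events.
#' @return List with elements `agents` (updated table) and `events` (data
#'   frame of this year's events: `id`, `event`, `age`).
#' @export
step_year <- function(agents, models, policy = no_screening(), seed = 1L,
                      year = 1L) {
  stopifnot(inherits(agents, "agent_table"), inherits(models, "mgus_models"))
  streams <- rng_streams(seed)
  E <- new_sim_state(agents, capacity = nrow(agents) + 1000L,
                     start_year = year - 1L)
  A <- max(models$life_table$age)
  lam_mat <- cbind(lambda_vector(models$incidence, "low"),
                   lambda_vector(models$incidence, "high"))
  sim_year_core(
    E, year, models$life_table$mu, lam_mat,
    screen_prob_matrix(models, policy),
    progression_probability(0:A, FALSE, models$progression),
    progression_probability(0:A, TRUE, models$progression, policy),
    models$disease$q_mm, models$disease$combine_background,
    models$population$birth_rate, models$population$f_high,
    models$population$sex_ratio, streams
  )
  out <- state_to_agents(E)
  list(agents = out, events = event_log(out, years = year))
}

#' Simulate the screened population
#'
#' Runs the individual-based engine for `years` annual steps from an initial
#' population drawn from the configured age pyramid. The first `burn_in`
#' years let MGUS and MM occupancy reach quasi-stationarity (the initial
#' population starts disease-free); outcome functions discard events from the
#' burn-in window. Fully reproducible for a fixed seed.
#'
#' @param models An [mgus_models()] bundle.
#' @param policy A [screening_policy()].
#' @param years Number of simulated years.
#' @param burn_in Years discarded before outcomes are measured (stored with
#'   the result; default 60).
#' @param seed Master seed; one RNG stream per demographic process (deaths,
#'   onset, screening, progression, births) is derived from it, so runs that
#'   differ only in policy share all other randomness.
#' @param n Initial population size (default from the bundle).
#' @param screen_prob Optional per-group annual screening probabilities
#'   `list(low = , high = )` overriding `1/delta_a`, used for budgeted
#'   allocation experiments.
#' @return An object of class `mgus_sim`: list with `agents` (final agent
#'   table including the dead), `yearly` (one row per year of population and
#'   event tallies), and the run metadata (`policy`, `years`, `burn_in`,
#'   `seed`, `n0`).
#' @examples
#' m <- mgus_models(n = 2000)
#' sim <- simulate_population(m, screening_policy(50, 1, 0.61),
#'                            years = 80, seed = 7)
#' tail(sim$yearly[, c("year", "n_alive", "mm_low", "mm_high")])
#' @export
simulate_population <- function(models, policy = no_screening(),
                                years = 120L, burn_in = 60L, seed = 1L,
                                n = models$population$n,
                                screen_prob = NULL) {
  stopifnot(inherits(models, "mgus_models"), inherits(policy, "screening_policy"),
            years >= 1)
  pop <- models$population
  if (n != pop$n) {
    pop <- population_config(n = n, f_high = pop$f_high,
                             birth_rate = pop$birth_rate,
                             sex_ratio = pop$sex_ratio,
                             life_table = models$life_table)
  }
  streams <- rng_streams(seed)
  init <- stream_eval(streams, "init", {
    ages <- sample.int(length(pop$pyramid), as.integer(n), replace = TRUE,
                       prob = pop$pyramid) - 1L
    sexes <- as.integer(stats::runif(n) < pop$sex_ratio)
    groups <- as.integer(stats::runif(n) < pop$f_high)
    agent_table(seq_len(as.integer(n)), ages, sexes, groups)
  })
  cap <- as.integer(n + ceiling(pop$birth_rate * n * years * 1.4) + 1000)
  E <- new_sim_state(init, capacity = cap)
  A <- max(models$life_table$age)
  lam_mat <- cbind(lambda_vector(models$incidence, "low"),
                   lambda_vector(models$incidence, "high"))
  s_mat <- screen_prob_matrix(models, policy, screen_prob)
  h_u <- progression_probability(0:A, FALSE, models$progression)
  h_d <- progression_probability(0:A, TRUE, models$progression, policy)
  yearly <- vector("list", years)
  for (year in seq_len(years)) {
    tallies <- sim_year_core(E, year, models$life_table$mu, lam_mat, s_mat,
                             h_u, h_d, models$disease$q_mm,
                             models$disease$combine_background,
                             pop$birth_rate, pop$f_high, pop$sex_ratio,
                             streams)
    yearly[[year]] <- yearly_snapshot(E, year, tallies)
  }
  structure(
    list(agents = state_to_agents(E), yearly = do.call(rbind, yearly),
         policy = policy, years = years, burn_in = burn_in, seed = seed,
         n0 = as.integer(n)),
    class = "mgus_sim"
  )
}

#' @export
print.mgus_sim <- function(x, ...) {
  last <- x$yearly[nrow(x$yearly), ]
  cat(sprintf(
    "<mgus_sim> n0 = %d, %d years (burn-in %d), seed %d\n  final: %d alive, %d MGUS detected, %d with MM, %d MM deaths total\n",
    x$n0, x$years, x$burn_in, x$seed, last$n_alive,
    last$det_low + last$det_high, last$mm_low + last$mm_high, last$dead_mm
  ))
  invisible(x)
}

#' Extract the event log
#'
#' Assembles the append-only event history (births, MGUS onsets, detections,
#' progressions to MM, deaths by cause) from a simulation's agent table.
#' Screens of individuals without MGUS are tallied in the yearly summary but
#' not logged per agent; with an ideal test a logged detection is exactly a
#' positive screen.
#'
#' @param x An `mgus_sim` object or an `agent_table`.
#' @param years Optional year range `c(from, to)` (or a single year) to
#'   restrict the log to.
#' @return Data frame with columns `year`, `id`, `event`, `age`, ordered by
#'   year then id.
#' @export
event_log <- function(x, years = NULL) {
  agents <- if (inherits(x, "mgus_sim")) x$agents else x
  stopifnot(inherits(agents, "agent_table"))
  pull <- function(year_col, event, age_col) {
    i <- which(!is.na(agents[[year_col]]))
    if (!length(i)) return(NULL)
    data.frame(year = agents[[year_col]][i], id = agents$id[i],
               event = event, age = agents[[age_col]][i])
  }
  born <- which(!is.na(agents$birth_year) & agents$birth_year > 0)
  logs <- list(
    if (length(born)) data.frame(year = agents$birth_year[born],
                                 id = agents$id[born], event = "birth", age = 0L),
    pull("onset_year", "mgus_onset", "onset_age"),
    pull("detected_year", "detection", "detected_age"),
    pull("mm_year", "progression", "mm_age")
  )
  dth <- which(!is.na(agents$death_year))
  if (length(dth)) {
    logs <- c(logs, list(data.frame(
      year = agents$death_year[dth], id = agents$id[dth],
      event = ifelse(agents$death_cause[dth] == "mm", "death_mm", "death_other"),
      age = agents$death_age[dth]
    )))
  }
  out <- do.call(rbind, Filter(Negate(is.null), logs))
  if (!is.null(years)) {
    if (length(years) == 1L) years <- c(years, years)
    out <- out[out$year >= years[1] & out$year <= years[2], , drop = FALSE]
  }
  out <- out[order(out$year, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
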