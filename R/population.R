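#' Population configuration
#'
#' Size, risk-group mix, birth process and initial age pyramid for the
#' stochastic engine. The default pyramid is the stationary age distribution
#' implied by the life table (proportional to survival from birth), and the
#' default crude birth rate is the stationary one, `1 / sum(S(a))` — together
#' they keep the simulated population approximately constant in size and age
#' structure, which is the regime all prevalences are reported in.
#'
#' @param n Initial number of individuals.
#' @param f_high Fraction assigned to the high-risk group, in `[0, 1]`.
#' @param birth_rate Crude birth rate per capita per year, or `NULL` for the
#'   stationary rate.
#' @param sex_ratio Probability that a new individual is male.
#' @param pyramid Optional vector of age weights over ages `0..max_age`
#'   (normalised internally), or a path to a CSV with columns `age, weight`.
#' @param life_table Life table used to derive the stationary pyramid/birth
#'   rate when they are not supplied.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n = 1e5, f_high = 0.2, birth_rate = NULL,
                              sex_ratio = 0.5, pyramid = NULL,
                              life_table = build_life_table()) {
  stopifnot(n >= 1, f_high >= 0, f_high <= 1, sex_ratio >= 0, sex_ratio <= 1)
  S <- survival_from_birth(life_table)
  if (is.null(birth_rate)) birth_rate <- 1 / sum(S)
  stopifnot(birth_rate > 0, birth_rate < 1)
  if (is.null(pyramid)) {
    pyramid <- S / sum(S)
  } else if (is.character(pyramid)) {
    tab <- utils::read.csv(pyramid)
    if (!all(c("age", "weight") %in% names(tab))) {
      stop("pyramid file must have columns `age` and `weight`")
    }
    w <- numeric(length(life_table$age))
    w[tab$age + 1L] <- tab$weight
    pyramid <- w / sum(w)
  } else {
    stopifnot(length(pyramid) == length(life_table$age), all(pyramid >= 0))
    pyramid <- pyramid / sum(pyramid)
  }
  structure(
    list(n = n, f_high = f_high, birth_rate = birth_rate,
         sex_ratio = sex_ratio, pyramid = pyramid,
         max_age = max(life_table$age)),
    class = "population_config"
  )
}

#' Build the initial agent table
#'
#' Draws `n` healthy individuals with ages from the configured pyramid, risk
#' group from `Bernoulli(f_high)` and sex from `Bernoulli(sex_ratio)`.
#' Deterministic for a fixed seed.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return An `agent_table`: a data frame with one row per individual and
#'   columns `id`, `age`, `sex` (0 female, 1 male), `group` (0 low, 1 high),
#'   `state` (see [mgus_states]), `duration` (years since MGUS onset),
#'   `onset_age`, `detected_age`, `mm_age`, `death_age` (NA until the event
#'   happens) and `death_cause`.
#' @export
build_initial_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  n <- as.integer(config$n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ages <- sample.int(length(config$pyramid), n, replace = TRUE,
                     prob = config$pyramid) - 1L
  agent_table(
    id = seq_len(n),
    age = ages,
    sex = as.integer(stats::runif(n) < config$sex_ratio),
    group = as.integer(stats::runif(n) < config$f_high)
  )
}

# construct a consistent agent table from the id/age/sex/group columns
agent_table <- function(id, age, sex, group) {
  n <- length(id)
  out <- data.frame(
    id = as.integer(id), age = as.integer(age),
    sex = as.integer(sex), group = as.integer(group),
    state = rep(mgus_states[["HEALTHY"]], n),
    duration = rep(NA_integer_, n),
    onset_age = rep(NA_integer_, n),
    detected_age = rep(NA_integer_, n),
    mm_age = rep(NA_integer_, n),
    death_age = rep(NA_integer_, n),
    death_cause = rep(NA_character_, n)
  )
  class(out) <- c("agent_table", "data.frame")
  out
}
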