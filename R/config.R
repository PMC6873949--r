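# Configuration handling and structured output writing for the command-line
# entry points. A configuration is a nested list mirroring the model
# components; YAML and JSON are both accepted.

#' Default model configuration
#'
#' The full default parameter set: annual screening from age 50 with the
#' published point estimate r = 0.61; constant progression at p = 0.01/year;
#' MM death rate calibrated to a 4.5-year median; 20% high-risk individuals;
#' incidence calibrated to 2% MGUS prevalence at ages 50+ and a two-fold
#' high-risk lifetime risk.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    policy = list(a0 = 50, delta_a = 1, r = 0.61),
    progression = list(mode = "constant", p = 0.01, beta = NULL,
                       mixing = NULL),
    disease = list(q_mm = NULL, combine_background = TRUE,
                   mm_median_target = 4.5),
    demography = list(
      n = 1e5, f_high = 0.2, birth_rate = NULL, sex_ratio = 0.5,
      a_min = 30, g = 0.035,
      prevalence_target = 0.02, lifetime_risk_ratio = 2.0,
      life_table = list(A = 2.5e-5, G = 0.095, c = 6e-4),
      life_table_file = NULL, incidence_file = NULL, pyramid_file = NULL
    ),
    simulation = list(years = 120, burn_in = 60, seed = 1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      # single-bracket assignment keeps NULL-valued fields in place
      base[nm] <- list(override[[nm]])
    }
  }
  base
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration file, fills every unspecified field
#' from [default_config()], and validates all parameter constraints by
#' constructing the corresponding model objects. The validated configuration
#' is attached to every output written by [write_outputs()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return Validated configuration list of class `mgus_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  # constructing the component objects enforces every invariant
  screening_policy(cfg$policy$a0, cfg$policy$delta_a, cfg$policy$r)
  progression_model(cfg$progression$mode, p = cfg$progression$p,
                    beta = cfg$progression$beta,
                    mixing = cfg$progression$mixing)
  if (!is.null(cfg$disease$q_mm)) {
    disease_rates(cfg$disease$q_mm, cfg$disease$combine_background)
  }
  d <- cfg$demography
  if (d$f_high < 0 || d$f_high > 1) stop("demography$f_high must lie in [0, 1]")
  if (d$n < 1) stop("demography$n must be >= 1")
  if (!is.null(d$birth_rate) && (d$birth_rate <= 0 || d$birth_rate >= 1)) {
    stop("demography$birth_rate must lie in (0, 1)")
  }
  if (cfg$simulation$years < 1) stop("simulation$years must be >= 1")
  if (cfg$simulation$burn_in < 0) stop("simulation$burn_in must be >= 0")
  class(cfg) <- c("mgus_config", "list")
  cfg
}

#' Build the model bundle described by a configuration
#'
#' @param cfg A configuration from [load_config()] / [default_config()].
#' @return An [mgus_models()] bundle.
#' @export
models_from_config <- function(cfg) {
  if (!inherits(cfg, "mgus_config")) cfg <- validate_config(cfg)
  d <- cfg$demography
  lt <- build_life_table(file = d$life_table_file, makeham = d$life_table)
  prog <- progression_model(cfg$progression$mode, p = cfg$progression$p,
                            beta = cfg$progression$beta,
                            mixing = cfg$progression$mixing)
  dis <- if (!is.null(cfg$disease$q_mm)) {
    disease_rates(cfg$disease$q_mm, cfg$disease$combine_background)
  } else {
    calibrate_mm_death_rate(cfg$disease$mm_median_target)
  }
  inc <- if (!is.null(d$incidence_file)) {
    incidence_model(file = d$incidence_file, max_age = max(lt$age))
  } else {
    calibrate_incidence(
      lt, targets = list(prevalence_50plus_lowrisk = d$prevalence_target,
                         lifetime_risk_ratio = d$lifetime_risk_ratio),
      g = d$g, a_min = d$a_min, progression = prog, disease = dis
    )
  }
  mgus_models(life_table = lt, incidence = inc, progression = prog,
              disease = dis, n = d$n, f_high = d$f_high,
              birth_rate = d$birth_rate)
}

#' Write structured outputs
#'
#' Writes each data frame in `results` as a CSV (floats at 6 significant
#' digits, deterministic column order) and a `metadata.json` carrying the
#' seed, a hash of the configuration, and the package version, so any output
#' directory can be regenerated exactly.
#'
#' @param results Named list of data frames (and/or scalar summaries, which
#'   go into `summary.json`).
#' @param out_dir Output directory, created if needed.
#' @param config Configuration list echoed into the metadata.
#' @param seed Seed echoed into the metadata.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(results, out_dir, config = default_config(), seed = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop(sprintf("cannot write to output directory: %s", out_dir))
  }
  written <- character()
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      num <- vapply(x, is.numeric, logical(1))
      x[num] <- lapply(x[num], signif, digits = 6)
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    } else {
      scalars[[nm]] <- x
    }
  }
  if (length(scalars)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(scalars, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, f)
  }
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  meta <- list(
    package = "mgusscreen",
    version = as.character(utils::packageVersion("mgusscreen")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file))
  )
  mf <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(written, cfg_file, mf))
}
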