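#' Build a life table
#'
#' Annual background death probabilities `mu(a)` for healthy and MGUS
#' individuals over ages 0 to 110. The packaged parametric default is a
#' Gompertz-Makeham hazard `mu(a) = c + A * exp(G * a)` with constants chosen
#' to reproduce a 2013-US-like expectation of life (about 79 years at birth,
#' 15.5 remaining years at 70). A delimited file with columns `age, qx` can be
#' supplied instead, e.g. to use an official census life table.
#'
#' The table is closed out at `mu(110) = 1`: nobody survives past age 110.
#'
#' @param file Optional path to a CSV with columns `age` (0, 1, 2, ...) and
#'   `qx` (annual death probability). Ages beyond the last row inherit its
#'   `qx`; the closeout rule still applies.
#' @param makeham Parameters of the parametric form, a list with elements
#'   `A`, `G`, `c` (all positive).
#' @param max_age Final age of the table (death is certain there).
#' @return An object of class `life_table`: list with `age` (0..`max_age`)
#'   and `mu` (annual death probabilities), plus a `source` tag.
#' @examples
#' lt <- build_life_table()
#' life_expectancy(lt)
#' @export
build_life_table <- function(file = NULL,
                             makeham = list(A = 2.5e-5, G = 0.095, c = 6e-4),
                             max_age = 110L) {
  ages <- 0:max_age
  if (is.null(file)) {
    stopifnot(makeham$A > 0, makeham$G > 0, makeham$c > 0)
    mu <- pmin(1, makeham$c + makeham$A * exp(makeham$G * ages))
    src <- "parametric"
  } else {
    tab <- utils::read.csv(file)
    if (!all(c("age", "qx") %in% names(tab))) {
      stop("life table file must have columns `age` and `qx`")
    }
    if (is.unsorted(tab$age, strictly = TRUE)) {
      bad <- which(diff(tab$age) <= 0)[1] + 1
      stop(sprintf("life table file: ages not strictly increasing at row %d", bad))
    }
    bad <- which(tab$qx < 0 | tab$qx > 1)
    if (length(bad)) {
      stop(sprintf("life table file: qx outside [0, 1] at row %d (age %g)",
                   bad[1], tab$age[bad[1]]))
    }
    idx <- findInterval(ages, tab$age)
    if (any(idx == 0)) stop("life table file must start at or below age 0")
    mu <- tab$qx[idx]
    src <- "file"
  }
  mu[length(mu)] <- 1
  structure(list(age = ages, mu = mu, source = src), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages 0..%d (%s), e0 = %.1f y, mu(70) = %.4f\n",
              max(x$age), x$source, life_expectancy(x), x$mu[71]))
  invisible(x)
}

# survival from birth to the *start* of each age: S(0) = 1
survival_from_birth <- function(lt) {
  c(1, cumprod(1 - lt$mu)[-length(lt$mu)])
}

#' Life expectancy
#'
#' Discrete expectation of remaining life from a given age, computed by
#' summing survival probabilities over whole years (with the usual half-year
#' continuity correction).
#'
#' @param lt A [build_life_table()] object.
#' @param age Age from which remaining life expectancy is computed.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age = 0) {
  stopifnot(inherits(lt, "life_table"), age >= 0, age <= max(lt$age))
  S <- survival_from_birth(lt)
  i <- age + 1
  sum(S[i:length(S)]) / S[i] - 0.5
}
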