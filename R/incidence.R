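#' MGUS incidence model
#'
#' Annual probability of MGUS onset `lambda(a; group, sex)`. The parametric
#' form is exponential in age, `lambda(a) = k * exp(g * a)` for ages at or
#' above the onset floor `a_min` and 0 below it, with a group-specific scale
#' `k` (low risk vs high risk). The default slope `g = 0.035`/year makes
#' incidence rise about four-fold between ages 50 and 90, the shape reported
#' by the published Mayo Clinic MGUS incidence estimates; the scales are set
#' by [calibrate_incidence()]. Rates are sex-symmetric unless overridden from
#' a file.
#'
#' @param k Length-2 vector of scale parameters, `c(low, high)`.
#' @param g Exponential age slope per year (shared by both groups).
#' @param a_min Onset floor: no MGUS incidence below this age.
#' @param max_age Last age of the model.
#' @param file Optional CSV with columns `age, group, lambda` (and optionally
#'   `sex`), giving tabulated onset probabilities that replace the parametric
#'   form. `group` must be `"low"`/`"high"`; `sex`, if present,
#'   `"female"`/`"male"`.
#' @return An object of class `incidence_model` holding a
#'   `(max_age+1) x 2 x 2` array `lambda[age, group, sex]`.
#' @export
incidence_model <- function(k = c(low = 1e-5, high = 2e-5), g = 0.035,
                            a_min = 30, max_age = 110L, file = NULL) {
  ages <- 0:max_age
  lam <- array(0, dim = c(max_age + 1L, 2L, 2L),
               dimnames = list(NULL, c("low", "high"), c("female", "male")))
  if (is.null(file)) {
    stopifnot(length(k) == 2, all(k >= 0), g >= 0, a_min >= 0)
    for (gi in 1:2) {
      v <- ifelse(ages >= a_min, pmin(1, k[gi] * exp(g * ages)), 0)
      lam[, gi, 1] <- v
      lam[, gi, 2] <- v
    }
  } else {
    tab <- utils::read.csv(file)
    if (!all(c("age", "group", "lambda") %in% names(tab))) {
      stop("incidence file must have columns `age`, `group`, `lambda`")
    }
    bad <- which(tab$lambda < 0 | tab$lambda > 1)
    if (length(bad)) {
      stop(sprintf("incidence file: lambda outside [0, 1] at row %d", bad[1]))
    }
    sexes <- if ("sex" %in% names(tab)) tab$sex else NA
    for (i in seq_len(nrow(tab))) {
      a <- tab$age[i]
      if (a < 0 || a > max_age) next
      gi <- match(tab$group[i], c("low", "high"))
      if (is.na(gi)) stop(sprintf("incidence file: unknown group %s", tab$group[i]))
      si <- if (all(is.na(sexes))) 1:2 else match(sexes[i], c("female", "male"))
      lam[a + 1L, gi, si] <- tab$lambda[i]
    }
  }
  structure(
    list(lambda = lam, k = k, g = g, a_min = a_min, max_age = max_age,
         source = if (is.null(file)) "parametric" else "file"),
    class = "incidence_model"
  )
}

#' @export
print.incidence_model <- function(x, ...) {
  cat(sprintf(
    "<incidence_model> %s; onset floor %g y; lambda(70): low %.2e, high %.2e / year\n",
    x$source, x$a_min, mgus_incidence(70, "low", model = x),
    mgus_incidence(70, "high", model = x)
  ))
  invisible(x)
}

#' Look up the annual MGUS onset probability
#'
#' @param age Vector of ages.
#' @param group `"low"` or `"high"` risk.
#' @param sex `"female"`, `"male"`, or `NULL` for the sex-averaged rate.
#' @param model An [incidence_model()].
#' @return Vector of annual onset probabilities.
#' @export
mgus_incidence <- function(age, group = "low", sex = NULL, model) {
  stopifnot(inherits(model, "incidence_model"))
  gi <- match(group, c("low", "high"))
  if (any(is.na(gi))) stop("`group` must be 'low' or 'high'")
  i <- pmin(age, model$max_age) + 1L
  if (is.null(sex)) {
    (model$lambda[cbind(i, gi, 1L)] + model$lambda[cbind(i, gi, 2L)]) / 2
  } else {
    si <- match(sex, c("female", "male"))
    if (any(is.na(si))) stop("`sex` must be 'female' or 'male'")
    model$lambda[cbind(i, gi, si)]
  }
}

# sex-averaged lambda vector over all ages for one group (engine lookup)
lambda_vector <- function(model, group) {
  gi <- match(group, c("low", "high"))
  (model$lambda[, gi, 1] + model$lambda[, gi, 2]) / 2
}
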