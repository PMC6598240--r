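#' Fit a cubic polynomial to age-specific rates
#'
#' Smooths one stratum's 5-year age-group rates with a third-degree
#' polynomial for use in continuous-age calculations. The fit is ordinary
#' least squares of log(rate) on age-group midpoints (the open-ended 85+
#' group uses midpoint 87), which guarantees a strictly positive fitted
#' rate everywhere. Zero rates — possible in rare strata — are floored at
#' half the smallest positive rate in the table before taking logs, and a
#' message records how many cells were floored.
#'
#' @param table A `rate_table` (or plain data frame with `age_lo, age_hi,
#'   rate`) restricted to a single (sex, race) stratum.
#' @return An object of class `rate_polynomial`: coefficients `c0..c3` of
#'   the cubic in age on the log-rate scale, the age domain
#'   `[age_min, age_max]`, and the stratum labels.
#' @export
#' @examples
#' tab <- generate_rate_table("gompertz", list(a = 2e-5, b = 0.08))
#' poly <- fit_rate_polynomial(tab)
#' evaluate_rate(poly, 60)
fit_rate_polynomial <- function(table) {
  stopifnot(all(c("age_lo", "age_hi", "rate") %in% names(table)))
  key_cols <- intersect(c("sex", "race"), names(table))
  strata <- unique(as.data.frame(table)[key_cols])
  if (length(key_cols) > 0 && nrow(strata) > 1) {
    abort("fit_rate_polynomial() expects a single (sex, race) stratum; use fit_rate_polynomials() for many")
  }
  tab <- table[order(table$age_lo), ]
  # arithmetic midpoint of the closed group; the 85+ group, stored as 85-89,
  # gets midpoint 87
  mid <- (tab$age_lo + tab$age_hi) / 2
  rate <- tab$rate
  if (all(rate == 0)) abort("cannot fit: all rates are zero")
  n_floored <- sum(rate == 0)
  if (n_floored > 0) {
    floor_val <- min(rate[rate > 0]) / 2
    rate[rate == 0] <- floor_val
    inform(sprintf("floored %d zero rate(s) at %.3g before log transform",
                   n_floored, floor_val))
  }
  if (length(mid) < 4) {
    abort(sprintf("cubic fit needs >= 4 age groups with usable rates, got %d",
                  length(mid)))
  }
  fit <- lm(log(rate) ~ mid + I(mid^2) + I(mid^3))
  structure(
    list(
      coefficients = setNames(as.numeric(coef(fit)), c("c0", "c1", "c2", "c3")),
      age_min = min(tab$age_lo),
      age_max = max(tab$age_hi),
      sex = if ("sex" %in% names(tab)) tab$sex[1] else NA_character_,
      race = if ("race" %in% names(tab)) tab$race[1] else NA_character_,
      outcome = attr(table, "outcome") %||% NA_character_,
      n_floored = n_floored
    ),
    class = "rate_polynomial"
  )
}

#' @export
print.rate_polynomial <- function(x, ...) {
  cat(sprintf(
    "<rate_polynomial> %s %s %s | log-rate = %.4g %+.4g a %+.4g a^2 %+.4g a^3 | ages [%d, %d]\n",
    x$outcome, x$sex, x$race,
    x$coefficients[1], x$coefficients[2], x$coefficients[3], x$coefficients[4],
    x$age_min, x$age_max
  ))
  invisible(x)
}

#' Construct a rate polynomial directly from coefficients
#'
#' @param c0,c1,c2,c3 Cubic coefficients on the log-rate scale.
#' @param age_min,age_max Age domain in years.
#' @param sex,race,outcome Optional stratum labels.
#' @return A `rate_polynomial`.
#' @export
rate_polynomial <- function(c0, c1 = 0, c2 = 0, c3 = 0,
                            age_min = 40, age_max = 89,
                            sex = NA_character_, race = NA_character_,
                            outcome = NA_character_) {
  structure(
    list(coefficients = c(c0 = c0, c1 = c1, c2 = c2, c3 = c3),
         age_min = age_min, age_max = age_max,
         sex = sex, race = race, outcome = outcome, n_floored = 0L),
    class = "rate_polynomial"
  )
}

#' Evaluate a fitted rate polynomial at given ages
#'
#' Returns `exp(c0 + c1*age + c2*age^2 + c3*age^3)`. Ages above the fitted
#' domain are clamped to the domain maximum (extrapolating a cubic beyond
#' the data is unsafe); ages below 40 are an error — the calculator
#' supports ages 40 and over only, matching the range of its rate inputs.
#'
#' @param poly A `rate_polynomial`.
#' @param age Ages in years (vectorized).
#' @return Rates in events per person-year, strictly positive.
#' @export
evaluate_rate <- function(poly, age) {
  stopifnot(inherits(poly, "rate_polynomial"))
  if (any(age < 40)) {
    abort("ages below 40 are not supported (rate inputs cover ages 40 to 85+)")
  }
  a <- pmin(pmax(age, poly$age_min), poly$age_max)
  cc <- poly$coefficients
  exp(cc[[1]] + cc[[2]] * a + cc[[3]] * a^2 + cc[[4]] * a^3)
}

#' Fit rate polynomials for every stratum in a rate table
#'
#' @param table A `rate_table` possibly holding several (sex, race) strata
#'   and, for cause-specific mortality, several causes.
#' @return A tibble with one row per stratum: the stratum labels, the
#'   coefficients `c0..c3`, the age domain, and a list-column `poly` of
#'   `rate_polynomial` objects. Dropping the list-column gives the CSV
#'   serialization form.
#' @export
fit_rate_polynomials <- function(table) {
  keys <- intersect(c("cause", "sex", "race"), names(table))
  outcome <- attr(table, "outcome")
  groups <- dplyr::group_split(dplyr::group_by(tibble::as_tibble(unclass(table)),
                                               dplyr::across(dplyr::all_of(keys))))
  purrr::map_dfr(groups, function(sub) {
    p <- fit_rate_polynomial(structure(sub, outcome = outcome))
    out <- sub[1, keys]
    out$c0 <- p$coefficients[[1]]
    out$c1 <- p$coefficients[[2]]
    out$c2 <- p$coefficients[[3]]
    out$c3 <- p$coefficients[[4]]
    out$age_min <- p$age_min
    out$age_max <- p$age_max
    out$poly <- list(p)
    out
  })
}

#' Model of EAC incidence in persons with Barrett's esophagus
#'
#' In the Barrett's stratum the registry polynomial is replaced by a
#' simple anchored exponential model: incidence 0.31% per person-year for
#' white men at the 60–64 age-group midpoint (age 62), scaled by a factor
#' of 1.04 per year of age, with sex/race multipliers 0.4 for white women
#' and 0.75 for black men. Strata without a multiplier (for example black
#' women, for whom reliable progression data are unavailable) are
#' unsupported and raise an error rather than extrapolate.
#'
#' @param anchor_rate Incidence at `anchor_age` for white men, per
#'   person-year.
#' @param anchor_age Age in years the anchor applies to.
#' @param age_factor Multiplicative change in incidence per year of age.
#' @param multipliers Named vector of sex/race multipliers; names are
#'   `"sex race"` keys such as `"male white"`.
#' @return An object of class `be_incidence_model`.
#' @export
#' @examples
#' m <- be_incidence_model()
#' be_incidence(m, age = 62, sex = "male", race = "white")  # 0.0031
be_incidence_model <- function(anchor_rate = 0.0031,
                               anchor_age = 62,
                               age_factor = 1.04,
                               multipliers = c("male white" = 1,
                                               "female white" = 0.4,
                                               "male black" = 0.75)) {
  stopifnot(anchor_rate > 0, age_factor > 0, all(multipliers > 0))
  structure(
    list(anchor_rate = anchor_rate, anchor_age = anchor_age,
         age_factor = age_factor, multipliers = multipliers),
    class = "be_incidence_model"
  )
}

#' EAC incidence for a person with Barrett's esophagus
#'
#' Computes `anchor_rate * age_factor^(age - anchor_age) * multiplier`.
#'
#' @param model A [be_incidence_model()].
#' @param age Age in years, 40 or over (vectorized).
#' @param sex `"male"` or `"female"`.
#' @param race `"white"` or `"black"`.
#' @return Incidence in events per person-year.
#' @export
be_incidence <- function(model, age, sex, race) {
  stopifnot(inherits(model, "be_incidence_model"))
  if (any(age < 40)) abort("ages below 40 are not supported")
  key <- paste(sex, race)
  if (!key %in% names(model$multipliers)) {
    stop_stratum(sex, race,
                 "no Barrett's-stratum incidence multiplier for this sex/race")
  }
  model$anchor_rate * model$age_factor^(age - model$anchor_age) *
    model$multipliers[[key]]
}

#' Competing (all-cause) mortality hazard at an age
#'
#' The competing hazard used in the absolute-risk combination is the
#' all-cause mortality rate, evaluated from its fitted polynomial. It is
#' not adjusted by subtracting EAC-specific deaths, which are a negligible
#' share of all-cause mortality.
#'
#' @param poly_allcause Fitted `rate_polynomial` for all-cause mortality.
#' @param age Ages in years (vectorized).
#' @return Hazard in deaths per person-year.
#' @export
competing_mortality <- function(poly_allcause, age) {
  evaluate_rate(poly_allcause, age)
}
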