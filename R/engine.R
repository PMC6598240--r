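#' Population-mean relative risk of a factor set
#'
#' Under the multiplicative model with independent factors, the mean
#' relative risk in the population is the product over factors of the
#' prevalence-weighted mean level RR. Its reciprocal is one minus the
#' population attributable risk (PAR): `1 - PAR = 1 / mean_population_rr`.
#'
#' @param factors A `risk_factor_set` (or data frame with `factor, rr,
#'   prevalence` columns).
#' @return A single number `>= ` the smallest possible individual RR.
#' @export
#' @examples
#' f <- tibble::tibble(
#'   factor = "x", level = c("ref", "exposed"),
#'   rr = c(1, 3), ci_low = 1, ci_high = c(1, 5),
#'   prevalence = c(0.5, 0.5), is_reference = c(TRUE, FALSE)
#' )
#' mean_population_rr(f)  # 0.5*1 + 0.5*3 = 2
mean_population_rr <- function(factors) {
  df <- tibble::as_tibble(unclass(factors))
  per_factor <- tapply(df$rr * df$prevalence, df$factor, sum)
  prod(per_factor)
}

#' Baseline hazard from population incidence
#'
#' The baseline hazard is the hazard for individuals at the lowest-risk
#' (reference) level of every factor. It is recovered from the observed
#' population incidence by dividing out the population-mean relative risk
#' — equivalently, multiplying by `1 - PAR`.
#'
#' @param incidence Population incidence (events per person-year);
#'   vectorized.
#' @param factors The active `risk_factor_set`.
#' @return Baseline hazard, same length as `incidence`.
#' @export
baseline_hazard <- function(incidence, factors) {
  stopifnot(all(incidence >= 0))
  incidence / mean_population_rr(factors)
}

#' Relative risk of one individual
#'
#' The product of the relative risks of the individual's selected level of
#' each factor in the active set. All-reference selections give 1.
#'
#' @param factors The active `risk_factor_set`.
#' @param selections Named list or character vector mapping every factor
#'   name in the set to one of its level labels.
#' @return The RR product (dimensionless).
#' @export
individual_rr <- function(factors, selections) {
  df <- tibble::as_tibble(unclass(factors))
  selections <- as.list(selections)
  rr <- 1
  for (f in unique(df$factor)) {
    sel <- selections[[f]]
    if (is.null(sel) || is.na(sel)) {
      abort(sprintf("no level selected for factor '%s'", f))
    }
    sub <- df[df$factor == f, ]
    i <- match(sel, sub$level)
    if (is.na(i)) {
      abort(sprintf("unknown level '%s' for factor '%s' (levels: %s)",
                    sel, f, paste(sub$level, collapse = ", ")))
    }
    rr <- rr * sub$rr[i]
  }
  rr
}

#' Cumulative incidence under competing piecewise-constant hazards
#'
#' Core actuarial combination: with the event hazard `h[t]` and competing
#' mortality hazard `m[t]` constant within each 1-year step, the
#' probability of the event occurring first within the horizon is
#' `sum_t h/(h+m) * (1 - exp(-(h+m))) * S(t)` where `S(t)` is survival
#' free of both events to the start of step `t`. For constant hazards this
#' telescopes exactly to `h/(h+m) * (1 - exp(-T*(h+m)))`.
#'
#' @param h Event hazard per year, one value per step.
#' @param m Competing mortality hazard per year, same length.
#' @return Probability in `[0, 1]`; 0 when all `h` are 0.
#' @export
cuminc_competing <- function(h, m) {
  stopifnot(length(h) == length(m), all(h >= 0), all(m >= 0))
  total <- h + m
  share <- ifelse(total > 0, h / total, 0)
  step_p <- share * (1 - exp(-total))
  surv <- c(1, exp(-cumsum(total)))[seq_along(h)]
  sum(step_p * surv)
}

# vectorized over relative risks r: event hazard in step t is h0[t] * r
cuminc_competing_many <- function(r, h0, m) {
  if (length(r) == 0) return(numeric(0))
  H <- outer(h0, r)
  total <- H + m
  share <- ifelse(total > 0, H / total, 0)
  step_p <- share * (1 - exp(-total))
  csum <- apply(total, 2, cumsum)
  if (is.null(dim(csum))) csum <- matrix(csum, nrow = 1)
  surv <- rbind(1, exp(-csum[-nrow(csum), , drop = FALSE]))
  as.numeric(colSums(step_p * surv))
}

ages_midstep <- function(age, horizon) age + seq_len(horizon) - 0.5

incidence_at <- function(incidence_model, ages, sex, race) {
  if (inherits(incidence_model, "be_incidence_model")) {
    be_incidence(incidence_model, ages, sex, race)
  } else if (inherits(incidence_model, "rate_polynomial")) {
    evaluate_rate(incidence_model, ages)
  } else {
    abort("incidence_model must be a rate_polynomial or be_incidence_model")
  }
}

#' Absolute risk of EAC over a horizon, adjusted for competing mortality
#'
#' Combines the baseline hazard (population incidence divided by the
#' population-mean RR), the individual's RR product, and the competing
#' all-cause mortality hazard over annual steps. Hazards are evaluated at
#' mid-step ages (`age + t + 0.5`), constant within each step.
#'
#' @param profile List with `age` (years, 40–89), `sex`, `race`, and
#'   `selections` (named factor-level map, see [individual_rr()]).
#' @param factors The active `risk_factor_set` for the profile's
#'   Barrett's stratum.
#' @param incidence_model A `rate_polynomial` (general population) or
#'   [be_incidence_model()] (Barrett's stratum) for the profile's sex/race.
#' @param mortality All-cause mortality `rate_polynomial` for the
#'   profile's sex/race.
#' @param horizon Projection horizon in years (default 10).
#' @return Probability of developing EAC within the horizon, in `[0, 1]`.
#' @export
absolute_risk <- function(profile, factors, incidence_model, mortality,
                          horizon = 10) {
  stopifnot(is.numeric(profile$age), length(profile$age) == 1)
  ages <- ages_midstep(profile$age, horizon)
  inc <- incidence_at(incidence_model, ages, profile$sex, profile$race)
  h0 <- baseline_hazard(inc, factors)
  r <- individual_rr(factors, profile$selections)
  m <- competing_mortality(mortality, ages)
  cuminc_competing(h0 * r, m)
}

#' Delta-method confidence interval for the absolute risk
#'
#' Propagates the uncertainty of each factor's RR estimate into the
#' absolute risk. The standard error of a factor's log RR is recovered
#' from the selected level's 95% CI as `(log ci_high - log ci_low) /
#' (2 * 1.96)`. The gradient of `log(AR)` with respect to each factor's
#' log RR is computed by central finite differences, perturbing the
#' selected level's RR — which moves both the individual RR product and
#' that level's contribution to the population-mean RR (and hence the
#' baseline hazard), so the PAR feedback is captured. Factor estimates
#' are treated as independent; the CI is
#' `AR * exp(-+ z * SE(log AR))`, capped at 1.
#'
#' @inheritParams absolute_risk
#' @param level Coverage of the returned interval (default 0.95).
#' @param log_step Finite-difference step on the log-RR scale.
#' @return Named numeric vector `c(ci_low, ci_high)` bracketing the point
#'   estimate.
#' @export
delta_ci <- function(profile, factors, incidence_model, mortality,
                     level = 0.95, horizon = 10, log_step = 1e-4) {
  fdf <- tibble::as_tibble(unclass(factors))
  ar0 <- absolute_risk(profile, fdf, incidence_model, mortality, horizon)
  z_in <- ci_z(0.95)   # the input CIs are 95% intervals
  z_out <- ci_z(level)
  var_log <- 0
  for (f in unique(fdf$factor)) {
    sel <- as.list(profile$selections)[[f]]
    row <- which(fdf$factor == f & fdf$level == sel)
    if (length(row) != 1) abort(sprintf("no level selected for factor '%s'", f))
    lo <- fdf$ci_low[row]; hi <- fdf$ci_high[row]
    if (!is.finite(lo) || !is.finite(hi) || lo <= 0) {
      abort(sprintf("non-finite or non-positive CI for factor '%s' level '%s'",
                    f, sel))
    }
    se <- (log(hi) - log(lo)) / (2 * z_in)
    if (se == 0) next
    perturbed <- function(s) {
      d <- fdf
      d$rr[row] <- d$rr[row] * exp(s)
      absolute_risk(profile, d, incidence_model, mortality, horizon)
    }
    grad <- (log(perturbed(log_step)) - log(perturbed(-log_step))) /
      (2 * log_step)
    var_log <- var_log + (grad * se)^2
  }
  sd_log <- sqrt(var_log)
  c(ci_low = ar0 * exp(-z_out * sd_log),
    ci_high = min(1, ar0 * exp(z_out * sd_log)))
}

#' Display forms of a 10-year risk
#'
#' Converts a probability to the display quantities: risk per 1000
#' (rounded to one decimal), the "1 in N" form (`round(1000 / per_1000)`),
#' the count of filled circles in a 1000-circle pictogram, and a
#' qualitative category from fixed log-spaced bins on the per-1000 scale
#' (< 0.5 very low, 0.5–2 low, 2–8 moderate, 8–32 high, >= 32 very high).
#'
#' @param prob10 Probability in `[0, 1]` (vectorized). A zero probability
#'   yields the sentinel category `"none expected"` and `NA` for
#'   `one_in_n`.
#' @return A tibble with columns `prob10, per_1000, one_in_n, circles,
#'   category`.
#' @export
#' @examples
#' format_risk(0.0057)  # 5.7 per 1000, 1 in 175
#' format_risk(0.0340)  # 34.0 per 1000, 1 in 29
format_risk <- function(prob10) {
  stopifnot(all(prob10 >= 0), all(prob10 <= 1))
  per_1000 <- round(1000 * prob10, 1)
  one_in_n <- ifelse(per_1000 > 0, round(1000 / per_1000),
                     ifelse(prob10 > 0, round(1 / prob10), NA_real_))
  category <- as.character(cut(
    per_1000,
    breaks = c(-Inf, 0.5, 2, 8, 32, Inf),
    labels = c("very low", "low", "moderate", "high", "very high"),
    right = FALSE
  ))
  category[prob10 == 0] <- "none expected"
  one_in_n[prob10 == 0] <- NA_real_
  tibble::tibble(
    prob10 = prob10,
    per_1000 = per_1000,
    one_in_n = as.integer(one_in_n),
    circles = as.integer(round(per_1000)),
    category = category
  )
}

#' Ten-year mortality from selected causes, for display context
#'
#' For each cause, the probability of dying from that cause within the
#' horizon, treating all *other* mortality as the competing hazard — the
#' same actuarial machinery as [absolute_risk()]. These probabilities are
#' specific for age, sex and race but are population averages: they do not
#' consider non-demographic risk factors.
#'
#' @param age Age in years (40–89).
#' @param sex,race Demographic stratum.
#' @param cause_polys Named list of cause-specific mortality
#'   `rate_polynomial`s for this stratum.
#' @param allcause_poly All-cause mortality `rate_polynomial` for this
#'   stratum.
#' @param horizon Years (default 10).
#' @return A tibble with columns `cause` and `prob10`.
#' @export
comparator_mortality <- function(age, sex, race, cause_polys, allcause_poly,
                                 horizon = 10) {
  if (length(cause_polys) == 0) {
    stop_stratum(sex, race, "no cause-specific mortality rates for this stratum")
  }
  ages <- ages_midstep(age, horizon)
  m_all <- evaluate_rate(allcause_poly, ages)
  prob <- purrr::map_dbl(cause_polys, function(p) {
    h <- evaluate_rate(p, ages)
    cuminc_competing(h, pmax(m_all - h, 0))
  })
  tibble::tibble(cause = names(cause_polys), prob10 = as.numeric(prob))
}

#' Body mass index and WHO category
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in meters (> 0).
#' @return A tibble with `value` (kg/m^2) and `category` (WHO bins,
#'   left-closed: underweight < 18.5, normal 18.5–<25, overweight 25–<30,
#'   obese category I 30–<35, II 35–<40, III >= 40).
#' @export
#' @examples
#' bmi(85, 1.74)
bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    abort("weight and height must be positive")
  }
  value <- weight / height^2
  category <- as.character(cut(
    value,
    breaks = c(-Inf, 18.5, 25, 30, 35, 40, Inf),
    labels = c("underweight", "normal", "overweight",
               "obese category I", "obese category II", "obese category III"),
    right = FALSE
  ))
  tibble::tibble(value = value, category = category)
}
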