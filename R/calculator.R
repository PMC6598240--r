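#' Assemble a calculator from a configuration directory
#'
#' Loads the five parameter files (`risk_factors_general.csv`,
#' `risk_factors_be.csv`, `rates_incidence.csv`,
#' `rates_mortality_allcause.csv`, `rates_mortality_causes.csv`), fits the
#' cubic log-rate polynomials for every (sex, race) stratum present, and
#' bundles them with the Barrett's-stratum incidence model into a single
#' object that [estimate_risk()] and [score_profiles()] consume.
#'
#' @param config_dir Directory holding the five CSV files. Defaults to the
#'   packaged synthetic illustrative configuration, [eacrisk_config()].
#' @param be_model A [be_incidence_model()]; the default carries the
#'   published anchor (0.31%/year at age 62 for white men, 1.04 per year
#'   of age, 0.4 for white women, 0.75 for black men).
#' @return An object of class `eac_calculator`.
#' @export
#' @examples
#' calc <- eac_calculator()
#' names(calc$incidence)
eac_calculator <- function(config_dir = eacrisk_config(),
                           be_model = be_incidence_model()) {
  files <- c(
    risk_factors_general = "risk_factors_general.csv",
    risk_factors_be = "risk_factors_be.csv",
    rates_incidence = "rates_incidence.csv",
    rates_mortality_allcause = "rates_mortality_allcause.csv",
    rates_mortality_causes = "rates_mortality_causes.csv"
  )
  paths <- file.path(config_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(c(sprintf("config directory %s is missing required files:", config_dir),
            unname(missing)))
  }
  names(paths) <- names(files)

  factors <- list(
    unknown_or_negative = read_risk_factors(paths[["risk_factors_general"]],
                                            "unknown_or_negative"),
    positive = read_risk_factors(paths[["risk_factors_be"]], "positive")
  )
  inc_tab <- read_rate_table(paths[["rates_incidence"]], "eac_incidence")
  mort_tab <- read_rate_table(paths[["rates_mortality_allcause"]],
                              "all_cause_mortality")
  cause_tab <- read_rate_table(paths[["rates_mortality_causes"]],
                               "cause_specific_mortality")

  poly_list <- function(fit) {
    keyed <- split(fit$poly, paste(fit$sex, fit$race))
    lapply(keyed, `[[`, 1)
  }
  inc_fit <- fit_rate_polynomials(inc_tab)
  mort_fit <- fit_rate_polynomials(mort_tab)
  cause_fit <- fit_rate_polynomials(cause_tab)
  causes <- lapply(split(cause_fit, paste(cause_fit$sex, cause_fit$race)),
                   function(d) setNames(lapply(d$poly, identity), d$cause))

  structure(
    list(
      factors = factors,
      incidence = poly_list(inc_fit),
      mortality = poly_list(mort_fit),
      causes = causes,
      be_model = be_model,
      config_dir = normalizePath(config_dir)
    ),
    class = "eac_calculator"
  )
}

#' @export
print.eac_calculator <- function(x, ...) {
  cat("<eac_calculator>\n")
  cat("  config:", x$config_dir, "\n")
  cat("  incidence strata:", paste(names(x$incidence), collapse = ", "), "\n")
  cat("  mortality strata:", paste(names(x$mortality), collapse = ", "), "\n")
  cat("  factors (general):",
      paste(unique(x$factors$unknown_or_negative$factor), collapse = ", "), "\n")
  cat("  factors (Barrett's):",
      paste(unique(x$factors$positive$factor), collapse = ", "), "\n")
  invisible(x)
}

# baseline-hazard and mortality vectors for one demographic cell
hazard_vectors <- function(calc, age, sex, race, be_status, horizon = 10) {
  ages <- ages_midstep(age, horizon)
  key <- paste(sex, race)
  mort_poly <- calc$mortality[[key]]
  if (is.null(mort_poly)) stop_stratum(sex, race)
  if (identical(be_status, "positive")) {
    set <- calc$factors$positive
    inc <- be_incidence(calc$be_model, ages, sex, race)
  } else {
    set <- calc$factors$unknown_or_negative
    inc_poly <- calc$incidence[[key]]
    if (is.null(inc_poly)) stop_stratum(sex, race)
    inc <- evaluate_rate(inc_poly, ages)
  }
  list(h0 = inc / mean_population_rr(set),
       m = competing_mortality(mort_poly, ages),
       set = set)
}

reference_selections <- function(set) {
  ref <- set[set$is_reference, ]
  setNames(as.list(ref$level), ref$factor)
}

#' Estimate one individual's 10-year EAC risk
#'
#' High-level wrapper around [absolute_risk()], [delta_ci()],
#' [format_risk()] and [comparator_mortality()] for a single profile.
#'
#' @param calc An [eac_calculator()].
#' @param age Age in years, 40–89.
#' @param sex `"male"` or `"female"`.
#' @param race `"white"` or `"black"`.
#' @param be_status `"unknown_or_negative"` (not screened or Barrett's
#'   absent) or `"positive"` (diagnosed Barrett's esophagus); selects the
#'   factor set and incidence model.
#' @param selections Named list mapping factor names of the active set to
#'   level labels. Factors left out default to their reference level.
#' @param level CI coverage (default 0.95).
#' @param horizon Years (default 10).
#' @return An object of class `eac_risk`: point estimate, CI, display
#'   forms, the individual's RR product, and the comparator-mortality
#'   table. Has `print()`, `tidy()` and `glance()` methods.
#' @export
#' @examples
#' calc <- eac_calculator()
#' estimate_risk(calc, age = 60, sex = "male", race = "white",
#'               selections = list(sgerd = "weekly_to_daily"))
estimate_risk <- function(calc, age, sex, race,
                          be_status = c("unknown_or_negative", "positive"),
                          selections = list(), level = 0.95, horizon = 10) {
  stopifnot(inherits(calc, "eac_calculator"))
  be_status <- match.arg(be_status)
  if (age < 40 || age > 89) abort("age must be between 40 and 89")
  hz <- hazard_vectors(calc, age, sex, race, be_status, horizon)
  set <- hz$set
  sels <- modifyList(reference_selections(set), as.list(selections))
  extra <- setdiff(names(sels), unique(set$factor))
  if (length(extra) > 0) {
    abort(sprintf("selections name factors not in the active set: %s",
                  paste(extra, collapse = ", ")))
  }
  profile <- list(age = age, sex = sex, race = race, selections = sels)
  inc_model <- if (be_status == "positive") calc$be_model
               else calc$incidence[[paste(sex, race)]]
  mort <- calc$mortality[[paste(sex, race)]]
  ar <- absolute_risk(profile, set, inc_model, mort, horizon)
  ci <- delta_ci(profile, set, inc_model, mort, level, horizon)
  disp <- format_risk(ar)
  comp <- comparator_mortality(age, sex, race,
                               calc$causes[[paste(sex, race)]] %||% list(),
                               mort, horizon)
  structure(
    list(
      prob10 = ar, ci_low = unname(ci[["ci_low"]]),
      ci_high = unname(ci[["ci_high"]]),
      per_1000 = disp$per_1000, one_in_n = disp$one_in_n,
      circles = disp$circles, category = disp$category,
      relative_risk = individual_rr(set, sels),
      comparator_mortality = comp,
      profile = profile, be_status = be_status,
      level = level, horizon = horizon
    ),
    class = "eac_risk"
  )
}

#' @export
print.eac_risk <- function(x, ...) {
  p <- x$profile
  cat(sprintf("%d-year risk of esophageal adenocarcinoma\n", x$horizon))
  cat(sprintf("  profile: age %d, %s, %s, Barrett's %s\n",
              as.integer(p$age), p$sex, p$race,
              if (x$be_status == "positive") "positive" else "unknown/negative"))
  cat(sprintf("  relative risk (vs all-reference): %.2f\n", x$relative_risk))
  cat(sprintf("  risk: %.1f per 1000 (1 in %d), %.0f%% CI %.1f-%.1f per 1000\n",
              x$per_1000, x$one_in_n, 100 * x$level,
              1000 * x$ci_low, 1000 * x$ci_high))
  cat(sprintf("  category: %s\n", x$category))
  if (nrow(x$comparator_mortality) > 0) {
    cat(sprintf("  for context, %d-year mortality (per 1000): %s\n", x$horizon,
                paste(sprintf("%s %.1f", x$comparator_mortality$cause,
                              1000 * x$comparator_mortality$prob10),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a risk estimate into a one-row tibble
#'
#' @param x An `eac_risk` object.
#' @param ... Unused.
#' @return One-row tibble with the estimate, CI and display forms.
#' @method tidy eac_risk
#' @export
tidy.eac_risk <- function(x, ...) {
  tibble::tibble(
    age = x$profile$age, sex = x$profile$sex, race = x$profile$race,
    be_status = x$be_status,
    relative_risk = x$relative_risk,
    prob10 = x$prob10, ci_low = x$ci_low, ci_high = x$ci_high,
    per_1000 = x$per_1000, one_in_n = x$one_in_n, category = x$category
  )
}

#' @rdname tidy.eac_risk
#' @method glance eac_risk
#' @export
glance.eac_risk <- function(x, ...) {
  tibble::tibble(prob10 = x$prob10, ci_low = x$ci_low, ci_high = x$ci_high,
                 relative_risk = x$relative_risk, level = x$level,
                 horizon = x$horizon)
}

#' Score many profiles at once
#'
#' Batch interface: takes a data frame with one profile per row (columns
#' `age, sex, race`, optional `be_status`, and one column per factor of
#' the relevant set, holding level labels) and appends the RR product and
#' absolute risk. Rows sharing a demographic cell share the hazard
#' computation, so scoring scales to large record sets.
#'
#' @param profiles Data frame / tibble of profiles.
#' @param calc An [eac_calculator()].
#' @param horizon Years (default 10).
#' @return The input tibble with `relative_risk`, `prob10` and `per_1000`
#'   columns appended.
#' @export
score_profiles <- function(profiles, calc, horizon = 10) {
  stopifnot(inherits(calc, "eac_calculator"))
  profiles <- tibble::as_tibble(profiles)
  need <- c("age", "sex", "race")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("profiles lack columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"be_status" %in% names(profiles)) {
    profiles$be_status <- "unknown_or_negative"
  }
  if (any(profiles$age < 40 | profiles$age > 89)) {
    abort("profile ages must be between 40 and 89")
  }
  n <- nrow(profiles)
  rel <- rep(1, n)
  for (stratum in unique(profiles$be_status)) {
    idx <- profiles$be_status == stratum
    set <- calc$factors[[stratum]]
    if (is.null(set)) abort(sprintf("unknown be_status '%s'", stratum))
    for (f in unique(set$factor)) {
      if (!f %in% names(profiles)) {
        abort(sprintf("profiles lack a column for factor '%s'", f))
      }
      lv <- profiles[[f]][idx]
      if (anyNA(lv)) {
        bad <- which(idx)[which(is.na(lv))[1]]
        abort(sprintf("missing level for factor '%s' in row %d (impute first)",
                      f, bad))
      }
      sub <- set[set$factor == f, ]
      m <- match(lv, sub$level)
      if (anyNA(m)) {
        abort(sprintf("unknown level '%s' for factor '%s'",
                      lv[which(is.na(m))[1]], f))
      }
      rel[idx] <- rel[idx] * sub$rr[m]
    }
  }
  prob <- numeric(n)
  cell <- paste(profiles$age, profiles$sex, profiles$race, profiles$be_status)
  for (k in unique(cell)) {
    rows <- which(cell == k)
    i <- rows[1]
    hz <- hazard_vectors(calc, profiles$age[i], profiles$sex[i],
                         profiles$race[i], profiles$be_status[i], horizon)
    prob[rows] <- cuminc_competing_many(rel[rows], hz$h0, hz$m)
  }
  dplyr::mutate(profiles, relative_risk = rel, prob10 = prob,
                per_1000 = 1000 * prob)
}
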