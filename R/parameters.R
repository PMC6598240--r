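#' Read and validate a risk-factor set
#'
#' A risk-factor set is the calculator's table of multiplicative risk
#' factors for one Barrett's-esophagus stratum. Each factor has two or more
#' mutually exclusive levels; each level carries a relative risk (RR), its
#' 95% confidence interval, and its prevalence in the target population.
#' Exactly one level per factor is the reference (RR = 1), and a factor's
#' level prevalences must sum to 1.
#'
#' The CSV dialect is fixed: comma-separated, UTF-8, header row, `.` decimal
#' separator, columns `factor, level, rr, ci_low, ci_high, prevalence,
#' is_reference`.
#'
#' @param path Path to a CSV file with the columns listed above.
#' @param be_stratum Which stratum the file describes:
#'   `"unknown_or_negative"` (general population; Barrett's esophagus not
#'   diagnosed) or `"positive"` (diagnosed Barrett's esophagus).
#' @return A tibble of class `risk_factor_set` with one row per factor
#'   level and a `be_stratum` attribute.
#' @export
#' @examples
#' general <- read_risk_factors(
#'   file.path(eacrisk_config(), "risk_factors_general.csv"),
#'   be_stratum = "unknown_or_negative"
#' )
#' unique(general$factor)
read_risk_factors <- function(path,
                              be_stratum = c("unknown_or_negative", "positive")) {
  be_stratum <- match.arg(be_stratum)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    factor = readr::col_character(),
    level = readr::col_character(),
    rr = readr::col_double(),
    ci_low = readr::col_double(),
    ci_high = readr::col_double(),
    prevalence = readr::col_double(),
    is_reference = readr::col_logical()
  ), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "parse error in %s at line %d: expected %s, got '%s'",
      path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]
    ))
  }
  missing_cols <- setdiff(
    c("factor", "level", "rr", "ci_low", "ci_high", "prevalence", "is_reference"),
    names(df)
  )
  if (length(missing_cols) > 0) {
    abort(sprintf("parse error in %s: missing columns %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  risk_factor_set(df, be_stratum = be_stratum)
}

#' Construct a risk-factor set from a data frame
#'
#' Programmatic constructor for the object [read_risk_factors()] builds from
#' CSV. All invariants are checked; an invalid set is never returned.
#'
#' @param df Data frame with columns `factor, level, rr, ci_low, ci_high,
#'   prevalence, is_reference`.
#' @param be_stratum `"unknown_or_negative"` or `"positive"`.
#' @return A validated `risk_factor_set` tibble.
#' @export
risk_factor_set <- function(df, be_stratum = c("unknown_or_negative", "positive")) {
  be_stratum <- match.arg(be_stratum)
  df <- tibble::as_tibble(df)
  validate_risk_factor_set(df)
  attr(df, "be_stratum") <- be_stratum
  class(df) <- c("risk_factor_set", class(df))
  df
}

validate_risk_factor_set <- function(df) {
  need <- c("factor", "level", "rr", "ci_low", "ci_high", "prevalence", "is_reference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("risk factor table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(df[need])) {
    bad <- which(rowSums(is.na(df[need])) > 0)
    abort(sprintf("risk factor table has missing values in rows: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  fail <- function(factor, msg) {
    abort(sprintf("invalid risk factor '%s': %s", factor, msg),
          class = "eacrisk_validation_error")
  }
  for (f in unique(df$factor)) {
    sub <- df[df$factor == f, ]
    if (nrow(sub) < 2) fail(f, "needs at least 2 levels")
    if (anyDuplicated(sub$level)) fail(f, "duplicate level labels")
    if (any(sub$rr <= 0)) fail(f, "rr must be > 0")
    bad_ci <- sub$ci_low <= 0 | sub$ci_low > sub$rr | sub$ci_high < sub$rr
    if (any(bad_ci)) {
      fail(f, sprintf("level '%s' violates 0 < ci_low <= rr <= ci_high",
                      sub$level[which(bad_ci)[1]]))
    }
    if (any(sub$prevalence < 0 | sub$prevalence > 1)) {
      fail(f, "prevalences must lie in [0, 1]")
    }
    if (abs(sum(sub$prevalence) - 1) > 1e-9) {
      fail(f, sprintf("level prevalences sum to %.6f, not 1", sum(sub$prevalence)))
    }
    ref <- sub[sub$is_reference, ]
    if (nrow(ref) != 1) fail(f, "must have exactly one reference level")
    if (ref$rr != 1 || ref$ci_low != 1 || ref$ci_high != 1) {
      fail(f, "reference level must have rr = ci_low = ci_high = 1")
    }
  }
  invisible(df)
}

#' Write a risk-factor set to CSV
#'
#' Inverse of [read_risk_factors()]: the written file re-loads to a
#' field-for-field identical set.
#'
#' @param set A `risk_factor_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_factors <- function(set, path) {
  stopifnot(inherits(set, "risk_factor_set"))
  readr::write_csv(tibble::as_tibble(unclass(set)), path, progress = FALSE)
  invisible(path)
}

#' Read and validate an age-specific rate table
#'
#' Rate tables hold incidence or mortality rates (events per person-year)
#' in closed 5-year age groups, by sex and race, in the style of SEER /
#' NCHS extracts. Age groups within a stratum must be non-overlapping and
#' contiguous and cover at least ages 40 to 85+ (the open-ended top group
#' is written as 85–89).
#'
#' @param path CSV with columns `sex, race, age_lo, age_hi, rate` (plus
#'   `cause` when `outcome = "cause_specific_mortality"`).
#' @param outcome What the rates measure; determines required columns.
#' @return A tibble of class `rate_table` with an `outcome` attribute,
#'   containing every (sex, race) stratum present in the file. Strata
#'   absent from the file (for example black females, for whom reliable
#'   inputs are typically unavailable) simply have no rows; downstream
#'   scoring raises a "stratum unsupported" error rather than extrapolate.
#' @export
#' @examples
#' inc <- read_rate_table(
#'   file.path(eacrisk_config(), "rates_incidence.csv"),
#'   outcome = "eac_incidence"
#' )
#' dplyr::count(inc, sex, race)
read_rate_table <- function(path,
                            outcome = c("eac_incidence", "all_cause_mortality",
                                        "cause_specific_mortality")) {
  outcome <- match.arg(outcome)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  need <- c("sex", "race", "age_lo", "age_hi", "rate")
  if (outcome == "cause_specific_mortality") need <- c("cause", need)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("parse error in %s: missing columns %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  rate_table(df[need], outcome = outcome)
}

#' Construct a rate table from a data frame
#'
#' @param df Data frame with columns `sex, race, age_lo, age_hi, rate`
#'   (and optionally `cause`).
#' @param outcome `"eac_incidence"`, `"all_cause_mortality"` or
#'   `"cause_specific_mortality"`.
#' @return A validated `rate_table` tibble.
#' @export
rate_table <- function(df, outcome = c("eac_incidence", "all_cause_mortality",
                                       "cause_specific_mortality")) {
  outcome <- match.arg(outcome)
  df <- tibble::as_tibble(df)
  validate_rate_table(df)
  attr(df, "outcome") <- outcome
  class(df) <- c("rate_table", class(df))
  df
}

validate_rate_table <- function(df) {
  need <- c("sex", "race", "age_lo", "age_hi", "rate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("rate table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(df[need])) abort("rate table has missing values")
  if (any(df$rate < 0)) abort("rates must be >= 0", class = "eacrisk_validation_error")
  keys <- c(intersect("cause", names(df)), "sex", "race")
  split_df <- split(df, interaction(df[keys], drop = TRUE))
  for (sub in split_df) {
    lab <- paste(unlist(sub[1, keys]), collapse = " ")
    sub <- sub[order(sub$age_lo), ]
    if (any(sub$age_hi < sub$age_lo)) {
      abort(sprintf("stratum %s: age_hi < age_lo", lab),
            class = "eacrisk_validation_error")
    }
    if (nrow(sub) > 1) {
      gap <- sub$age_lo[-1] != sub$age_hi[-nrow(sub)] + 1
      if (any(gap)) {
        i <- which(gap)[1]
        abort(sprintf(
          "stratum %s: age groups not contiguous between %d-%d and %d-%d",
          lab, sub$age_lo[i], sub$age_hi[i], sub$age_lo[i + 1], sub$age_hi[i + 1]
        ), class = "eacrisk_validation_error")
      }
    }
    if (min(sub$age_lo) > 40 || max(sub$age_hi) < 85) {
      abort(sprintf("stratum %s: age groups must cover at least [40, 85]", lab),
            class = "eacrisk_validation_error")
    }
  }
  invisible(df)
}
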