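#' Generate a synthetic age-specific rate table
#'
#' Builds a 5-year age-group table (40–44 through 85+, stored as 85–89)
#' from a named generator, for offline testing of the smoothing and
#' scoring pipeline:
#'
#' * `"constant"`: `params$rate` everywhere;
#' * `"gompertz"`: `a * exp(b * midpoint)` — consecutive-midpoint rate
#'   ratio is exactly `exp(5 b)`;
#' * `"cubic"`: `exp(c0 + c1 x + c2 x^2 + c3 x^3)` at midpoints `x` —
#'   exactly recoverable by [fit_rate_polynomial()].
#'
#' @param shape Generator name.
#' @param params Named list of generator parameters (`rate`; `a`, `b`;
#'   or `c0..c3`). Scale parameters (`rate`, `a`) must be positive.
#' @param sex,race Stratum labels attached to the rows.
#' @param outcome Outcome label for the resulting `rate_table`.
#' @return A validated `rate_table` with 10 rows.
#' @export
#' @examples
#' generate_rate_table("gompertz", list(a = 2e-5, b = 0.08))
generate_rate_table <- function(shape = c("constant", "gompertz", "cubic"),
                                params = list(),
                                sex = "male", race = "white",
                                outcome = "eac_incidence") {
  shape <- match.arg(shape)
  age_lo <- seq(40, 85, by = 5)
  age_hi <- age_lo + 4
  mid <- (age_lo + age_hi) / 2
  rate <- switch(shape,
    constant = {
      if (is.null(params$rate) || params$rate <= 0) {
        abort("constant generator needs a positive 'rate'")
      }
      rep(params$rate, length(mid))
    },
    gompertz = {
      if (is.null(params$a) || params$a <= 0) {
        abort("gompertz generator needs a positive scale 'a'")
      }
      if (is.null(params$b)) abort("gompertz generator needs a slope 'b'")
      params$a * exp(params$b * mid)
    },
    cubic = {
      cc <- params[c("c0", "c1", "c2", "c3")]
      if (any(vapply(cc, is.null, logical(1)))) {
        abort("cubic generator needs coefficients c0, c1, c2, c3")
      }
      exp(cc$c0 + cc$c1 * mid + cc$c2 * mid^2 + cc$c3 * mid^3)
    }
  )
  rate_table(
    tibble::tibble(sex = sex, race = race, age_lo = age_lo,
                   age_hi = age_hi, rate = rate),
    outcome = if (outcome == "eac_incidence") "eac_incidence"
              else "all_cause_mortality"
  )
}

#' Generate a synthetic case-control population with known ground truth
#'
#' Emulates pooled population-based case-control data: controls draw each
#' factor level independently from the set's prevalences; cases draw from
#' the RR-tilted level distribution (the multi-level generalization of
#' [case_prevalence_from_or()], so empirical case/control odds ratios
#' converge to the set's RRs — under the rare-disease assumption RRs and
#' ORs coincide). Ages are drawn from a reference (age-group, sex)
#' distribution shared by cases and controls, mirroring how controls are
#' ascertained to match cases. Optional missingness is
#' missing-completely-at-random. Byte-identical output for a fixed seed.
#'
#' @param n_cases,n_controls Arm sizes (> 0).
#' @param factors A `risk_factor_set` providing the ground-truth RRs and
#'   control prevalences.
#' @param reference Tibble `age_lo, age_hi, sex, proportion` to draw
#'   demographics from; defaults to a flat 40–84 distribution over both
#'   sexes. Ages are uniform integers within the drawn group.
#' @param race Race label for all records.
#' @param missing_rate MCAR missingness proportion applied to every
#'   factor column (default 0).
#' @param seed Integer seed.
#' @return Tibble with `is_case, age, sex, race, weight` and one column
#'   per factor.
#' @export
generate_case_control <- function(n_cases, n_controls, factors,
                                  reference = NULL, race = "white",
                                  missing_rate = 0, seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0, missing_rate >= 0, missing_rate < 1)
  fdf <- tibble::as_tibble(unclass(factors))
  if (is.null(reference)) {
    reference <- tidyr::expand_grid(
      tibble::tibble(age_lo = seq(40, 80, 5), age_hi = seq(44, 84, 5)),
      sex = c("male", "female")
    )
    reference$proportion <- 1 / nrow(reference)
  }
  reference$proportion <- reference$proportion / sum(reference$proportion)
  n <- n_cases + n_controls
  withr::with_seed(seed, {
    cell <- sample.int(nrow(reference), n, replace = TRUE,
                       prob = reference$proportion)
    width <- reference$age_hi[cell] - reference$age_lo[cell] + 1
    age <- reference$age_lo[cell] + floor(runif(n) * width)
    out <- tibble::tibble(
      is_case = rep(c(TRUE, FALSE), c(n_cases, n_controls)),
      age = as.integer(age),
      sex = reference$sex[cell],
      race = race,
      weight = 1
    )
    for (f in unique(fdf$factor)) {
      sub <- fdf[fdf$factor == f, ]
      p_ctrl <- sub$prevalence / sum(sub$prevalence)
      p_case <- case_level_probs(p_ctrl, sub$rr)
      out[[f]] <- ifelse(
        out$is_case,
        sample(sub$level, n, replace = TRUE, prob = p_case),
        sample(sub$level, n, replace = TRUE, prob = p_ctrl)
      )
      if (missing_rate > 0) {
        out[[f]][runif(n) < missing_rate] <- NA_character_
      }
    }
    out
  })
}
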