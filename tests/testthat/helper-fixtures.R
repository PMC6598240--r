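# shared fixtures, all built in code

# one binary factor: reference (prev 1-p) and an exposed level with given rr
one_factor_set <- function(p = 0.4, rr = 2, ci_low = 0.7 * rr,
                           ci_high = 1.45 * rr, name = "exposure") {
  risk_factor_set(tibble::tibble(
    factor = name,
    level = c("ref", "exposed"),
    rr = c(1, rr),
    ci_low = c(1, ci_low),
    ci_high = c(1, ci_high),
    prevalence = c(1 - p, p),
    is_reference = c(TRUE, FALSE)
  ))
}

# two independent factors with known RRs, used as simulation ground truth
toy_factor_set <- function() {
  risk_factor_set(dplyr::bind_rows(
    tibble::tibble(factor = "exposure", level = c("ref", "exposed"),
                   rr = c(1, 3), ci_low = c(1, 2), ci_high = c(1, 4.5),
                   prevalence = c(0.5, 0.5), is_reference = c(TRUE, FALSE)),
    tibble::tibble(factor = "protect", level = c("none", "user"),
                   rr = c(1, 0.5), ci_low = c(1, 0.4), ci_high = c(1, 0.7),
                   prevalence = c(0.6, 0.4), is_reference = c(TRUE, FALSE))
  ))
}

# constant-rate polynomial (exact on the log scale)
const_poly <- function(rate, age_min = 40, age_max = 89) {
  rate_polynomial(c0 = log(rate), age_min = age_min, age_max = age_max)
}

# the packaged calculator, built once per test run
packaged_calc <- local({
  calc <- NULL
  function() {
    if (is.null(calc)) calc <<- eac_calculator()
    calc
  }
})

# draw n profiles from a factor set's prevalence distribution (independent
# factors), as a tibble score_profiles() accepts
draw_profiles <- function(n, set, age = 60, sex = "male", race = "white",
                          be_status = "unknown_or_negative", seed = 1L) {
  df <- tibble::as_tibble(unclass(set))
  withr::with_seed(seed, {
    out <- tibble::tibble(age = age, sex = sex, race = race,
                          be_status = be_status, .rows = n)
    for (f in unique(df$factor)) {
      sub <- df[df$factor == f, ]
      out[[f]] <- sample(sub$level, n, replace = TRUE, prob = sub$prevalence)
    }
    out
  })
}
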