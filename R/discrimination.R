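#' Case prevalence implied by a control prevalence and odds ratio
#'
#' When a covariate is unmeasured in case-control data, it can be
#' assigned at random so that the case/control contrast reproduces a
#' predetermined odds ratio. For a binary factor with control prevalence
#' `p0` and target OR, the case prevalence is `OR*q / (1 + OR*q)` with
#' `q = p0 / (1 - p0)`; the implied odds ratio then equals the target
#' exactly. For example, with 33% of controls exposed and OR 0.57, about
#' 22% of cases are assigned exposure.
#'
#' @param control_prev Control-group prevalence, strictly inside (0, 1).
#' @param odds_ratio Target odds ratio (> 0).
#' @return The case-group prevalence.
#' @export
#' @examples
#' case_prevalence_from_or(0.33, 0.57)  # ~0.219
case_prevalence_from_or <- function(control_prev, odds_ratio) {
  if (any(control_prev <= 0) || any(control_prev >= 1)) {
    abort("control_prev must be strictly between 0 and 1")
  }
  if (any(odds_ratio <= 0)) abort("odds_ratio must be positive")
  q <- control_prev / (1 - control_prev)
  odds_ratio * q / (1 + odds_ratio * q)
}

# multi-level generalization: case level probabilities are control
# prevalences tilted by the level RRs (treated as ORs), renormalized
case_level_probs <- function(control_prevs, rrs) {
  stopifnot(length(control_prevs) == length(rrs))
  w <- control_prevs * rrs
  w / sum(w)
}

#' Randomly assign an unmeasured factor to case-control records
#'
#' Controls draw levels from the stated control prevalences; cases draw
#' from the RR-tilted distribution (see [case_prevalence_from_or()] and
#' its multi-level generalization), so the empirical case/control odds
#' ratios converge to the factor's RRs as the sample grows. Deterministic
#' given the seed.
#'
#' @param records Tibble with at least `is_case`; must not already have a
#'   column named after the factor.
#' @param factor_rows The factor's rows from a `risk_factor_set` (one row
#'   per level, with `level`, `rr`, `prevalence`), or the whole set plus
#'   `factor_name`.
#' @param factor_name Name of the factor to assign (and of the new
#'   column). Defaults to the single factor present in `factor_rows`.
#' @param control_prevalences Optional override of the control-level
#'   prevalences (defaults to the factor's `prevalence` column).
#' @param seed Integer seed.
#' @return `records` with the new factor column appended.
#' @export
assign_unmeasured <- function(records, factor_rows, factor_name = NULL,
                              control_prevalences = NULL, seed = 1L) {
  records <- tibble::as_tibble(records)
  factor_rows <- tibble::as_tibble(unclass(factor_rows))
  if (!is.null(factor_name)) {
    factor_rows <- factor_rows[factor_rows$factor == factor_name, ]
  } else {
    factor_name <- unique(factor_rows$factor)
  }
  if (length(factor_name) != 1 || nrow(factor_rows) < 1) {
    abort("factor_rows must describe exactly one factor")
  }
  if (factor_name %in% names(records)) {
    abort(sprintf("factor '%s' is already present in the records", factor_name))
  }
  p_control <- control_prevalences %||% factor_rows$prevalence
  stopifnot(length(p_control) == nrow(factor_rows), all(p_control >= 0))
  p_control <- p_control / sum(p_control)
  p_case <- case_level_probs(p_control, factor_rows$rr)
  lv <- factor_rows$level
  withr::with_seed(seed, {
    records[[factor_name]] <- ifelse(
      records$is_case,
      sample(lv, nrow(records), replace = TRUE, prob = p_case),
      sample(lv, nrow(records), replace = TRUE, prob = p_control)
    )
  })
  records
}

#' Hot-deck multiple imputation of missing factor levels
#'
#' Each missing level is drawn from the observed level distribution among
#' donor records matching on case status, sex and 10-year age band. Cells
#' with no observed donors fall back to the factor's marginal observed
#' distribution (a message records the fallback). Produces `m`
#' independently completed copies of the record set; downstream risks are
#' averaged across copies.
#'
#' @param records Tibble with `is_case`, `age`, `sex` and factor columns;
#'   missingness (`NA`) is allowed only in factor columns.
#' @param factor_cols Character vector of factor column names to impute.
#' @param seed Integer seed.
#' @param m Number of completed copies (default 10).
#' @return A list of `m` tibbles with no missing factor levels.
#' @export
impute_missing <- function(records, factor_cols, seed = 1L, m = 10L) {
  records <- tibble::as_tibble(records)
  stopifnot(all(factor_cols %in% names(records)))
  if (anyNA(records$age) || anyNA(records$sex) || anyNA(records$is_case)) {
    abort("demographics (is_case, age, sex) must be complete")
  }
  band <- 10 * (records$age %/% 10)
  cell <- paste(records$is_case, records$sex, band)
  # donor pools per (factor, cell), built once
  pools <- lapply(setNames(factor_cols, factor_cols), function(f) {
    obs <- !is.na(records[[f]])
    if (!any(obs)) {
      abort(sprintf("factor '%s' has no observed values to impute from", f))
    }
    list(by_cell = split(records[[f]][obs], cell[obs]),
         marginal = records[[f]][obs])
  })
  withr::with_seed(seed, {
    lapply(seq_len(m), function(rep) {
      out <- records
      for (f in factor_cols) {
        miss <- which(is.na(out[[f]]))
        if (length(miss) == 0) next
        for (cl in unique(cell[miss])) {
          rows <- miss[cell[miss] == cl]
          donors <- pools[[f]]$by_cell[[cl]]
          if (is.null(donors)) {
            inform(sprintf(
              "impute_missing: no donors for factor '%s' in cell '%s'; using marginal",
              f, cl))
            donors <- pools[[f]]$marginal
          }
          out[[f]][rows] <- sample(donors, length(rows), replace = TRUE)
        }
      }
      out
    })
  })
}

#' Post-stratify control weights to a reference population
#'
#' Controls ascertained to match cases on age and sex do not represent
#' the general population; their weights are adjusted so the weighted
#' control distribution over (age group, sex) cells equals a reference
#' population distribution. Each control's weight is multiplied by
#' (reference proportion / weighted sample proportion) for its cell, then
#' renormalized so the weights sum to the control count. Case weights are
#' untouched.
#'
#' @param records Tibble with `is_case`, `age`, `sex` and a `weight`
#'   column (created as 1 if absent).
#' @param reference Tibble with columns `age_lo, age_hi, sex, proportion`
#'   covering every control's (age group, sex) cell; proportions are
#'   normalized internally.
#' @return `records` with updated control weights.
#' @export
reweight_controls <- function(records, reference) {
  records <- tibble::as_tibble(records)
  reference <- tibble::as_tibble(reference)
  stopifnot(all(c("age_lo", "age_hi", "sex", "proportion") %in% names(reference)))
  if (!"weight" %in% names(records)) records$weight <- 1
  if (any(records$weight < 0)) abort("weights must be non-negative")
  reference$proportion <- reference$proportion / sum(reference$proportion)
  ctrl <- !records$is_case
  if (!any(ctrl)) return(records)
  cell_of <- function(age, sex) {
    i <- purrr::map_int(seq_along(age), function(j) {
      hit <- which(reference$sex == sex[j] &
                     reference$age_lo <= age[j] & age[j] <= reference$age_hi)
      if (length(hit) != 1) NA_integer_ else hit
    })
    i
  }
  idx <- cell_of(records$age[ctrl], records$sex[ctrl])
  if (anyNA(idx)) {
    miss <- unique(paste(records$sex[ctrl][is.na(idx)],
                         records$age[ctrl][is.na(idx)]))
    abort(c("controls fall outside the reference cells:", head(miss, 5)))
  }
  empty <- setdiff(which(reference$proportion > 0), unique(idx))
  if (length(empty) > 0) {
    abort(c("reference cells with nonzero mass have no sample controls:",
            paste(reference$sex[empty], reference$age_lo[empty],
                  reference$age_hi[empty])))
  }
  w <- records$weight[ctrl]
  samp_prop <- tapply(w, idx, sum) / sum(w)
  ref_prop <- reference$proportion[as.integer(names(samp_prop))]
  ratio <- setNames(ref_prop / samp_prop, names(samp_prop))
  new_w <- w * ratio[as.character(idx)]
  new_w <- new_w * length(new_w) / sum(new_w)
  records$weight[ctrl] <- as.numeric(new_w)
  records
}

#' Score case-control records with the calculator
#'
#' Thin delegation to [score_profiles()]; accepts either one completed
#' record set or the list of completions from [impute_missing()], in
#' which case each record's risk is the average across completions.
#'
#' @param records A tibble of completed records, or a list of tibbles
#'   (multiple imputations of the same records, same row order).
#' @param calc An [eac_calculator()].
#' @param horizon Years (default 10).
#' @return A scored tibble with `relative_risk`, `prob10`, `per_1000`.
#' @export
score_records <- function(records, calc, horizon = 10) {
  if (is.data.frame(records)) {
    return(score_profiles(records, calc, horizon))
  }
  scored <- purrr::map(records, score_profiles, calc = calc, horizon = horizon)
  out <- scored[[1]]
  probs <- purrr::map(scored, "prob10")
  rels <- purrr::map(scored, "relative_risk")
  out$prob10 <- Reduce(`+`, probs) / length(probs)
  out$relative_risk <- Reduce(`+`, rels) / length(rels)
  out$per_1000 <- 1000 * out$prob10
  out
}

# weighted AUC: probability a random case outscores a random control,
# ties counted half, via sorted controls and cumulative weights
weighted_auc <- function(case_scores, case_w, ctrl_scores, ctrl_w) {
  o <- order(ctrl_scores)
  cs <- ctrl_scores[o]
  cw <- ctrl_w[o]
  cum_lt <- c(0, cumsum(cw))
  below <- cum_lt[findInterval(case_scores, cs, left.open = TRUE) + 1]
  upper <- cum_lt[findInterval(case_scores, cs) + 1]
  ties <- upper - below
  sum(case_w * (below + 0.5 * ties)) / (sum(case_w) * sum(ctrl_w))
}

#' Weighted discrimination metrics over all risk thresholds
#'
#' At each candidate threshold (every distinct observed risk), computes
#' the weighted sensitivity (fraction of case weight at or above the
#' threshold), specificity (fraction of control weight below it), and a
#' model-based positive predictive value. Because case-control data carry
#' no population prevalence, the PPV at a threshold is the
#' prevalence-weighted mean *model* risk among the weighted controls
#' flagged at that threshold — the controls, post-stratified to the
#' population, act as the population proxy, and each flagged person
#' contributes their own predicted probability of becoming a case.
#'
#' The AUC is the weighted probability that a random case outscores a
#' random control (ties count half), with a stratified bootstrap CI
#' (cases and controls resampled separately).
#'
#' @param scored Tibble from [score_records()] with `is_case`, `per_1000`
#'   (or `prob10`) and optional `weight`.
#' @param risk_col Column holding the risk score (default `"per_1000"`).
#' @param boot_reps Bootstrap replicates for the AUC CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param level CI coverage (default 0.95).
#' @return An object of class `eac_discrimination`: `curves` (tibble of
#'   threshold, sensitivity, specificity, ppv), `auc`, `auc_ci`, counts.
#'   Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
threshold_metrics <- function(scored, risk_col = "per_1000",
                              boot_reps = 1000L, seed = 1L, level = 0.95) {
  scored <- tibble::as_tibble(scored)
  stopifnot(risk_col %in% names(scored), "is_case" %in% names(scored))
  if (!"weight" %in% names(scored)) scored$weight <- 1
  if (!"prob10" %in% names(scored)) scored$prob10 <- scored[[risk_col]] / 1000
  risk <- scored[[risk_col]]
  w <- scored$weight
  case <- scored$is_case & w > 0
  ctrl <- !scored$is_case & w > 0
  if (!any(case) || !any(ctrl)) {
    abort("need at least one case and one control with positive weight")
  }
  thresholds <- sort(unique(risk))
  w_case <- sum(w[case]); w_ctrl <- sum(w[ctrl])
  sens <- purrr::map_dbl(thresholds, ~ sum(w[case & risk >= .x]) / w_case)
  spec <- purrr::map_dbl(thresholds, ~ sum(w[ctrl & risk < .x]) / w_ctrl)
  ppv <- purrr::map_dbl(thresholds, function(t) {
    flag <- ctrl & risk >= t
    if (!any(flag)) return(NA_real_)
    sum(w[flag] * scored$prob10[flag]) / sum(w[flag])
  })
  auc <- weighted_auc(risk[case], w[case], risk[ctrl], w[ctrl])
  ci <- if (boot_reps > 0) {
    ic <- which(case); iv <- which(ctrl)
    boots <- withr::with_seed(seed, {
      purrr::map_dbl(seq_len(boot_reps), function(b) {
        bc <- sample(ic, length(ic), replace = TRUE)
        bv <- sample(iv, length(iv), replace = TRUE)
        weighted_auc(risk[bc], w[bc], risk[bv], w[bv])
      })
    })
    unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      curves = tibble::tibble(threshold = thresholds, sensitivity = sens,
                              specificity = spec, ppv = ppv),
      auc = auc, auc_ci = ci, level = level,
      n_cases = sum(case), n_controls = sum(ctrl),
      boot_reps = boot_reps
    ),
    class = "eac_discrimination"
  )
}

#' @export
print.eac_discrimination <- function(x, ...) {
  cat("<eac_discrimination>\n")
  cat(sprintf("  %d cases, %d controls (weighted)\n", x$n_cases, x$n_controls))
  cat(sprintf("  AUC %.3f (%.0f%% CI %.3f-%.3f, %d bootstrap reps)\n",
              x$auc, 100 * x$level, x$auc_ci[1], x$auc_ci[2], x$boot_reps))
  cat(sprintf("  %d thresholds from %.3g to %.3g\n",
              nrow(x$curves), min(x$curves$threshold), max(x$curves$threshold)))
  invisible(x)
}

#' Tidy discrimination curves
#'
#' @param x An `eac_discrimination` object.
#' @param ... Unused.
#' @return `tidy()`: the threshold-by-metric curves tibble. `glance()`:
#'   a one-row tibble with the AUC and its CI.
#' @method tidy eac_discrimination
#' @export
tidy.eac_discrimination <- function(x, ...) x$curves

#' @rdname tidy.eac_discrimination
#' @method glance eac_discrimination
#' @export
glance.eac_discrimination <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_ci_low = x$auc_ci[1],
                 auc_ci_high = x$auc_ci[2], level = x$level,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}
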