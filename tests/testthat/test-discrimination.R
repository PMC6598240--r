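# exhaustive weighted pairwise AUC oracle, O(cases x controls)
auc_pairwise_oracle <- function(scores, is_case, w) {
  cs <- scores[is_case]; cw <- w[is_case]
  vs <- scores[!is_case]; vw <- w[!is_case]
  num <- 0
  for (i in seq_along(cs)) {
    for (j in seq_along(vs)) {
      num <- num + cw[i] * vw[j] *
        (if (cs[i] > vs[j]) 1 else if (cs[i] == vs[j]) 0.5 else 0)
    }
  }
  num / (sum(cw) * sum(vw))
}

test_that("constrained assignment reproduces the target odds ratio in closed form", {
  expect_equal(case_prevalence_from_or(0.33, 0.57), 0.2192, tolerance = 1e-4)
  expect_equal(case_prevalence_from_or(0.4, 1), 0.4)
  expect_equal(case_prevalence_from_or(0.5, 3), 0.75)
  # the implied case/control odds ratio equals the input exactly
  p0 <- 0.27; or <- 2.3
  p1 <- case_prevalence_from_or(p0, or)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), or)
  expect_error(case_prevalence_from_or(0, 2), "between 0 and 1")
  expect_error(case_prevalence_from_or(1, 2), "between 0 and 1")
  expect_error(case_prevalence_from_or(0.5, -1), "positive")
})

test_that("random assignment of an unmeasured factor hits its prevalence targets", {
  n <- 200000
  records <- tibble::tibble(is_case = rep(c(TRUE, FALSE), each = n),
                            age = 60L, sex = "male")
  statin <- tibble::tibble(factor = "statin", level = c("nonuser", "user"),
                           rr = c(1, 0.57), ci_low = c(1, 0.43),
                           ci_high = c(1, 0.75), prevalence = c(0.67, 0.33),
                           is_reference = c(TRUE, FALSE))
  out <- assign_unmeasured(records, statin, seed = 5)
  ctrl_prev <- mean(out$statin[!out$is_case] == "user")
  case_prev <- mean(out$statin[out$is_case] == "user")
  expect_equal(ctrl_prev, 0.33, tolerance = 0.005 / 0.33)
  expect_lt(abs(case_prev - 0.219), 0.005)
  # deterministic given seed, and refuses to overwrite
  out2 <- assign_unmeasured(records, statin, seed = 5)
  expect_identical(out, out2)
  expect_error(assign_unmeasured(out, statin, seed = 5), "already present")
  # degenerate prevalence puts every record on that level
  degen <- statin; degen$prevalence <- c(1, 0)
  all_ref <- assign_unmeasured(records[1:100, ], degen, seed = 1)
  expect_true(all(all_ref$statin == "nonuser"))
})

test_that("hot-deck imputation preserves structure and marginals", {
  set <- toy_factor_set()
  records <- generate_case_control(2000, 3000, set, seed = 21)
  # no missing values: every completion is the input
  done <- impute_missing(records, c("exposure", "protect"), seed = 3, m = 3)
  expect_length(done, 3)
  expect_identical(done[[1]], records)
  expect_identical(done[[2]], records)

  # 20% MCAR: pooled imputed frequencies match observed-complete frequencies
  miss <- generate_case_control(25000, 25000, set, missing_rate = 0.2, seed = 8)
  completions <- impute_missing(miss, c("exposure", "protect"), seed = 9, m = 5)
  for (comp in completions) {
    expect_false(anyNA(comp$exposure))
    expect_true(all(comp$exposure %in% c("ref", "exposed")))
  }
  was_missing <- is.na(miss$exposure)
  pooled_imputed <- mean(purrr::map_dbl(
    completions, ~ mean(.x$exposure[was_missing & !.x$is_case] == "exposed")
  ))
  observed <- mean(miss$exposure[!was_missing & !miss$is_case] == "exposed",
                   na.rm = TRUE)
  expect_lt(abs(pooled_imputed - observed), 0.02)
})

test_that("imputation falls back to the marginal when a cell has no donors", {
  records <- tibble::tibble(
    is_case = c(TRUE, TRUE, FALSE, FALSE),
    age = c(45L, 47L, 72L, 75L), sex = "male",
    f = c("a", "b", NA, NA)
  )
  # controls in their 70s have no observed donors at all
  expect_message(done <- impute_missing(records, "f", seed = 1, m = 2),
                 "marginal")
  expect_true(all(done[[1]]$f %in% c("a", "b")))
})

test_that("control reweighting matches the reference distribution exactly", {
  reference <- tibble::tibble(age_lo = c(40, 60), age_hi = c(59, 79),
                              sex = "male", proportion = c(0.5, 0.5))
  records <- tibble::tibble(
    is_case = FALSE, sex = "male",
    age = c(rep(50L, 80), rep(70L, 20))
  )
  out <- reweight_controls(records, reference)
  expect_equal(unique(out$weight[out$age == 50]), 0.625)
  expect_equal(unique(out$weight[out$age == 70]), 2.5)
  expect_equal(sum(out$weight), 100)
  # weighted proportions equal the reference
  wp <- tapply(out$weight, out$age >= 60, sum) / sum(out$weight)
  expect_equal(as.vector(wp), c(0.5, 0.5), tolerance = 1e-12)

  # already matched -> all weights 1
  bal <- tibble::tibble(is_case = FALSE, sex = "male",
                        age = rep(c(50L, 70L), each = 10))
  expect_equal(reweight_controls(bal, reference)$weight, rep(1, 20))

  # reference mass with no sample controls -> error listing cells
  ref3 <- tibble::tibble(age_lo = c(40, 60, 80), age_hi = c(59, 79, 89),
                         sex = "male", proportion = c(0.4, 0.4, 0.2))
  expect_error(reweight_controls(records, ref3), "no sample controls")
  # case weights untouched
  mixed <- dplyr::bind_rows(
    tibble::tibble(is_case = TRUE, sex = "male", age = 50L, weight = 7),
    dplyr::mutate(records, weight = 1)
  )
  expect_equal(reweight_controls(mixed, reference)$weight[1], 7)
})

test_that("record scoring delegates to the engine and is order-invariant", {
  calc <- packaged_calc()
  set <- calc$factors$unknown_or_negative
  records <- draw_profiles(50, set, seed = 31)
  records$is_case <- rep(c(TRUE, FALSE), 25)
  scored <- score_records(records, calc)
  est <- estimate_risk(calc, 60, "male", "white",
                       selections = as.list(records[1, unique(set$factor)]))
  expect_equal(scored$prob10[1], est$prob10)
  # permutation invariance
  perm <- withr::with_seed(4, sample(nrow(records)))
  scored_perm <- score_records(records[perm, ], calc)
  expect_equal(scored_perm$prob10, scored$prob10[perm])
  # duplicated records get identical scores
  dup <- score_records(records[c(1, 1), ], calc)
  expect_equal(dup$prob10[1], dup$prob10[2])
  # averaging across imputation copies equals the mean of per-copy scores
  copies <- list(records, dplyr::mutate(records, sgerd = "more_than_daily"))
  avg <- score_records(copies, calc)
  per_copy <- purrr::map(copies, ~ score_records(.x, calc)$prob10)
  expect_equal(avg$prob10, (per_copy[[1]] + per_copy[[2]]) / 2)
})

test_that("threshold metrics handle separation, ties and weighted toys", {
  sep <- tibble::tibble(is_case = rep(c(TRUE, FALSE), each = 5),
                        per_1000 = c(6:10, 1:5))
  res <- threshold_metrics(sep, boot_reps = 50, seed = 2)
  expect_equal(res$auc, 1)
  perfect <- res$curves$sensitivity == 1 & res$curves$specificity == 1
  expect_true(any(perfect))
  # all scores identical -> AUC 1/2 by the tie convention
  tied <- tibble::tibble(is_case = rep(c(TRUE, FALSE), 5), per_1000 = 2)
  expect_equal(threshold_metrics(tied, boot_reps = 0)$auc, 0.5)
  # weighted toy equals the exhaustive pairwise oracle
  toy <- tibble::tibble(
    is_case = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    per_1000 = c(5, 2, 8, 2, 3, 1),
    weight = c(1.5, 0.5, 2, 1, 2.5, 0.7)
  )
  res_toy <- threshold_metrics(toy, boot_reps = 0)
  expect_equal(res_toy$auc,
               auc_pairwise_oracle(toy$per_1000, toy$is_case, toy$weight),
               tolerance = 1e-12)
  expect_error(threshold_metrics(toy[toy$is_case, ], boot_reps = 0),
               "at least one case and one control")
})

test_that("pairwise AUC equals the trapezoidal area under the ROC curve", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 40
      df <- tibble::tibble(
        is_case = runif(n) < 0.4,
        per_1000 = round(rexp(n, 0.2), 1),  # rounding forces ties
        weight = runif(n, 0.2, 3)
      )
      if (!any(df$is_case) || all(df$is_case)) next
      res <- threshold_metrics(df, boot_reps = 0)
      x <- c(1 - res$curves$specificity, 0)
      y <- c(res$curves$sensitivity, 0)
      area <- sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
      expect_equal(res$auc, area, tolerance = 1e-9)
    }
  })
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set <- toy_factor_set()
  calc <- packaged_calc()
  records <- generate_case_control(400, 800, calc$factors$unknown_or_negative,
                                   race = "white", seed = 12)
  scored <- score_records(records, calc)
  res <- threshold_metrics(scored, boot_reps = 100, seed = 3)
  expect_true(all(diff(res$curves$sensitivity) <= 1e-12))
  expect_true(all(diff(res$curves$specificity) >= -1e-12))
  expect_gt(res$auc, 0.5)  # cases enriched in risk factors by construction
  expect_true(res$auc_ci[1] <= res$auc && res$auc <= res$auc_ci[2])
  # bootstrap CI is seeded: identical on re-run
  res2 <- threshold_metrics(scored, boot_reps = 100, seed = 3)
  expect_identical(res$auc_ci, res2$auc_ci)
  # reweighting to the sampling distribution leaves the AUC invariant
  tidy_curves <- tidy(res)
  expect_named(tidy_curves, c("threshold", "sensitivity", "specificity", "ppv"))
  expect_equal(glance(res)$auc, res$auc)
})
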