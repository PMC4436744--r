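test_that("imputation returns identical copies when nothing is missing", {
  tr <- simulate_trial(null_config(n = 16, visits = c(0, 6, 18)), seed = 3)
  imps <- impute_missing(tr, "wpfd", m = 3, seed = 9)
  expect_length(imps, 3)
  expect_identical(imps[[1]], imps[[2]])
  expect_identical(imps[[1]], imps[[3]])
  expect_equal(attr(imps, "outcome"), "wpfd")
})

test_that("imputed datasets are complete, deterministic, and never alter observed rows", {
  tr <- simulate_trial(null_config(n = 30, visits = c(0, 6, 18)), seed = 5)
  tr <- apply_missingness(tr, data.frame(arm = c("treatment", "control"),
                                         last_month = c(0, 6), n = c(3, 2)),
                          seed = 2)
  obs <- visit_totals(tr)
  imps <- impute_missing(tr, "wpfd", m = 4, seed = 11)

  expect_identical(imps, impute_missing(tr, "wpfd", m = 4, seed = 11))
  expect_false(identical(imps[[1]], imps[[2]]))  # draws differ across imputations

  for (k in 1:4) {
    tabk <- imps[[k]]
    # every subject at every scheduled visit
    expect_equal(nrow(tabk), 30 * 3)
    expect_true(all(table(tabk$subject_id) == 3))
    # observed cells unchanged
    merged <- merge(obs, tabk, by = c("subject_id", "visit_month"),
                    suffixes = c(".obs", ".imp"))
    expect_equal(merged$whole_grains.obs, merged$whole_grains.imp)
    expect_equal(merged$energy_kcal.obs, merged$energy_kcal.imp)
  }
})

test_that("MCAR-masked visits are recovered within pooled uncertainty", {
  tr <- simulate_trial(null_config(n = 136, visits = c(0, 6, 18)), seed = 42)
  tot <- visit_totals(tr)
  f <- tot[tot$visit_month == 18, ]
  full_diff <- hei_population_summary(f[f$arm == "treatment", ], "wpfd") -
    hei_population_summary(f[f$arm == "control", ], "wpfd")

  # delete 10% of post-baseline subject-visits completely at random
  set.seed(7)
  post <- which(tr$diet_days$visit_month > 0)
  keys <- unique(tr$diet_days[post, c("subject_id", "visit_month")])
  drop <- keys[sample.int(nrow(keys), round(0.1 * nrow(keys))), ]
  del <- paste(tr$diet_days$subject_id, tr$diet_days$visit_month) %in%
    paste(drop$subject_id, drop$visit_month)
  masked <- tr
  masked$diet_days <- tr$diet_days[!del, ]

  fit <- itt_permutation_test(masked, "wpfd", m = 5, n_perm = 199,
                              n_boot = 300, seed = 13)
  pooled <- fit$pooled_final_difference
  expect_lt(abs(pooled$pooled_estimate - full_diff),
            2 * sqrt(pooled$total_variance))
})

test_that("Rubin's combining rule matches the hand-worked example", {
  res <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(res$pooled_estimate, 2)
  expect_equal(res$within_variance, 1)
  expect_equal(res$between_variance, 2)
  expect_equal(res$total_variance, 1 + 1.5 * 2)   # within + (1 + 1/m) * between

  same <- pool_rubin(c(5, 5, 5), c(2, 2, 2))
  expect_equal(same$pooled_estimate, 5)
  expect_equal(same$between_variance, 0)
  expect_equal(same$total_variance, 2)
  expect_equal(same$df, Inf)                      # pooled inference = single-dataset

  expect_error(pool_rubin(1, 1), "at least 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "non-negative")

  set.seed(3)
  for (i in 1:25) {
    m <- sample(2:10, 1)
    res <- pool_rubin(stats::rnorm(m), stats::runif(m))
    expect_gte(res$total_variance, res$within_variance)
  }
})

test_that("probit combination of p-values is idempotent, monotone and clamped", {
  expect_equal(combine_permutation_p(rep(0.2, 5)), 0.2)
  expect_equal(combine_permutation_p(rep(1, 3)), 1)

  set.seed(6)
  for (i in 1:30) {
    p <- stats::runif(6, 0.01, 0.99)
    smaller <- p * stats::runif(6, 0.3, 1)
    expect_lte(combine_permutation_p(smaller), combine_permutation_p(p))
    expect_gt(combine_permutation_p(p), 0)
    expect_lte(combine_permutation_p(p), 1)
  }

  expect_warning(res <- combine_permutation_p(c(0, 0.01), n_perm = 999),
                 "clamped")
  expect_gt(res, 0)
  expect_error(combine_permutation_p(c(0, 0.5)), "n_perm")
  expect_error(combine_permutation_p(c(-0.1, 0.5)), "lie in")
})

test_that("the intent-to-treat wrapper combines imputations coherently", {
  tr <- simulate_trial(trial_config(n_subjects = 60,
                                    diet_visits = c(0, 6, 18),
                                    hba1c_visits = c(0, 6, 18),
                                    effect = study_effect_profile()),
                       seed = 19)
  fit <- itt_permutation_test(tr, "wpfd", m = 3, n_perm = 199, n_boot = 200,
                              seed = 23)
  expect_s3_class(fit, "dq_itt")
  expect_length(fit$p_per_imputation, 3)
  expect_gte(fit$p_value, 0)
  expect_lte(fit$p_value, 1)
  expect_identical(fit$p_value,
                   itt_permutation_test(tr, "wpfd", m = 3, n_perm = 199,
                                        n_boot = 200, seed = 23)$p_value)
})
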