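test_that("visit vectors line up with per-visit population ratios", {
  tab <- mk_ratio_table(4, visits = c(0, 6, 12), seed = 6)
  vv <- visit_vector(tab, "whole_grains", "treatment")
  expect_length(vv, 3)
  for (v in c(0, 6, 12)) {
    rows <- tab[tab$arm == "treatment" & tab$visit_month == v, ]
    expect_equal(unname(vv[as.character(v)]),
                 population_ratio(rows$whole_grains, rows$energy_kcal))
  }

  one <- tab[tab$visit_month == 0, ]
  v1 <- visit_vector(one, "whole_grains", "control")
  rows <- one[one$arm == "control", ]
  expect_equal(unname(v1), population_ratio(rows$whole_grains, rows$energy_kcal))

  # constant data across visits give a constant vector
  const <- tab
  base <- const[const$visit_month == 0, setdiff(names(const), "visit_month")]
  const <- do.call(rbind, lapply(c(0, 6, 12), function(v) cbind(base, visit_month = v)))
  vc <- visit_vector(const, "whole_grains", "treatment")
  expect_equal(max(vc) - min(vc), 0)

  empty_arm <- tab[!(tab$arm == "control" & tab$visit_month == 6), ]
  expect_error(visit_vector(empty_arm, "whole_grains", "control"), "visit month 6")
})

test_that("euclidean distance behaves like a metric coordinate-wise", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(8)
  for (i in 1:20) {
    u <- stats::rnorm(6); v <- stats::rnorm(6)
    expect_equal(euclidean_distance(u, v), euclidean_distance(v, u))
    expect_gte(euclidean_distance(u, v), 0)
  }
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
})

test_that("identical arms give observed distance 0 and p = 1", {
  half <- mk_ratio_table(3, visits = c(0, 6), seed = 2)
  half <- half[half$arm == "treatment", ]
  mirror <- half
  mirror$subject_id <- sub("T", "C", mirror$subject_id)
  mirror$arm <- "control"
  tab <- rbind(half, mirror)
  res <- permutation_test(tab, "whole_grains", n_perm = 200, seed = 4)
  expect_equal(res$observed_distance, 0)
  expect_equal(res$p_value, 1)
  expect_s3_class(res, "dq_permtest")
})

test_that("Monte-Carlo p matches exhaustive enumeration on a 3v3 dataset", {
  tab <- mk_ratio_table(3, visits = c(0, 6, 12), seed = 14)
  exact <- exact_perm_p(tab)                     # all 20 label splits
  mc <- permutation_test(tab, "whole_grains", n_perm = 5000, seed = 1)
  expect_equal(mc$observed_distance, exact$observed, tolerance = 1e-10)
  se <- sqrt(exact$p * (1 - exact$p) / mc$n_permutations)
  expect_lt(abs(mc$p_value - exact$p), 2 * se + 1e-9)
})

test_that("permutation bookkeeping invariants hold", {
  tab <- mk_ratio_table(5, seed = 3)
  res <- permutation_test(tab, "whole_grains", n_perm = 500, seed = 11)
  expect_equal(res$p_value, res$n_at_least_as_extreme / res$n_permutations)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_identical(res$p_value,
                   permutation_test(tab, "whole_grains", n_perm = 500,
                                    seed = 11)$p_value)
  expect_error(permutation_test(tab, "whole_grains", n_perm = 0), "at least 1")
})

test_that("incomplete datasets are rejected unless complete-case is requested", {
  tab <- mk_ratio_table(4, visits = c(0, 6), seed = 5)
  drop_one <- tab[-which(tab$subject_id == "T01" & tab$visit_month == 6), ]
  expect_error(permutation_test(drop_one, "whole_grains", n_perm = 50),
               "missing")
  res <- permutation_test(drop_one, "whole_grains", n_perm = 50, seed = 1,
                          complete_case = TRUE)
  expect_equal(res$n_subjects, 7)
})

test_that("the permutation test runs on scores and HbA1c, not just densities", {
  cfg <- null_config(n = 24, visits = c(0, 18))
  tr <- simulate_trial(cfg, seed = 55)
  for (oc in c("hei2005", "hba1c")) {
    res <- permutation_test(tr, oc, n_perm = 200, seed = 2)
    expect_true(res$p_value > 0 && res$p_value <= 1)
    expect_equal(unname(res$vector_treatment),
                 unname(visit_vector(tr, oc, "treatment")), tolerance = 1e-10)
    expect_equal(unname(res$vector_control),
                 unname(visit_vector(tr, oc, "control")), tolerance = 1e-10)
  }
})

test_that("baseline comparisons reproduce the standard tests", {
  # identical groups: t = 0, p = 1
  x <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  res <- baseline_comparison(x, g, "continuous")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # printed sex counts: males 35 treatment / 31 control, females 31 / 39
  sex <- matrix(c(35, 31, 31, 39), 2, byrow = TRUE,
                dimnames = list(c("male", "female"), c("treatment", "control")))
  res <- baseline_comparison(sex, kind = "categorical")
  expect_equal(round(res$p_value, 2), 0.31)

  # exactly equal proportions: chi-square 0, p = 1
  eq <- matrix(c(20, 10, 40, 20), 2)
  res <- baseline_comparison(eq, kind = "categorical")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  expect_warning(res <- baseline_comparison(rep(5, 8), rep(c("a", "b"), 4),
                                            "continuous"),
                 "zero variance")
  expect_equal(res$p_value, 1)
})
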