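test_that("record-day aggregation sums field-wise and validates input", {
  d <- mk_day(energy_kcal = 1500, total_fruit = 1.2, whole_grains = 2)
  tot <- aggregate_record(rbind(d, d, d))
  expect_equal(tot$energy_kcal, 4500)
  expect_equal(tot$total_fruit, 3.6)
  expect_equal(tot$whole_grains, 6)
  expect_equal(tot$n_days, 3)

  days <- rbind(mk_day(1500), mk_day(2000), mk_day(2500))
  expect_equal(aggregate_record(days)$energy_kcal, 6000)

  expect_error(aggregate_record(mk_day()[0, ]), "at least one")
  expect_error(aggregate_record(mk_day(energy_kcal = 0)), "energy")
  bad <- mk_day(); bad$milk <- -1
  expect_error(aggregate_record(bad), "non-negative")
})

test_that("legume allocation credits meat first, remainder to vegetables", {
  std <- hei_standards()

  no_leg <- mk_day(energy_kcal = 2000, meat_beans = 2, total_vegetables = 1)
  expect_identical(allocate_legumes(no_leg, std), no_leg)

  # meat already at its density standard: all legumes flow to vegetables 1:1
  full_meat <- mk_day(energy_kcal = 2000, meat_beans = 5, legumes = 0.5,
                      total_vegetables = 1, dark_green_orange_veg = 0.2)
  adj <- allocate_legumes(full_meat, std)
  expect_equal(adj$meat_beans, 5)
  expect_equal(adj$total_vegetables, 1.5)
  expect_equal(adj$dark_green_orange_veg, 0.7)

  # no meat, plenty of legumes: meat topped up to exactly its standard at
  # 4 oz-eq per cup-eq, remainder to vegetables
  leg_only <- mk_day(energy_kcal = 2000, meat_beans = 0, legumes = 2)
  adj <- allocate_legumes(leg_only, std)
  expect_equal(adj$meat_beans / adj$energy_kcal * 1000, 2.5) # exactly at standard
  expect_equal(adj$total_vegetables, 2 - 5 / 4)              # 0.75 cup-eq left
  expect_identical(leg_only$meat_beans, 0)                   # input unmodified
})

test_that("component scores follow proration, truncation and the anchors", {
  std <- hei_standards()
  fruit <- std[std$component == "total_fruit", ]
  expect_equal(score_component(0, fruit), 0)
  expect_equal(score_component(c(0.8, 1.5, 50), fruit), c(5, 5, 5))
  expect_equal(score_component(0.4, fruit), 2.5)

  satfat <- std[std$component == "saturated_fat", ]
  expect_equal(score_component(7, satfat), 10)
  expect_equal(score_component(10, satfat), 8)   # intermediate anchor
  expect_equal(score_component(15, satfat), 0)
  expect_equal(score_component(20, satfat), 0)

  sodium <- std[std$component == "sodium", ]
  expect_equal(score_component(1.1, sodium), 8)
  sofaas <- std[std$component == "sofaas", ]
  expect_equal(score_component(c(10, 20, 50, 80), sofaas), c(20, 20, 0, 0))
  expect_equal(score_component(35, sofaas), 10)  # midpoint of the linear leg
})

test_that("moderation scoring matches an independently coded piecewise oracle", {
  std <- hei_standards()
  set.seed(42)
  for (comp in c("saturated_fat", "sodium", "sofaas")) {
    spec <- std[std$component == comp, ]
    dens <- stats::runif(300, 0, spec$zero_value * 1.4)
    expect_equal(score_component(dens, spec),
                 oracle_moderation(dens, spec$max_points, spec$standard,
                                   spec$mid_value, spec$mid_points,
                                   spec$zero_value),
                 tolerance = 1e-12)
  }
})

test_that("HEI2005 totals hit 100 for ideal intake, 0 for worst intake", {
  sc <- score_hei2005(perfect_day())
  expect_equal(sc$hei2005_total, 100)
  expect_equal(score_hei2005(worst_day())$hei2005_total, 0)
  expect_error(score_hei2005(mk_day(energy_kcal = 0)), "energy")
})

test_that("HEI2005 and WPFD are invariant to scaling all fields", {
  tot <- random_intakes(50, seed = 7)
  for (c_scale in c(0.5, 2, 10)) {
    scaled <- tot * c_scale
    expect_equal(score_hei2005(scaled)$hei2005_total,
                 score_hei2005(tot)$hei2005_total, tolerance = 1e-12)
    expect_equal(compute_wpfd(scaled), compute_wpfd(tot), tolerance = 1e-12)
  }
})

test_that("HEI2005 component scores stay within bounds on random intakes", {
  std <- hei_standards()
  sc <- score_hei2005(random_intakes(200, seed = 11), std)
  for (i in seq_len(nrow(std))) {
    comp <- std$component[i]
    expect_true(all(sc[[comp]] >= 0 & sc[[comp]] <= std$max_points[i]))
  }
  expect_true(all(sc$hei2005_total >= 0 & sc$hei2005_total <= 100))
  expect_equal(sc$hei2005_total, rowSums(sc[std$component]))
})

test_that("adequacy scores are monotone in intake, moderation scores non-increasing", {
  base <- mk_day(energy_kcal = 2000, total_fruit = 0.5, saturated_fat = 20,
                 meat_beans = 5)
  std <- hei_standards()
  amounts <- seq(0, 4, by = 0.25)
  fruit_scores <- vapply(amounts, function(a) {
    b <- base; b$total_fruit <- a
    score_hei2005(b, std)$total_fruit
  }, numeric(1))
  expect_true(all(diff(fruit_scores) >= 0))
  sat_scores <- vapply(seq(0, 50, by = 2), function(a) {
    b <- base; b$saturated_fat <- a
    score_hei2005(b, std)$saturated_fat
  }, numeric(1))
  expect_true(all(diff(sat_scores) <= 0))
})

test_that("WPFD matches its definition", {
  tot <- mk_day(energy_kcal = 2000, whole_fruit = 1, total_vegetables = 1,
                whole_grains = 2)
  expect_equal(compute_wpfd(tot), 2.0)
  expect_equal(compute_wpfd(mk_day(energy_kcal = 1800)), 0)
  expect_error(compute_wpfd(mk_day(energy_kcal = 0)), "energy")
})

test_that("standards file is validated", {
  expect_silent(std <- hei_standards())
  expect_equal(sum(std$max_points), 100)
  tmp <- tempfile(fileext = ".csv")
  bad <- std; bad$max_points[1] <- 6
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(hei_standards(tmp), "sum to 100")
})
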