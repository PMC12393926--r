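test_that("fit_tgc and project_weight are exact inverses", {
  temps <- rep(23.5, 65)
  tgc <- fit_tgc(14.1, 47.8, temps)
  expect_equal(tgc, (47.8^(1 / 3) - 14.1^(1 / 3)) / sum(temps))
  w <- project_weight(14.1, temps, tgc)
  expect_length(w, 65)
  expect_equal(w[65], 47.8)
  # round-trip for a variable temperature series and another exponent
  set.seed(7)
  temps2 <- runif(40, 18, 26)
  tgc2 <- fit_tgc(10, 55, temps2, exponent = 0.4)
  expect_equal(project_weight(10, temps2, tgc2, exponent = 0.4)[40], 55)
})

test_that("projection is monotone for positive TGC", {
  w <- project_weight(14.1, rep(23.5, 65), 8e-4)
  expect_true(all(diff(w) > 0))
  expect_error(project_weight(14.1, rep(23.5, 65), -1),
               "non-positive weight")
})

test_that("feeding_table validates classes and lookup covers half-open intervals", {
  tbl <- feeding_table(data.frame(
    weight_min = c(10, 30), weight_max = c(30, 60),
    temp_min = 20, temp_max = 26, rate = c(3, 2)))
  expect_s3_class(tbl, "feeding_table")
  plan_tank <- demo_tank()
  tgc <- fit_tgc(14.1, 47.8, plan_tank$temperatures)
  plan <- build_feeding_plan(plan_tank, tbl, tgc)
  expect_equal(nrow(plan), 65)
  # rate follows the projected weight's class (half-open [min, max))
  expect_true(all(plan$rate[plan$mean_weight < 30] == 3))
  expect_true(all(plan$rate[plan$mean_weight >= 30] == 2))
  expect_equal(plan$ration, plan$biomass * plan$rate / 100)
  expect_error(feeding_table(data.frame(weight_min = 10, weight_max = 5,
                                        temp_min = 20, temp_max = 26,
                                        rate = 2)),
               "min < max")
  expect_error(feeding_table(data.frame(weight_min = 1, weight_max = 5,
                                        temp_min = 20, temp_max = 26,
                                        rate = 0)),
               "positive")
})

test_that("uncovered weight/temperature classes fail with the day named", {
  tbl <- feeding_table(data.frame(weight_min = 10, weight_max = 20,
                                  temp_min = 20, temp_max = 26, rate = 3))
  t <- demo_tank()
  tgc <- fit_tgc(14.1, 47.8, t$temperatures)
  expect_error(build_feeding_plan(t, tbl, tgc), "does not cover")
})

test_that("re-anchoring with the projected biomass leaves the plan unchanged", {
  tbl <- feeding_table(data.frame(weight_min = 5, weight_max = 100,
                                  temp_min = 20, temp_max = 26, rate = 2.5))
  t <- demo_tank()
  tgc <- fit_tgc(14.1, 47.8, t$temperatures)
  base <- build_feeding_plan(t, tbl, tgc)
  # biomass projected through day 29 = weight entering day 30's growth
  w29 <- base$mean_weight[29] * t$n_initial
  re <- build_feeding_plan(t, tbl, tgc,
                           anchors = data.frame(day = 30, biomass = w29))
  expect_equal(re$mean_weight, base$mean_weight)
  expect_equal(re$ration, base$ration)
  expect_true(re$anchored[30])

  # anchoring at a genuinely different biomass changes the plan from there on
  re2 <- build_feeding_plan(t, tbl, tgc,
                            anchors = data.frame(day = 30,
                                                 biomass = 0.9 * w29))
  expect_equal(re2$mean_weight[1:29], base$mean_weight[1:29])
  expect_true(all(re2$mean_weight[30:65] < base$mean_weight[30:65]))
})
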