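test_that("tank_record validates and recycles temperatures", {
  t <- demo_tank()
  expect_s3_class(t, "tank_record")
  expect_length(t$temperatures, 65)
  expect_true(all(t$temperatures == 23.5))
  expect_error(tank_record("T", "D", 90, 91, 100, 200, 50, 10, 23),
               "n_final exceeds n_initial")
  expect_error(tank_record("T", "D", 90, 85, 100, 200, 50, 10, rep(23, 9)),
               "temperature series length")
  expect_error(tank_record("T", "D", 90, 85, 0, 200, 50, 10, 23),
               "positive")
  expect_error(tank_record("T", "D", 90, 85, 100, 200, -1, 10, 23),
               "feed_distributed")
})

test_that("fish_morphometry checks organ weights against body weight", {
  df <- data.frame(body_weight = c(40, 50), total_length = c(13, 14),
                   viscera_weight = c(3, 4), liver_weight = c(0.6, 0.7))
  expect_s3_class(fish_morphometry(df), "tbl_df")
  df$viscera_weight[2] <- 60
  expect_error(fish_morphometry(df), "viscera_weight")
  expect_error(fish_morphometry(data.frame(body_weight = 1)),
               "total_length")
})

test_that("body_composition enforces the wet-basis consistency check", {
  expect_s3_class(body_composition("wet", dm = 30, protein = 17,
                                   lipid = 9, ash = 3.5, phosphorus = 0.45,
                                   energy = 7), "body_composition")
  expect_error(body_composition("wet", dm = 20, protein = 17, lipid = 9,
                                ash = 3.5, phosphorus = 0.45, energy = 7),
               "exceeds dry matter")
  # the check is wet-basis only
  expect_no_error(body_composition("dry", dm = 100, protein = 55,
                                   lipid = 30, ash = 17, phosphorus = 1.5,
                                   energy = 23))
})

test_that("faecal_sample requires a positive marker", {
  expect_error(faecal_sample("T1", 14, 5, 2, 16, 0), "marker")
  expect_error(faecal_sample("T1", -1, 5, 2, 16, 0.1), ">= 0")
})

test_that("qpcr_dataset validates genes, samples and the Ct matrix", {
  genes <- data.frame(gene = c("tgt", "ref"), efficiency = c(100, 95),
                      role = c("target", "reference"))
  samples <- data.frame(sample = c("s1", "s2"), tank_id = "T1",
                        diet = "D", period = "growth")
  ct <- matrix(c(25, 20, 24, 20), 2, 2,
               dimnames = list(c("tgt", "ref"), c("s1", "s2")))
  q <- qpcr_dataset(genes, samples, ct)
  expect_s3_class(q, "qpcr_dataset")

  # rows/columns are reordered to match the tables
  ct_perm <- ct[c("ref", "tgt"), c("s2", "s1")]
  q2 <- qpcr_dataset(genes, samples, ct_perm)
  expect_identical(q2$ct, q$ct)

  expect_error(qpcr_dataset(genes[1, ], samples, ct[1, , drop = FALSE]),
               "reference")
  bad <- genes; bad$efficiency[1] <- 160
  expect_error(qpcr_dataset(bad, samples, ct), "\\(50, 150\\)")
  warn <- genes; warn$efficiency[1] <- 135
  expect_no_warning(qpcr_dataset(warn, samples, ct))
  warn$efficiency[1] <- 58
  expect_warning(qpcr_dataset(warn, samples, ct), "flagged")
  ct_bad <- ct; ct_bad[1, 1] <- 46
  expect_error(qpcr_dataset(genes, samples, ct_bad), "\\(0, 45\\)")
})

test_that("trial_dataset rejects tanks referencing unknown diets", {
  d <- demo_diet()
  t <- demo_tank()
  expect_s3_class(trial_dataset(list(d), list(t)), "trial_dataset")
  orphan <- demo_tank(diet = "NOPE")
  expect_error(trial_dataset(list(d), list(orphan)), "unknown diet")
})

test_that("tanks_table flattens and filters by period", {
  d <- demo_diet()
  tr <- trial_dataset(list(d), list(demo_tank("T1"),
                                    demo_tank("T2", period = "challenge")))
  tb <- tanks_table(tr)
  expect_equal(nrow(tb), 2)
  expect_equal(nrow(tanks_table(tr, period = "growth")), 1)
  expect_equal(tb$mean_temp, c(23.5, 23.5))
})
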