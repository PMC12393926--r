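test_that("reference_biomass supports all conventions", {
  expect_equal(reference_biomass(14100, 42600), 28.35)
  expect_equal(reference_biomass(14100, 42600, "initial"), 14.1)
  expect_equal(reference_biomass(14100, 42600, "final"), 42.6)
  expect_equal(reference_biomass(14100, 42600, "geometric"),
               sqrt(14.1 * 42.6))
  expect_error(reference_biomass(14100, 42600, "harmonic"))
})

test_that("phosphorus flux formulas match hand arithmetic", {
  d <- demo_diet()  # total_p = 1.1% as fed
  cpi <- crude_p_intake(36.3, d, reference_biomass(14.1, 47.8), 65)
  expect_equal(cpi, 1000 * (36.3 * 1.1 / 100) / (30.95 / 1000) / 65)
  expect_equal(faecal_p_loss(100, 60), 40)
  expect_equal(faecal_p_loss(100, 100), 0)
  pg <- p_gain(14.1, 47.8, 0.4, 0.45, 30.95 / 1000, 65)
  expect_equal(pg, 1000 * (47.8 * 0.0045 - 14.1 * 0.004) / (30.95 / 1000) / 65)
  expect_equal(metabolic_p_loss(100, 30, 40), 30)
  expect_warning(metabolic_p_loss(100, 70, 40), "negative metabolic")
})

test_that("FPL/CPI + ADC/100 = 1 by construction", {
  adc <- runif(30, 1, 99)
  cpi <- runif(30, 10, 200)
  expect_equal(faecal_p_loss(cpi, adc) / cpi + adc / 100, rep(1, 30))
})

test_that("retention flags >100% and rejects bad ADCs", {
  expect_equal(retention(10, 40, 50), 50)
  expect_warning(retention(30, 40, 50), "above 100")
  expect_error(retention(10, 40, 0), "ADC in \\(0, 100\\]")
})

test_that("phosphorus_balance closes the mass balance exactly per tank", {
  d <- demo_diet()
  bc0 <- body_composition("wet", dm = 27, protein = 15.5, lipid = 7.5,
                          ash = 3.9, phosphorus = 0.4, energy = 6.5)
  bc1 <- body_composition("wet", dm = 31, protein = 17, lipid = 10,
                          ash = 3.5, phosphorus = 0.42, energy = 7.6)
  tr <- trial_dataset(
    list(d), list(demo_tank("T1")),
    faeces = list(T1 = demo_faeces("T1")),
    body_composition = list(initial = bc0, final = list(T1 = bc1)))
  adc <- trial_adc(tr)
  bal <- phosphorus_balance(tr, adc)
  expect_equal(bal$cpi, bal$pg + bal$fpl + bal$mpl)
  # hand recomputation of every term
  rb <- reference_biomass(90 * 14.1, 87 * 47.8)
  expect_equal(bal$ref_biomass_kg, rb)
  expect_equal(bal$cpi, crude_p_intake(87 * 36.3, d, rb, 65))
  expect_equal(bal$fpl, faecal_p_loss(bal$cpi, adc$adc_phosphorus))
  expect_error(phosphorus_balance(tr, adc[0, ]), "no phosphorus ADC")
})

test_that("retention_set computes mass- and energy-based retentions", {
  d <- demo_diet()
  bc0 <- body_composition("wet", dm = 27, protein = 15.5, lipid = 7.5,
                          ash = 3.9, phosphorus = 0.4, energy = 6.5)
  bc1 <- body_composition("wet", dm = 31, protein = 17, lipid = 10,
                          ash = 3.5, phosphorus = 0.42, energy = 7.6)
  tr <- trial_dataset(
    list(d), list(demo_tank("T1")),
    faeces = list(T1 = demo_faeces("T1")),
    body_composition = list(initial = bc0, final = list(T1 = bc1)))
  adc <- trial_adc(tr)
  rs <- retention_set(tr, adc)
  expect_setequal(rs$constituent,
                  c("protein", "lipid", "phosphorus", "energy"))
  gain_p <- 87 * 47.8 * 17 / 100 - 90 * 14.1 * 15.5 / 100
  intake_p <- 87 * 36.3 * d$crude_protein / 100
  expect_equal(rs$retention_pct_digestible[rs$constituent == "protein"],
               100 * gain_p / (intake_p * adc$adc_protein / 100))
  # energy uses kJ/g directly (no /100)
  gain_e <- 87 * 47.8 * 7.6 - 90 * 14.1 * 6.5
  intake_e <- 87 * 36.3 * d$gross_energy
  expect_equal(rs$retention_pct_digestible[rs$constituent == "energy"],
               100 * gain_e / (intake_e * adc$adc_energy / 100))
})
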