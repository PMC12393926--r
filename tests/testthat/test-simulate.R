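test_that("substream seeds are deterministic and order-free", {
  expect_identical(aquatrial:::substream_seed(1, "a"),
                   aquatrial:::substream_seed(1, "a"))
  expect_false(aquatrial:::substream_seed(1, "a") ==
                 aquatrial:::substream_seed(1, "b"))
  expect_false(aquatrial:::substream_seed(1, "a") ==
                 aquatrial:::substream_seed(2, "a"))
})

test_that("lognorm_factor has mean one and collapses at cv = 0", {
  expect_equal(aquatrial:::lognorm_factor(5, 0), rep(1, 5))
  set.seed(1)
  f <- aquatrial:::lognorm_factor(2e5, 0.2)
  expect_true(all(f > 0))
  expect_equal(mean(f), 1, tolerance = 0.005)
  expect_equal(sd(f) / mean(f), 0.2, tolerance = 0.01)
})

test_that("truth_config defaults encode the emulated study conditions", {
  cfg <- truth_config(seed = 1)
  expect_named(cfg$diets, c("CTRL", "ORG", "ECO"))
  expect_equal(cfg$n_replicates, 3)
  expect_equal(cfg$n_fish, 90)
  expect_equal(cfg$days, 65)
  expect_equal(cfg$ibw, 14.1)
  expect_equal(unique(cfg$temperature), 23.5)
  expect_equal(unname(cfg$true_fbw), c(47.8, 42.6, 48.8))
  expect_equal(cfg$true_adc$ORG[["protein"]], 96.6)
  # TGC consistency: projecting the fitted TGC lands on the true FBW
  for (d in names(cfg$diets)) {
    expect_equal(project_weight(cfg$ibw, cfg$temperature,
                                cfg$true_tgc[[d]])[cfg$days],
                 cfg$true_fbw[[d]])
  }
  expect_error(truth_config(true_adc = list(
    CTRL = c(dm = 101, protein = 90, lipid = 90, phosphorus = 60,
             energy = 90))),
    "inside \\(0, 100\\)")
})

test_that("simulation is reproducible for a fixed seed", {
  cfg <- truth_config(seed = 99)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_equal(tanks_table(t1), tanks_table(t2))
  expect_equal(t1$qpcr$ct, t2$qpcr$ct)
  t3 <- simulate_trial(truth_config(seed = 100))
  expect_false(isTRUE(all.equal(tanks_table(t1)$biomass_final,
                                tanks_table(t3)$biomass_final)))
})

test_that("noiseless faeces invert the ADC formulas exactly", {
  d <- demo_diet()
  truth <- c(dm = 72.5, protein = 94.7, lipid = 98.1, phosphorus = 60.4,
             energy = 89.9)
  f <- simulate_faeces(d, truth, noise_cv = 0, tank_ids = "T1")[[1]]
  adc <- compute_adc_set(d, f)
  expect_equal(adc$adc_dm, truth[["dm"]])
  expect_equal(adc$adc_protein, truth[["protein"]])
  expect_equal(adc$adc_lipid, truth[["lipid"]])
  expect_equal(adc$adc_phosphorus, truth[["phosphorus"]])
  expect_equal(adc$adc_energy, truth[["energy"]])
  expect_error(simulate_faeces(d, replace(truth, 1, 100)), "below 100")
})

test_that("noiseless qPCR reproduces designed folds exactly", {
  genes <- data.frame(gene = c("tgt", "ref1", "ref2"),
                      efficiency = c(128.6, 95, 105),
                      role = c("target", "reference", "reference"))
  design <- data.frame(gene = "tgt", diet = c("CTRL", "ORG"),
                       fold_growth = c(1, 13.8), fold_post = c(1, 0.5))
  q <- simulate_qpcr(design, genes, ct_noise_sd = 0)
  expr <- relative_expression(q, "CTRL")
  expect_equal(expr$expression[expr$diet == "ORG"], rep(13.8, 9))
  pp <- pre_post_expression(q)
  expect_equal(pp$expression[pp$diet == "ORG"], rep(0.5, 9))
  expect_equal(pp$expression[pp$diet == "CTRL"], rep(1, 9))
})

test_that("a noiseless trial round-trips the full growth truth", {
  cfg <- noiseless(truth_config(seed = 5))
  tr <- simulate_trial(cfg)
  expect_s3_class(tr, "trial_dataset")
  expect_equal(length(tr$tanks), 9)
  kpi <- trial_kpi(tr)
  for (d in names(cfg$diets)) {
    rows <- kpi[kpi$diet == d, ]
    expect_equal(rows$fbw, rep(cfg$true_fbw[[d]], 3))
    expect_equal(rows$fcr, rep(cfg$true_fcr[[d]], 3))
    expect_equal(rows$vsi, rep(cfg$true_vsi[[d]], 3))
    expect_equal(rows$hsi, rep(cfg$true_hsi[[d]], 3))
    expect_equal(rows$k, rep(cfg$true_k[[d]], 3))
    expect_equal(rows$survival, rep(100, 3))
  }
  adc <- trial_adc(tr)
  for (d in names(cfg$diets)) {
    expect_equal(adc$adc_protein[adc$diet == d],
                 rep(cfg$true_adc[[d]][["protein"]], 3))
  }
  # recovered TGC equals the configured truth
  t1 <- tr$tanks[["CTRL-1"]]
  expect_equal(fit_tgc(t1$biomass_initial / t1$n_initial,
                       t1$biomass_final / t1$n_final, t1$temperatures),
               cfg$true_tgc[["CTRL"]])
})

test_that("mortality respects the survival range", {
  cfg <- truth_config(seed = 17)
  tr <- simulate_trial(cfg)
  tb <- tanks_table(tr)
  expect_true(all(tb$n_final <= tb$n_initial))
  expect_true(all(tb$n_final >= 0.8 * tb$n_initial))  # loose sanity bound
})
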