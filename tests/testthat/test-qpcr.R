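test_that("efficiency_to_factor converts and flags extremes", {
  expect_equal(efficiency_to_factor(100), 2)
  expect_equal(efficiency_to_factor(128.6), 2.286)
  expect_warning(efficiency_to_factor(150), "flagged")
  expect_error(efficiency_to_factor(-10))
})

test_that("pfaffl_ratio matches its closed form", {
  expect_equal(pfaffl_ratio(2, 3, data.frame(e = c(2, 2), dct = c(1, 3))),
               2^3 / sqrt(2^1 * 2^3))
  # single reference gene
  expect_equal(pfaffl_ratio(2.1, 2, data.frame(e = 1.9, dct = 1.5)),
               2.1^2 / 1.9^1.5)
  expect_error(pfaffl_ratio(2, 1, data.frame(e = numeric(), dct = numeric())),
               "at least one reference")
  expect_error(pfaffl_ratio(0.9, 1, data.frame(e = 2, dct = 1)))
})

make_qpcr <- function(ct_fun, periods = "growth",
                      eff = c(tgt = 100, ref1 = 95, ref2 = 105)) {
  genes <- data.frame(gene = names(eff), efficiency = unname(eff),
                      role = c("target", "reference", "reference"))
  samples <- expand.grid(diet = c("CTRL", "ORG"), rep = 1:2,
                         period = periods, stringsAsFactors = FALSE)
  samples$tank_id <- paste0(samples$diet, "-", samples$rep)
  samples$sample <- paste0(samples$tank_id, ".", samples$period)
  ct <- ct_fun(genes, samples)
  qpcr_dataset(genes, samples[, c("sample", "tank_id", "diet", "period")],
               ct)
}

test_that("relative_expression reproduces a designed fold change", {
  # ORG target gene is 1 cycle earlier (2-fold up at E = 2), refs constant
  q <- make_qpcr(function(genes, samples) {
    ct <- matrix(20, nrow(genes), nrow(samples),
                 dimnames = list(genes$gene, samples$sample))
    ct["tgt", samples$diet == "ORG"] <- 19
    ct
  })
  expr <- relative_expression(q, "CTRL")
  expect_equal(expr$expression[expr$diet == "CTRL"], c(1, 1))
  expect_equal(expr$expression[expr$diet == "ORG"], c(2, 2))
  expect_error(relative_expression(q, "NOPE"), "no samples in reference")
})

test_that("reference-gene shifts cancel through the geometric mean", {
  # every gene of one sample shifted by the same amount: ratio unchanged
  # only when target and reference factors agree; use E = 2 throughout
  q <- make_qpcr(function(genes, samples) {
    ct <- matrix(20, nrow(genes), nrow(samples),
                 dimnames = list(genes$gene, samples$sample))
    ct[, samples$sample == "ORG-1.growth"] <-
      ct[, samples$sample == "ORG-1.growth"] - 1.5
    ct
  }, eff = c(tgt = 100, ref1 = 100, ref2 = 100))
  expr <- relative_expression(q, "CTRL")
  expect_equal(expr$expression, rep(1, 4))
})

test_that("Pfaffl reduces to 2^-ddCt when all factors are 2", {
  set.seed(11)
  for (i in 1:25) {
    dct_t <- runif(1, -3, 3)
    dct_r <- runif(1, -3, 3)
    r <- pfaffl_ratio(2, dct_t, data.frame(e = 2, dct = dct_r))
    ddct <- -dct_t - (-dct_r)  # dCt as sample - calibrator
    expect_equal(r, 2^-ddct)
  }
})

test_that("pre_post_expression calibrates within each diet", {
  # challenge Ct 1 cycle later for the target in every diet -> ratio 0.5
  q <- make_qpcr(function(genes, samples) {
    ct <- matrix(20, nrow(genes), nrow(samples),
                 dimnames = list(genes$gene, samples$sample))
    ct["tgt", samples$period == "challenge"] <- 21
    # diets differ wildly at growth; must not leak across diets
    ct["tgt", samples$diet == "ORG"] <- ct["tgt", samples$diet == "ORG"] - 3
    ct
  }, periods = c("growth", "challenge"),
  eff = c(tgt = 100, ref1 = 100, ref2 = 100))
  expr <- pre_post_expression(q)
  expect_true(all(expr$period == "challenge"))
  expect_equal(expr$expression, rep(0.5, 4))
})

test_that("summarize_expression averages tanks before diets", {
  q <- make_qpcr(function(genes, samples) {
    ct <- matrix(20, nrow(genes), nrow(samples),
                 dimnames = list(genes$gene, samples$sample))
    ct["tgt", samples$sample == "ORG-1.growth"] <- 19
    ct
  }, eff = c(tgt = 100, ref1 = 100, ref2 = 100))
  s <- summarize_expression(relative_expression(q, "CTRL"))
  org <- s[s$diet == "ORG" & s$gene == "tgt", ]
  expect_equal(org$mean, mean(c(2, 1)))
  expect_equal(org$n_tanks, 2)
})
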