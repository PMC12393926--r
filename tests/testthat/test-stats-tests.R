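test_that("dunn_test agrees with hand-computed rank z-statistics", {
  values <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  group <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_test(values, group)
  # no ties: SE = sqrt(n(n+1)/12 * (1/3 + 1/3)), mean ranks 2, 5, 8
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], (2 - 5) / se)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], (2 - 8) / se)
  expect_equal(d$p_adjusted, pmin(1, d$p * 3))
})

test_that("dunn_test applies the tie correction", {
  values <- c(1, 1, 2, 2, 3, 3)
  group <- rep(c("a", "b"), 3)
  d <- dunn_test(values, group)
  n <- 6
  tie_corr <- 3 * (2^3 - 2) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - tie_corr) * (2 / 3))
  expect_equal(abs(d$z), abs(mean(rank(values)[c(1, 3, 5)]) -
                               mean(rank(values)[c(2, 4, 6)])) / se)
})

test_that("gate_and_test takes the parametric path for clean normal data", {
  set.seed(10)
  values <- c(rnorm(6, 10), rnorm(6, 10.5), rnorm(6, 18))
  group <- rep(c("a", "b", "c"), each = 6)
  res <- gate_and_test(values, group)
  expect_identical(res$test, "anova_tukey")
  expect_identical(res$transform, "none")
  fit <- aov(values ~ factor(group))
  expect_equal(res$omnibus_p, summary(fit)[[1]][["Pr(>F)"]][1])
  # c clearly separated from a and b, which share a letter
  expect_false(grepl(res$letters[["c"]], res$letters[["a"]], fixed = TRUE))
  expect_true(any(strsplit(res$letters[["a"]], "")[[1]] %in%
                    strsplit(res$letters[["b"]], "")[[1]]))
})

test_that("gate violations switch to Kruskal-Wallis + Dunn", {
  set.seed(12)
  # heavy-tailed, strongly heteroscedastic
  values <- c(rcauchy(8, 0, 0.1), rcauchy(8, 0, 10), rcauchy(8, 5, 10))
  group <- rep(c("a", "b", "c"), each = 8)
  res <- gate_and_test(values, group)
  expect_identical(res$test, "kruskal_dunn")
  kw <- kruskal.test(values, factor(group))
  expect_equal(res$omnibus_p, kw$p.value)
})

test_that("percentage responses are arcsine transformed before gating", {
  set.seed(13)
  values <- pmin(99, pmax(1, c(rnorm(5, 90, 2), rnorm(5, 80, 2))))
  res <- gate_and_test(values, rep(c("a", "b"), each = 5),
                       is_percentage = TRUE)
  expect_identical(res$transform, "arcsine_sqrt")
  # group_means stay on the original percentage scale
  expect_equal(unname(res$group_means),
               unname(tapply(values, rep(c("a", "b"), each = 5), mean)))
})

test_that("singleton groups force the non-parametric path with a warning", {
  values <- c(1, 2, 3, 10)
  group <- c("a", "a", "a", "b")
  expect_warning(res <- gate_and_test(values, group), "single observation")
  expect_identical(res$test, "kruskal_dunn")
})

test_that("identical observations yield one shared letter", {
  res <- gate_and_test(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(res$letters), rep("a", 3))
  expect_equal(res$omnibus_p, 1)
})

test_that("letters are invariant to observation order", {
  set.seed(14)
  values <- c(rnorm(3, 94.7, 1.1), rnorm(3, 96.6, 0.5), rnorm(3, 89.6, 2.9))
  group <- rep(c("CTRL", "ORG", "ECO"), each = 3)
  res1 <- gate_and_test(values, group, is_percentage = TRUE)
  perm <- sample(length(values))
  res2 <- gate_and_test(values[perm], group[perm], is_percentage = TRUE)
  expect_identical(res1$letters, res2$letters)
  expect_equal(res1$omnibus_p, res2$omnibus_p)
})

test_that("gate_and_test needs at least two groups", {
  expect_error(gate_and_test(1:5, rep("a", 5)), "two groups")
})
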