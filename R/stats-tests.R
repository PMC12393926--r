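# Assumption-gated group testing: Shapiro-Wilk + Levene gates deciding
# between one-way ANOVA + Tukey and Kruskal-Wallis + Dunn.

#' Dunn's rank-based post-hoc pairwise test
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis analysis, with
#' the standard tie correction, adjusted for multiplicity (Bonferroni by
#' default).
#'
#' @param values Numeric response.
#' @param group Grouping factor.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Tibble with `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "bonferroni") {
  group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, group, mean)
  ni <- tapply(r, group, length)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p2) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ni[[p2[1]]] + 1 / ni[[p2[2]]]))
    (rbar[[p2[1]]] - rbar[[p2[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
                 p_adjusted = stats::p.adjust(p, method = p_adjust))
}

# Piepho-style insert-and-absorb compact letter display from a pairwise
# significance table. Groups sharing a letter are not significantly
# different.
assign_letters <- function(groups, pair_table, alpha = 0.05) {
  groups <- as.character(groups)
  sets <- list(groups)  # letter -> member set
  sig <- pair_table[pair_table$p_adjusted < alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      a <- sig$group1[i]; b <- sig$group2[i]
      new_sets <- list()
      for (s in sets) {
        if (all(c(a, b) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (j in seq_along(new_sets)) {
        for (k in seq_along(new_sets)) {
          if (j != k && keep[k] &&
              all(new_sets[[j]] %in% new_sets[[k]]) &&
              (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
            keep[j] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' Assumption-gated one-way group comparison
#'
#' Percentage responses are arcsine-square-root transformed first. The
#' transformed data are gated on normality (Shapiro-Wilk on model
#' residuals) and homoscedasticity (Levene's test, mean-centred): when both
#' hold at `alpha` the comparison runs as one-way ANOVA with Tukey HSD,
#' otherwise as Kruskal-Wallis with Dunn's Bonferroni-adjusted post hoc.
#' Any group with fewer than two observations forces the non-parametric
#' path with a warning. Compact significance letters are assigned so that
#' groups sharing a letter are not significantly different.
#'
#' @param values Numeric response (tank-level values).
#' @param group Grouping factor (diet).
#' @param is_percentage Apply the arcsine square-root transform first?
#' @param alpha Significance level for gates and comparisons.
#' @return A list of class `test_result`: `transform`, `normality_p`,
#'   `homoscedasticity_p`, `test` (`"anova_tukey"` or
#'   `"kruskal_dunn"`), `omnibus_p`, `pairwise` (tibble), `letters`
#'   (named by group, ordered by decreasing group mean), `group_means`.
#' @export
gate_and_test <- function(values, group, is_percentage = FALSE,
                          alpha = 0.05) {
  group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  y <- if (is_percentage) arcsine_sqrt(values) else values
  ni <- table(group)
  singleton <- any(ni < 2)
  if (singleton) {
    warning("group(s) with a single observation: using the ",
            "non-parametric path", call. = FALSE)
  }
  resid <- y - stats::ave(y, group)
  normality_p <- if (stats::sd(resid) == 0) 1 else
    tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) 0)
  homo_p <- if (singleton || stats::sd(y) == 0) 1 else
    car::leveneTest(y ~ group, center = mean)[1, "Pr(>F)"]
  parametric <- !singleton && normality_p > alpha && homo_p > alpha
  if (stats::sd(y) == 0) {
    # all observations identical: nothing to separate
    lev <- levels(group)
    return(structure(list(
      transform = if (is_percentage) "arcsine_sqrt" else "none",
      normality_p = 1, homoscedasticity_p = 1, test = "anova_tukey",
      omnibus_p = 1,
      pairwise = tibble::tibble(group1 = character(), group2 = character(),
                                p_adjusted = numeric()),
      letters = stats::setNames(rep("a", length(lev)), lev),
      group_means = tapply(values, group, mean)), class = "test_result"))
  }
  if (parametric) {
    fit <- stats::aov(y ~ group)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(group1 = vapply(nm, `[`, "", 1),
                               group2 = vapply(nm, `[`, "", 2),
                               estimate = tk[, "diff"],
                               p_adjusted = tk[, "p adj"])
    test <- "anova_tukey"
  } else {
    kw <- stats::kruskal.test(y, group)
    omnibus_p <- kw$p.value
    pairwise <- dunn_test(y, group)
    test <- "kruskal_dunn"
  }
  means <- tapply(values, group, mean)
  ord <- names(sort(means, decreasing = TRUE))
  letters_out <- assign_letters(ord, pairwise, alpha = alpha)
  structure(list(
    transform = if (is_percentage) "arcsine_sqrt" else "none",
    normality_p = normality_p, homoscedasticity_p = homo_p, test = test,
    omnibus_p = omnibus_p, pairwise = pairwise,
    letters = letters_out, group_means = means), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$test, " (transform: ", x$transform, ")\n",
      sep = "")
  cat(sprintf("  gates: normality p = %.3f, homoscedasticity p = %.3f\n",
              x$normality_p, x$homoscedasticity_p))
  cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  cat("  letters:", paste(names(x$letters), x$letters, sep = ":",
                          collapse = "  "), "\n")
  invisible(x)
}
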