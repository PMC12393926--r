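# Auto-scaled PCA of biomarker panels, with cos2, group ellipses and
# per-component two-group score tests.

#' Auto-scaled principal component analysis of a biomarker matrix
#'
#' Columns (variables, e.g. relative gene expressions) are auto-scaled to
#' mean 0 / SD 1 and decomposed by singular values ([stats::prcomp()]).
#' Zero-variance columns are dropped with a warning. A deterministic sign
#' convention is applied: within each component the loading of largest
#' magnitude is made positive.
#'
#' @param x Numeric matrix or data frame, samples in rows, variables in
#'   columns (no missing cells).
#' @param groups Optional factor of length `nrow(x)`; enables 95%
#'   confidence ellipses per group on PC1-PC2.
#' @return An object of class `pca_result`: `scores` (sample x component),
#'   `loadings` (variable x component), `variance_explained` (%, sums to
#'   100 over all components), `cos2` (variable x component
#'   quality-of-representation; each variable's row sums to 1),
#'   `ellipses` (per-group bivariate-normal 95% parameters on PC1-PC2, or
#'   NULL), `groups`.
#' @export
pca_integrate <- function(x, groups = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least two samples and two variables", call. = FALSE)
  }
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  var_expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  # cos2: squared correlation-like quality; rows (variables) sum to 1
  load_sd <- sweep(pc$rotation, 2, pc$sdev, `*`)
  cos2 <- load_sd^2 / rowSums(load_sd^2)
  ellipses <- NULL
  if (!is.null(groups)) {
    groups <- factor(groups)
    stopifnot(length(groups) == nrow(x))
    ellipses <- lapply(split(seq_len(nrow(x)), groups), function(idx) {
      s <- pc$x[idx, 1:2, drop = FALSE]
      list(centroid = colMeans(s),
           cov = if (length(idx) > 2) stats::cov(s) else NULL,
           radius = sqrt(stats::qchisq(0.95, df = 2)),
           n = length(idx))
    })
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = var_expl, cos2 = cos2,
                 ellipses = ellipses, groups = groups),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples x ", nrow(x$loadings),
      " variables\n", sep = "")
  ve <- x$variance_explained
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%%)\n",
              ve[1], ve[2], ve[1] + ve[2]))
  invisible(x)
}

#' Two-group score test on a principal component
#'
#' The scores of one component are treated as a new variable, Box-Cox
#' transformed (after a location shift when scores are non-positive, the
#' transform being defined on positive values only) and compared between
#' two groups with a Student's t-test.
#'
#' @param pca A [pca_integrate()] result.
#' @param grouping Factor with exactly two levels, length = number of
#'   samples.
#' @param component Component index (default 1).
#' @return A list: `component`, `p`, `t`, `lambda`, `shift`.
#' @export
pca_score_test <- function(pca, grouping, component = 1) {
  stopifnot(inherits(pca, "pca_result"))
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2) {
    stop("score test compares exactly two groups", call. = FALSE)
  }
  s <- pca$scores[, component]
  shift <- if (min(s) <= 0) 1 - min(s) else 0
  bc <- boxcox_transform(s + shift)
  tt <- stats::t.test(bc$y ~ grouping, var.equal = TRUE)
  list(component = component, p = tt$p.value,
       t = unname(tt$statistic), lambda = bc$lambda, shift = shift)
}

#' Score biplot of a PCA result
#'
#' Scatter of the samples on two components, coloured by group with 95%
#' normal ellipses where group sizes allow. Requires ggplot2.
#'
#' @param x A [pca_integrate()] result.
#' @param components Two component indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.pca_result <- function(x, components = c(1, 2), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  sx <- x$scores[, components[1]]
  sy <- x$scores[, components[2]]
  grp <- if (is.null(x$groups)) factor("all") else x$groups
  df <- tibble::tibble(x = sx, y = sy, group = grp)
  ve <- x$variance_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], ve[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2], ve[components[2]]))
  if (!is.null(x$groups) && all(table(x$groups) > 2)) {
    p <- p + ggplot2::stat_ellipse(level = 0.95, type = "norm")
  }
  p
}
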