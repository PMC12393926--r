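# Planned contrasts over the diet x period cell-means model.

#' Build the standard pre/post contrast set
#'
#' For diets d1..dk over periods growth/challenge, returns the pooled
#' growth-vs-challenge contrast plus one growth-vs-challenge contrast per
#' diet, on cells named `diet.period`.
#'
#' @param diets Character vector of diet labels.
#' @return Named list of contrast vectors (each summing to zero) over the
#'   2 x length(diets) cells.
#' @export
pre_post_contrasts <- function(diets) {
  cells <- c(paste0(diets, ".growth"), paste0(diets, ".challenge"))
  k <- length(diets)
  pooled <- stats::setNames(c(rep(1 / k, k), rep(-1 / k, k)), cells)
  out <- list(pooled = pooled)
  for (d in diets) {
    v <- stats::setNames(rep(0, 2 * k), cells)
    v[paste0(d, ".growth")] <- 1
    v[paste0(d, ".challenge")] <- -1
    out[[d]] <- v
  }
  out
}

#' Planned contrasts on a one-way cell-means model
#'
#' Tests pre-specified linear combinations of diet x period cell means
#' against the pooled within-cell error of a one-way cell-means model, the
#' standard planned-contrast construction. Responses are Box-Cox
#' transformed (lambda by maximum likelihood per response) before fitting
#' unless `boxcox = FALSE`. When a `gene` column is present the analysis
#' runs per gene.
#'
#' @param df Long tibble with columns `diet`, `period`, `value` and
#'   optionally `gene` (tank-level observations).
#' @param contrasts Named list of contrast vectors over cells named
#'   `diet.period`; each must sum to zero. Default: [pre_post_contrasts()]
#'   on the diets present (requires both periods).
#' @param boxcox Apply the Box-Cox transform per response first?
#' @return Tibble with one row per (gene x) contrast: `contrast`,
#'   `estimate` (on the transformed scale), `t`, `df`, `p`, `lambda`.
#' @export
planned_contrasts <- function(df, contrasts = NULL, boxcox = TRUE) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("diet", "period", "value") %in% names(df)))
  if (is.null(contrasts)) {
    contrasts <- pre_post_contrasts(sort(unique(df$diet)))
  }
  bad <- names(contrasts)[vapply(contrasts,
                                 function(v) abs(sum(v)) > 1e-8,
                                 logical(1))]
  if (length(bad)) {
    stop("contrast(s) not summing to zero: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  run_one <- function(d) {
    y <- d$value
    lambda <- NA_real_
    if (boxcox) {
      bc <- boxcox_transform(y)
      y <- bc$y
      lambda <- bc$lambda
    }
    cell <- factor(paste0(d$diet, ".", d$period))
    mu <- tapply(y, cell, mean)
    ni <- tapply(y, cell, length)
    n <- length(y)
    k <- nlevels(cell)
    dfe <- n - k
    mse <- sum((y - stats::ave(y, cell))^2) / dfe
    purrr::map_dfr(names(contrasts), function(cn) {
      v <- contrasts[[cn]]
      miss <- setdiff(names(v)[v != 0], names(mu))
      if (length(miss)) {
        stop("contrast '", cn, "' references absent cell(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      v <- v[names(mu)]
      v[is.na(v)] <- 0
      est <- sum(v * mu)
      se <- sqrt(mse * sum(v^2 / ni))
      tval <- est / se
      tibble::tibble(contrast = cn, estimate = est, t = tval, df = dfe,
                     p = 2 * stats::pt(-abs(tval), dfe), lambda = lambda)
    })
  }
  if ("gene" %in% names(df)) {
    df |>
      dplyr::group_by(.data$gene) |>
      dplyr::group_modify(~ run_one(.x)) |>
      dplyr::ungroup()
  } else {
    run_one(df)
  }
}
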