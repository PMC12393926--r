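#' Convert a slope-derived qPCR efficiency to an amplification factor
#'
#' Standard-curve efficiencies are reported as percentages (100% = perfect
#' doubling); the per-cycle amplification factor is `1 + efficiency/100`.
#' Efficiencies above 110% are used as given but flagged with a warning,
#' since factors above ~2.2 usually indicate assay problems (inhibition,
#' primer dimers).
#'
#' @param efficiency Efficiency in %, positive.
#' @return Amplification factor (e.g. 100 -> 2.0, 128.6 -> 2.286).
#' @export
efficiency_to_factor <- function(efficiency) {
  stopifnot(all(efficiency > 0))
  flagged <- efficiency < 60 | efficiency > 140
  if (any(flagged)) {
    warning("efficiency outside [60, 140]% flagged: ",
            paste(round(efficiency[flagged], 1), collapse = ", "),
            call. = FALSE)
  }
  1 + efficiency / 100
}

#' Pfaffl efficiency-corrected expression ratio
#'
#' \deqn{ratio = \frac{E_{target}^{\Delta Ct_{target}}}
#'   {\mathrm{geomean}_j\left(E_{ref,j}^{\Delta Ct_{ref,j}}\right)}}
#' with \eqn{\Delta Ct} = (reference-group mean Ct) - (sample Ct), per gene,
#' so up-regulation relative to the reference group yields a ratio above 1.
#' With a single reference gene and all factors equal to 2 this is the
#' classical \eqn{2^{-\Delta\Delta Ct}} value.
#'
#' @param e_target Amplification factor of the target gene (> 1).
#' @param dct_target \eqn{\Delta Ct} of the target gene, cycles.
#' @param refs Data frame (or list coercible to one) with columns `e`
#'   (amplification factors) and `dct` (reference-gene \eqn{\Delta Ct}s).
#' @return The dimensionless expression ratio.
#' @examples
#' pfaffl_ratio(2, 3, data.frame(e = c(2, 2), dct = c(1, 3))) # 2
#' @export
pfaffl_ratio <- function(e_target, dct_target, refs) {
  refs <- as.data.frame(refs)
  if (nrow(refs) == 0L) {
    stop("at least one reference gene is required", call. = FALSE)
  }
  stopifnot(all(refs$e > 1), e_target > 1)
  norm <- exp(mean(refs$dct * log(refs$e)))
  e_target^dct_target / norm
}

# Pfaffl ratios of a set of samples against a reference sample group.
# ref_ids/sample_ids index columns of the Ct matrix.
pfaffl_block <- function(data, ref_ids, sample_ids) {
  genes <- data$genes
  e <- suppressWarnings(efficiency_to_factor(genes$efficiency))
  names(e) <- genes$gene
  ct <- data$ct
  ref_mean <- rowMeans(ct[, ref_ids, drop = FALSE])
  dct <- ref_mean - ct[, sample_ids, drop = FALSE]  # gene x sample
  ref_genes <- genes$gene[genes$role == "reference"]
  tgt_genes <- genes$gene[genes$role == "target"]
  # per-sample normalisation factor: geomean over reference genes of E^dCt
  log_norm <- colMeans(log(e[ref_genes])
                       * dct[ref_genes, , drop = FALSE])
  purrr::map_dfr(tgt_genes, function(g) {
    tibble::tibble(sample = colnames(dct),
                   gene = g,
                   expression = unname(exp(dct[g, ] * log(e[[g]]) -
                                             log_norm)))
  })
}

#' Relative expression with a dietary reference group
#'
#' Computes per-sample Pfaffl ratios for every target gene, taking the
#' samples of `reference_group` (within `period`) as the calibrator: each
#' gene's \eqn{\Delta Ct} is that group's arithmetic mean Ct minus the
#' sample's Ct, and normalisation uses the geometric mean over the
#' reference (housekeeping) genes.
#'
#' @param data A [qpcr_dataset()].
#' @param reference_group Diet label of the calibrator group.
#' @param period Period(s) analysed; `NULL` for all samples (e.g. to put
#'   both periods on the common calibrator before a joint multivariate
#'   analysis). Default `"growth"`.
#' @param reference_period Period the calibrator samples are taken from
#'   (default `"growth"`).
#' @return An object of class `expression_table`: tibble with `sample`,
#'   `tank_id`, `diet`, `period`, `gene`, `expression`, plus attributes
#'   `reference_group` and `period`.
#' @export
relative_expression <- function(data, reference_group, period = "growth",
                                reference_period = "growth") {
  stopifnot(inherits(data, "qpcr_dataset"))
  smp <- data$samples
  in_period <- if (is.null(period)) smp$sample else
    smp$sample[smp$period %in% period]
  ref_ids <- smp$sample[smp$diet == reference_group &
                          smp$period == reference_period]
  if (length(ref_ids) == 0L) {
    stop("no samples in reference group '", reference_group,
         "' for period '", reference_period, "'", call. = FALSE)
  }
  out <- pfaffl_block(data, ref_ids, in_period)
  out <- dplyr::left_join(out, smp, by = "sample")
  out <- out[, c("sample", "tank_id", "diet", "period", "gene",
                 "expression")]
  structure(out, class = c("expression_table", class(out)),
            reference_group = reference_group, period = period)
}

#' Pre/post-stress relative expression within each diet
#'
#' For each diet independently, challenge-period samples are expressed
#' relative to that diet's growth-period group (the growth period acts as
#' the calibrator), so a designed post-stress halving yields a ratio of
#' 0.5 in that diet regardless of the others.
#'
#' @param data A [qpcr_dataset()] holding both periods.
#' @return An `expression_table` tibble of challenge-period samples with a
#'   `reference_period` attribute of `"growth"`.
#' @export
pre_post_expression <- function(data) {
  stopifnot(inherits(data, "qpcr_dataset"))
  smp <- data$samples
  diets <- unique(smp$diet)
  out <- purrr::map_dfr(diets, function(d) {
    ref_ids <- smp$sample[smp$diet == d & smp$period == "growth"]
    post_ids <- smp$sample[smp$diet == d & smp$period == "challenge"]
    if (length(ref_ids) == 0L || length(post_ids) == 0L) {
      stop("diet ", d, " lacks samples in one of the periods", call. = FALSE)
    }
    pfaffl_block(data, ref_ids, post_ids)
  })
  out <- dplyr::left_join(out, smp, by = "sample")
  out <- out[, c("sample", "tank_id", "diet", "period", "gene",
                 "expression")]
  structure(out, class = c("expression_table", class(out)),
            reference_period = "growth")
}

#' Treatment summary of an expression table
#'
#' Samples are first averaged within tank, then mean and SD are taken over
#' tanks (the experimental unit).
#'
#' @param expr An `expression_table`.
#' @return Tibble with `diet`, `gene`, `mean`, `sd`, `n_tanks`.
#' @export
summarize_expression <- function(expr) {
  expr |>
    dplyr::group_by(.data$diet, .data$gene, .data$tank_id) |>
    dplyr::summarise(expression = mean(.data$expression),
                     .groups = "drop") |>
    dplyr::group_by(.data$diet, .data$gene) |>
    dplyr::summarise(mean = mean(.data$expression),
                     sd = stats::sd(.data$expression),
                     n_tanks = dplyr::n(), .groups = "drop")
}
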