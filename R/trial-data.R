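#' Construct a tank record
#'
#' One row of the trial-side bookkeeping: counts, bulk biomasses, feed
#' actually consumed (distributed net of recorded leftovers) and the daily
#' water-temperature series for one tank over one period.
#'
#' @param tank_id Tank label.
#' @param diet Diet label; must match a [diet_spec()] name in the bundle.
#' @param n_initial,n_final Fish counts at the start and end of the period.
#' @param biomass_initial,biomass_final Bulk tank biomass, g.
#' @param feed_distributed Feed consumed over the period, g as fed
#'   (distributed minus recorded leftovers).
#' @param days Number of feeding days.
#' @param temperatures Daily water temperature series, degrees C. A single
#'   value is recycled to `days` entries (constant-mean convention).
#' @param period `"growth"` or `"challenge"`.
#' @return An object of class `tank_record`.
#' @export
tank_record <- function(tank_id, diet, n_initial, n_final,
                        biomass_initial, biomass_final, feed_distributed,
                        days, temperatures, period = "growth") {
  period <- match.arg(period, c("growth", "challenge"))
  if (length(temperatures) == 1L) temperatures <- rep(temperatures, days)
  if (n_final > n_initial) {
    stop("tank ", tank_id, ": n_final exceeds n_initial", call. = FALSE)
  }
  if (biomass_initial <= 0 || biomass_final <= 0) {
    stop("tank ", tank_id, ": biomasses must be positive", call. = FALSE)
  }
  if (feed_distributed < 0) {
    stop("tank ", tank_id, ": feed_distributed must be >= 0", call. = FALSE)
  }
  if (length(temperatures) != days) {
    stop("tank ", tank_id, ": temperature series length (",
         length(temperatures), ") must equal days (", days, ")",
         call. = FALSE)
  }
  structure(
    list(tank_id = tank_id, diet = diet,
         n_initial = as.integer(n_initial), n_final = as.integer(n_final),
         biomass_initial = biomass_initial, biomass_final = biomass_final,
         feed_distributed = feed_distributed, days = as.integer(days),
         temperatures = as.numeric(temperatures), period = period),
    class = "tank_record")
}

#' @export
print.tank_record <- function(x, ...) {
  cat(sprintf("<tank_record> %s (%s, %s): %d -> %d fish, %.0f -> %.0f g, feed %.0f g over %d d\n",
              x$tank_id, x$diet, x$period, x$n_initial, x$n_final,
              x$biomass_initial, x$biomass_final, x$feed_distributed,
              x$days))
  invisible(x)
}

#' Validate a fish morphometry table
#'
#' @param df Data frame with columns `body_weight` (g), `total_length` (cm)
#'   and optionally `viscera_weight`, `liver_weight` (g).
#' @return The validated tibble (invisibly usable downstream).
#' @export
fish_morphometry <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("body_weight", "total_length") %in% names(df)))
  if (any(df$body_weight <= 0) || any(df$total_length <= 0)) {
    stop("body weights and lengths must be positive", call. = FALSE)
  }
  for (col in c("viscera_weight", "liver_weight")) {
    if (col %in% names(df)) {
      bad <- !is.na(df[[col]]) & df[[col]] >= df$body_weight
      if (any(bad)) {
        stop(col, " must be smaller than body_weight (rows ",
             paste(which(bad), collapse = ", "), ")", call. = FALSE)
      }
    }
  }
  df
}

#' Construct a whole-body composition record
#'
#' @param basis `"wet"` or `"dry"`.
#' @param dm,protein,lipid,ash,phosphorus Fractions, % of the stated basis.
#' @param energy kJ/g on the stated basis.
#' @param tol Tolerance (percentage points) for the wet-basis consistency
#'   check protein + lipid + ash <= dm.
#' @return An object of class `body_composition`.
#' @export
body_composition <- function(basis = c("wet", "dry"), dm, protein, lipid,
                             ash, phosphorus, energy, tol = 1) {
  basis <- match.arg(basis)
  fr <- c(dm = dm, protein = protein, lipid = lipid, ash = ash,
          phosphorus = phosphorus)
  if (any(fr < 0) || any(fr > 100)) {
    stop("composition fractions must lie in [0, 100]", call. = FALSE)
  }
  if (basis == "wet" && protein + lipid + ash > dm + tol) {
    stop("wet-basis protein + lipid + ash exceeds dry matter", call. = FALSE)
  }
  structure(list(basis = basis, dm = dm, protein = protein, lipid = lipid,
                 ash = ash, phosphorus = phosphorus, energy = energy),
            class = "body_composition")
}

#' Construct a faecal composition sample
#'
#' Concentrations are on the dry-matter basis of the freeze-dried, ground
#' faecal material.
#'
#' @param tank_id Tank label.
#' @param protein,lipid,phosphorus Faecal concentrations, % DM.
#' @param energy Faecal gross energy, kJ/g DM.
#' @param marker Faecal inert-marker concentration, % DM.
#' @return An object of class `faecal_sample`.
#' @export
faecal_sample <- function(tank_id, protein, lipid, phosphorus, energy,
                          marker) {
  vals <- c(protein = protein, lipid = lipid, phosphorus = phosphorus,
            energy = energy)
  if (any(vals < 0)) stop("faecal concentrations must be >= 0", call. = FALSE)
  if (marker <= 0) stop("faecal marker must be positive", call. = FALSE)
  structure(list(tank_id = tank_id, protein = protein, lipid = lipid,
                 phosphorus = phosphorus, energy = energy, marker = marker),
            class = "faecal_sample")
}

#' Construct a qPCR dataset
#'
#' @param genes Data frame with columns `gene`, `efficiency` (% — 100 means
#'   perfect doubling) and `role` (`"target"` or `"reference"`).
#' @param samples Data frame with columns `sample`, `tank_id`, `diet`,
#'   `period`.
#' @param ct Numeric matrix of quantification cycles, genes in rows
#'   (rownames = gene names), samples in columns (colnames = sample ids).
#'   Technical duplicates should be averaged on the Ct scale before entry;
#'   [read_trial_bundle()] does this for long-format input.
#' @return An object of class `qpcr_dataset`. Efficiencies outside
#'   (50, 150)% raise an error; outside \[60, 140\]% a warning flag.
#' @export
qpcr_dataset <- function(genes, samples, ct) {
  genes <- tibble::as_tibble(genes)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("gene", "efficiency", "role") %in% names(genes)),
            all(c("sample", "tank_id", "diet", "period") %in% names(samples)),
            is.matrix(ct))
  if (!any(genes$role == "reference")) {
    stop("at least one reference (housekeeping) gene is required",
         call. = FALSE)
  }
  if (any(genes$efficiency <= 50 | genes$efficiency >= 150)) {
    stop("amplification efficiencies must lie in (50, 150)%", call. = FALSE)
  }
  flagged <- genes$gene[genes$efficiency < 60 | genes$efficiency > 140]
  if (length(flagged)) {
    warning("efficiencies outside [60, 140]% flagged for: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  if (!setequal(rownames(ct), genes$gene)) {
    stop("ct matrix rownames must match the gene table", call. = FALSE)
  }
  if (!setequal(colnames(ct), samples$sample)) {
    stop("ct matrix colnames must match the sample table", call. = FALSE)
  }
  ct <- ct[genes$gene, samples$sample, drop = FALSE]
  if (any(ct <= 0 | ct >= 45, na.rm = TRUE)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  structure(list(genes = genes, samples = samples, ct = ct),
            class = "qpcr_dataset")
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("<qpcr_dataset> %d genes (%d reference) x %d samples\n",
              nrow(x$genes), sum(x$genes$role == "reference"),
              nrow(x$samples)))
  invisible(x)
}

#' Bundle every table of one trial
#'
#' @param diets Named list of [diet_spec()] objects.
#' @param tanks List of [tank_record()] objects.
#' @param faeces Optional list of [faecal_sample()] objects.
#' @param morphometry Optional named list (by tank) of morphometry tibbles.
#' @param body_composition Optional list with elements `initial` (one
#'   [body_composition()]) and `final` (named list by tank).
#' @param qpcr Optional [qpcr_dataset()].
#' @param truth Optional embedded generator ground truth (see
#'   [truth_config()]); present on simulated trials only.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(diets, tanks, faeces = NULL, morphometry = NULL,
                          body_composition = NULL, qpcr = NULL,
                          truth = NULL) {
  stopifnot(is.list(diets), is.list(tanks))
  diet_names <- vapply(diets, function(d) d$name, character(1))
  names(diets) <- diet_names
  tank_diets <- vapply(tanks, function(t) t$diet, character(1))
  orphan <- setdiff(tank_diets, diet_names)
  if (length(orphan)) {
    stop("tanks reference unknown diet(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  names(tanks) <- vapply(tanks, function(t) t$tank_id, character(1))
  structure(list(diets = diets, tanks = tanks, faeces = faeces,
                 morphometry = morphometry,
                 body_composition = body_composition,
                 qpcr = qpcr, truth = truth),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d diets, %d tanks%s\n",
              length(x$diets), length(x$tanks),
              if (!is.null(x$truth)) " (synthetic, truth embedded)" else ""))
  invisible(x)
}

#' Tank records as a tibble
#'
#' @param trial A [trial_dataset()].
#' @param period Optional period filter.
#' @return A tibble, one row per tank, with per-fish initial/final weights.
#' @export
tanks_table <- function(trial, period = NULL) {
  tb <- purrr::map_dfr(trial$tanks, function(t) {
    tibble::tibble(tank_id = t$tank_id, diet = t$diet, period = t$period,
                   n_initial = t$n_initial, n_final = t$n_final,
                   biomass_initial = t$biomass_initial,
                   biomass_final = t$biomass_final,
                   feed_distributed = t$feed_distributed, days = t$days,
                   mean_temp = mean(t$temperatures))
  })
  if (!is.null(period)) tb <- tb[tb$period == period, , drop = FALSE]
  tb
}
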