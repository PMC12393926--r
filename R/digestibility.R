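#' Apparent digestibility coefficient of dry matter
#'
#' Inert-marker ratio method: an indigestible tracer (here yttrium oxide at
#' 0.02% of feed) concentrates in faeces exactly in proportion to dry-matter
#' disappearance, so
#' \deqn{ADC_{DM} = 100 \times (1 - marker_{diet} / marker_{faeces})}
#' with both markers on the same (dry-matter) basis.
#'
#' @param diet_marker Dietary marker concentration, % DM.
#' @param faecal_marker Faecal marker concentration, % DM.
#' @return ADC in %. A non-positive value (faecal marker not enriched over
#'   the diet) is physically implausible and is returned with a warning
#'   rather than silently clipped.
#' @examples
#' adc_dry_matter(0.02, 0.10) # 80
#' @export
adc_dry_matter <- function(diet_marker, faecal_marker) {
  stopifnot(all(diet_marker > 0), all(faecal_marker > 0))
  adc <- 100 * (1 - diet_marker / faecal_marker)
  if (any(adc <= 0)) {
    warning("non-positive dry-matter ADC: faecal marker not enriched over ",
            "the diet; check marker assays", call. = FALSE)
  }
  adc
}

#' Apparent digestibility coefficient of a nutrient or of energy
#'
#' \deqn{ADC = 100 \times \left(1 - \frac{marker_{diet}}{marker_{faeces}}
#'   \times \frac{level_{faeces}}{level_{diet}}\right)}
#' Marker and constituent levels must share a basis (dry matter throughout
#' this package). Reduces to [adc_dry_matter()] when the faecal and dietary
#' constituent levels are equal.
#'
#' @param diet_marker,faecal_marker Marker concentrations, % DM.
#' @param diet_level,faecal_level Constituent concentration (% DM) or gross
#'   energy (kJ/g DM) in diet and faeces.
#' @return ADC in %, with the same implausibility warning as
#'   [adc_dry_matter()] for values <= 0.
#' @examples
#' adc_nutrient(0.0212, 0.106, 53.66, 14.0) # about 94.78
#' @export
adc_nutrient <- function(diet_marker, faecal_marker, diet_level,
                         faecal_level) {
  stopifnot(all(diet_marker > 0), all(faecal_marker > 0),
            all(diet_level > 0), all(faecal_level >= 0))
  adc <- 100 * (1 - (diet_marker / faecal_marker) *
                  (faecal_level / diet_level))
  if (any(adc <= 0)) {
    warning("non-positive nutrient ADC flagged as physically implausible",
            call. = FALSE)
  }
  adc
}

#' Per-tank ADC set from diet and faecal composition
#'
#' Converts the diet's as-fed composition and marker to the dry-matter basis
#' (`value / (dm/100)`, see [as_dm_basis()]) and applies the marker-ratio
#' formulas for dry matter, protein, lipid, phosphorus and energy.
#'
#' @param diet A [diet_spec()].
#' @param faeces A [faecal_sample()] (DM-basis concentrations).
#' @return A one-row tibble: `tank_id`, `diet`, `adc_dm`, `adc_protein`,
#'   `adc_lipid`, `adc_phosphorus`, `adc_energy`, `implausible` (TRUE when
#'   any ADC is <= 0 or > 100).
#' @export
compute_adc_set <- function(diet, faeces) {
  stopifnot(inherits(diet, "diet_spec"), inherits(faeces, "faecal_sample"))
  dmarker <- as_dm_basis(diet$marker, diet$dm)
  dlev <- c(protein = as_dm_basis(diet$crude_protein, diet$dm),
            lipid = as_dm_basis(diet$crude_fat, diet$dm),
            phosphorus = as_dm_basis(diet$total_p, diet$dm),
            energy = as_dm_basis(diet$gross_energy, diet$dm))
  flev <- c(protein = faeces$protein, lipid = faeces$lipid,
            phosphorus = faeces$phosphorus, energy = faeces$energy)
  adc <- withCallingHandlers({
    c(dm = adc_dry_matter(dmarker, faeces$marker),
      vapply(names(dlev), function(k) {
        adc_nutrient(dmarker, faeces$marker, dlev[[k]], flev[[k]])
      }, numeric(1)))
  }, warning = function(w) invokeRestart("muffleWarning"))
  tibble::tibble(tank_id = faeces$tank_id, diet = diet$name,
                 adc_dm = adc[["dm"]], adc_protein = adc[["protein"]],
                 adc_lipid = adc[["lipid"]],
                 adc_phosphorus = adc[["phosphorus"]],
                 adc_energy = adc[["energy"]],
                 implausible = any(adc <= 0 | adc > 100))
}

#' Tank-level ADCs for a whole trial
#'
#' @param trial A [trial_dataset()] carrying faecal samples.
#' @return Tibble of per-tank ADC sets (see [compute_adc_set()]).
#' @export
trial_adc <- function(trial) {
  stopifnot(inherits(trial, "trial_dataset"))
  if (is.null(trial$faeces)) stop("trial has no faecal samples", call. = FALSE)
  purrr::map_dfr(trial$faeces, function(f) {
    diet_name <- trial$tanks[[f$tank_id]]$diet
    compute_adc_set(trial$diets[[diet_name]], f)
  })
}

#' Treatment-level ADC summary
#'
#' Mean and standard deviation over tank ADCs within each diet (the tank is
#' the experimental unit, n = number of replicate tanks).
#'
#' @param adc_set Tibble from [trial_adc()].
#' @return Tibble with one row per diet x constituent: `diet`, `constituent`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_adc <- function(adc_set) {
  adc_set |>
    tidyr::pivot_longer(dplyr::starts_with("adc_"),
                        names_to = "constituent", names_prefix = "adc_",
                        values_to = "adc") |>
    dplyr::group_by(.data$diet, .data$constituent) |>
    dplyr::summarise(mean = mean(.data$adc), sd = stats::sd(.data$adc),
                     n = dplyr::n(), .groups = "drop")
}
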