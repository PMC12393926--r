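# Bundled reference tables for the three-diet gilthead seabream trial the
# package's defaults emulate (CTRL commercial-like, ORG organic-based, ECO
# circular-economy). These drive the synthetic generator's default
# conditions and the worked examples.

ext_file <- function(name) {
  system.file("extdata", name, package = "aquatrial", mustWork = TRUE)
}

read_ext <- function(name) {
  tibble::as_tibble(utils::read.csv(ext_file(name),
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Reference diet specifications
#'
#' The three experimental feeds of the emulated seabream trial (CTRL, ORG,
#' ECO): ingredient formulations, proximate compositions (as fed), yttrium
#' oxide marker at 0.02%, and total amino-acid profiles. GWP factors are
#' attached from the bundled synthetic factor table when
#' `with_gwp_factors = TRUE`; these factors are calibrated stand-ins (the
#' underlying life-cycle database values are not public) and reproduce the
#' reference diet totals exactly, so they exercise the aggregation
#' mechanics, not the database values.
#'
#' @param with_gwp_factors Attach the synthetic per-ingredient GWP factors?
#' @return Named list of [diet_spec()] objects.
#' @export
reference_diets <- function(with_gwp_factors = FALSE) {
  comp <- read_ext("diet_composition.csv")
  ing <- read_ext("diet_ingredients.csv")
  aa <- read_ext("aa_profile.csv")
  if (with_gwp_factors) {
    fac <- read_ext("gwp_factors_synthetic.csv")
    ing <- dplyr::left_join(ing, fac, by = "ingredient")
  }
  out <- lapply(seq_len(nrow(comp)), function(i) {
    d <- comp[i, ]
    diet_spec(d$diet,
              ingredients = ing[ing$diet == d$diet,
                                setdiff(names(ing), "diet")],
              dm = d$dm, ash = d$ash, crude_protein = d$crude_protein,
              crude_fat = d$crude_fat, total_p = d$total_p,
              gross_energy = d$gross_energy, marker = d$marker,
              aa_profile = aa[aa$diet == d$diet,
                              c("amino_acid", "class", "mg_per_g_dm")])
  })
  names(out) <- comp$diet
  out
}

#' Reference treatment-level summaries
#'
#' Treatment means and SDs (n = 3 tanks) of the emulated trial: apparent
#' digestibility coefficients, growth/feed-utilisation/somatic indicators,
#' whole-body composition pools, retentions, qPCR gene panel (amplification
#' efficiencies and roles) and growth-period relative expression.
#'
#' @return A named list of tibbles: `adc`, `performance`,
#'   `body_composition`, `retention`, `genes`, `expression`.
#' @export
reference_tables <- function() {
  list(adc = read_ext("adc_reference.csv"),
       performance = read_ext("performance_reference.csv"),
       body_composition = read_ext("body_composition_reference.csv"),
       retention = read_ext("retention_reference.csv"),
       genes = read_ext("qpcr_genes.csv"),
       expression = read_ext("expression_reference.csv"))
}

#' Synthetic per-ingredient GWP factor table
#'
#' @return Tibble with `ingredient` and `gwp_factor` (kg CO2-eq per tonne
#'   of ingredient). See [reference_diets()] for the calibration caveat.
#' @export
synthetic_gwp_factors <- function() {
  read_ext("gwp_factors_synthetic.csv")
}
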