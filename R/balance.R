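#' Reference biomass for per-kilogram daily rates
#'
#' The phosphorus fluxes are expressed per kg of fish per day; which biomass
#' the kilogram refers to must be fixed by convention. The default is the
#' arithmetic mean of initial and final biomass; initial, final and
#' geometric-mean conventions are selectable.
#'
#' @param biomass_initial,biomass_final Biomass, g.
#' @param convention One of `"mean"`, `"initial"`, `"final"`, `"geometric"`.
#' @return Reference biomass in kg.
#' @examples
#' reference_biomass(14100, 42600) # 28.35 kg
#' @export
reference_biomass <- function(biomass_initial, biomass_final,
                              convention = c("mean", "initial", "final",
                                             "geometric")) {
  convention <- match.arg(convention)
  stopifnot(all(biomass_initial > 0), all(biomass_final > 0))
  g <- switch(convention,
              mean = (biomass_initial + biomass_final) / 2,
              initial = biomass_initial,
              final = biomass_final,
              geometric = sqrt(biomass_initial * biomass_final))
  g / 1000
}

#' Crude phosphorus intake
#'
#' CPI (mg P kg^-1 day^-1) = 1000 x P intake (g) / reference biomass (kg)
#' / feeding days. P intake is feed intake (as fed) times the diet's total
#' P (% as fed) — the as-fed product equals the DM product.
#'
#' @param feed_intake Feed consumed, g as fed (tank total or per fish, as
#'   long as `ref_biomass` is on the same footing).
#' @param diet A [diet_spec()].
#' @param ref_biomass Reference biomass, kg (see [reference_biomass()]).
#' @param days Feeding days.
#' @return CPI, mg P kg^-1 day^-1.
#' @export
crude_p_intake <- function(feed_intake, diet, ref_biomass, days) {
  stopifnot(inherits(diet, "diet_spec"), all(ref_biomass > 0),
            all(days >= 1))
  1000 * (feed_intake * diet$total_p / 100) / ref_biomass / days
}

#' Daily phosphorus gain
#'
#' Body P mass at the end minus at the start, per reference biomass per
#' day. Percent P is taken on the basis in which the body-composition table
#' is expressed (wet-weight pools here): masses, not percentages, enter the
#' balance.
#'
#' @param biomass_initial,biomass_final Biomass, g (same footing as
#'   `ref_biomass`).
#' @param p_initial,p_final Whole-body P content, % of body mass.
#' @param ref_biomass Reference biomass, kg.
#' @param days Feeding days.
#' @return PG, mg P kg^-1 day^-1.
#' @export
p_gain <- function(biomass_initial, biomass_final, p_initial, p_final,
                   ref_biomass, days) {
  stopifnot(all(p_initial >= 0), all(p_initial <= 100),
            all(p_final >= 0), all(p_final <= 100),
            all(ref_biomass > 0), all(days >= 1))
  1000 * (biomass_final * p_final / 100 -
            biomass_initial * p_initial / 100) / ref_biomass / days
}

#' Daily faecal phosphorus loss
#'
#' The undigested fraction of the phosphorus intake:
#' FPL = CPI x (100 - ADC_P)/100. By construction
#' FPL/CPI + ADC_P/100 = 1.
#'
#' @param cpi Crude P intake, mg P kg^-1 day^-1.
#' @param adc_p Apparent digestibility coefficient of P, %.
#' @return FPL, mg P kg^-1 day^-1.
#' @export
faecal_p_loss <- function(cpi, adc_p) {
  stopifnot(all(adc_p >= 0), all(adc_p <= 100))
  cpi * (100 - adc_p) / 100
}

#' Daily metabolic (non-faecal) phosphorus loss
#'
#' The mass-balance closure term: MPL = CPI - PG - FPL, covering urinary
#' and branchial excretion of absorbed P not fixed in the body. A negative
#' value (gain plus faecal loss exceeding intake) is physically suspicious
#' and is returned with a warning.
#'
#' @param cpi,pg,fpl Fluxes, mg P kg^-1 day^-1.
#' @return MPL, mg P kg^-1 day^-1.
#' @export
metabolic_p_loss <- function(cpi, pg, fpl) {
  mpl <- cpi - pg - fpl
  if (any(mpl < 0)) {
    warning("negative metabolic P loss: gain + faecal loss exceed intake",
            call. = FALSE)
  }
  mpl
}

#' Retention on a digestible-intake basis
#'
#' 100 x body gain / (intake x ADC/100), with gain and intake both as
#' masses (g) or energies (kJ). Values above 100 imply more nutrient fixed
#' than digested and are flagged.
#'
#' @param nutrient_gain Body content gain, g (or kJ).
#' @param intake Gross intake of the constituent, g (or kJ).
#' @param adc Apparent digestibility coefficient, % in (0, 100].
#' @return Retention, % of digestible intake.
#' @export
retention <- function(nutrient_gain, intake, adc) {
  stopifnot(all(intake > 0))
  if (any(adc <= 0 | adc > 100)) {
    stop("retention needs an ADC in (0, 100]", call. = FALSE)
  }
  r <- 100 * nutrient_gain / (intake * adc / 100)
  if (any(r > 100)) {
    warning("retention above 100% of digestible intake flagged", call. = FALSE)
  }
  r
}

#' Per-tank phosphorus balance
#'
#' Assembles CPI, PG, FPL and MPL for every tank of a period, using the
#' tank's ADC of phosphorus and its initial/final whole-body composition
#' pools. Conservation CPI = PG + FPL + MPL holds exactly, MPL being the
#' closure term.
#'
#' @param trial A [trial_dataset()] with body-composition pools.
#' @param adc_set Tibble from [trial_adc()] (needs `adc_phosphorus`).
#' @param convention Reference-biomass convention, see
#'   [reference_biomass()].
#' @param period Period to evaluate.
#' @return Tibble with per-tank `cpi`, `pg`, `fpl`, `mpl` (mg P kg^-1
#'   day^-1) and `ref_biomass_kg`.
#' @export
phosphorus_balance <- function(trial, adc_set, convention = "mean",
                               period = "growth") {
  stopifnot(inherits(trial, "trial_dataset"))
  bc <- trial$body_composition
  if (is.null(bc)) stop("trial has no body-composition pools", call. = FALSE)
  tanks <- Filter(function(t) t$period == period, trial$tanks)
  purrr::map_dfr(tanks, function(t) {
    adc_p <- adc_set$adc_phosphorus[match(t$diet, adc_set$diet)][1]
    if (is.na(adc_p)) {
      stop("no phosphorus ADC available for diet ", t$diet, call. = FALSE)
    }
    final_bc <- bc$final[[t$tank_id]]
    rb <- reference_biomass(t$biomass_initial, t$biomass_final, convention)
    cpi <- crude_p_intake(t$feed_distributed, trial$diets[[t$diet]], rb,
                          t$days)
    pg <- p_gain(t$biomass_initial, t$biomass_final,
                 bc$initial$phosphorus, final_bc$phosphorus, rb, t$days)
    fpl <- faecal_p_loss(cpi, adc_p)
    mpl <- suppressWarnings(metabolic_p_loss(cpi, pg, fpl))
    tibble::tibble(tank_id = t$tank_id, diet = t$diet,
                   ref_biomass_kg = rb, cpi = cpi, pg = pg, fpl = fpl,
                   mpl = mpl, mpl_negative = mpl < 0)
  })
}

#' Per-tank nutrient and energy retention
#'
#' Retention (% of digestible intake) of protein, lipid, phosphorus and
#' energy, from whole-body composition pools, tank feed intake and the
#' diet's tank/treatment ADCs.
#'
#' @inheritParams phosphorus_balance
#' @return Tibble with one row per tank x constituent: `tank_id`, `diet`,
#'   `constituent`, `retention_pct_digestible`.
#' @export
retention_set <- function(trial, adc_set, period = "growth") {
  stopifnot(inherits(trial, "trial_dataset"))
  bc <- trial$body_composition
  if (is.null(bc)) stop("trial has no body-composition pools", call. = FALSE)
  constituents <- c(protein = "crude_protein", lipid = "crude_fat",
                    phosphorus = "total_p", energy = "gross_energy")
  tanks <- Filter(function(t) t$period == period, trial$tanks)
  purrr::map_dfr(tanks, function(t) {
    diet <- trial$diets[[t$diet]]
    final_bc <- bc$final[[t$tank_id]]
    adc_row <- adc_set[match(t$diet, adc_set$diet), ]
    purrr::map_dfr(names(constituents), function(k) {
      diet_level <- diet[[constituents[[k]]]]
      # body composition is % (or kJ/g) of wet mass; intake is as fed
      gain <- t$biomass_final * final_bc[[k]] / 100 -
        t$biomass_initial * bc$initial[[k]] / 100
      intake <- t$feed_distributed * diet_level / 100
      if (k == "energy") {
        gain <- t$biomass_final * final_bc$energy -
          t$biomass_initial * bc$initial$energy
        intake <- t$feed_distributed * diet$gross_energy
      }
      adc <- adc_row[[paste0("adc_", k)]]
      tibble::tibble(tank_id = t$tank_id, diet = t$diet, constituent = k,
                     retention_pct_digestible =
                       suppressWarnings(retention(gain, intake, adc)))
    })
  })
}
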