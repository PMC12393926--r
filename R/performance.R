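#' Specific growth rate
#'
#' \deqn{SGR = (\ln FBW - \ln IBW) / days}
#' Reported here in natural-log units per day *without* the conventional
#' x100: a juvenile roughly trebling its weight over 65 days has SGR around
#' 0.018 day^-1 on this scale. Output headers carry the unit to prevent
#' misuse against %/day conventions.
#'
#' @param ibw,fbw Initial and final body weight, g (per fish).
#' @param days Number of feeding days.
#' @return SGR, day^-1.
#' @examples
#' sgr(14.1, 47.8, 65) # about 0.0188
#' @export
sgr <- function(ibw, fbw, days) {
  stopifnot(all(ibw > 0), all(fbw > 0), all(days >= 1))
  (log(fbw) - log(ibw)) / days
}

#' Feed intake per fish and feed conversion ratio
#'
#' FI = feed distributed / number of fish; FCR = apparent feed intake per
#' unit wet weight gain. At the per-fish level FCR = FI / (FBW - IBW),
#' algebraically identical to tank feed / tank gain when counts agree.
#'
#' @param feed_distributed Feed consumed, g as fed (net of leftovers).
#' @param n_fish Number of fish (fish counted at the end of the period).
#' @param ibw,fbw Initial and final mean body weight, g.
#' @return A list with `fi` (g/fish) and `fcr` (dimensionless).
#' @examples
#' fcr_fi(36.3 * 87, 87, 14.1, 47.8)
#' @export
fcr_fi <- function(feed_distributed, n_fish, ibw, fbw) {
  stopifnot(n_fish >= 1, feed_distributed >= 0)
  gain <- fbw - ibw
  if (gain <= 0) {
    stop("FCR is undefined for non-positive weight gain", call. = FALSE)
  }
  fi <- feed_distributed / n_fish
  list(fi = fi, fcr = fi / gain)
}

#' Protein efficiency ratio
#'
#' PER = wet weight gain / crude protein intake. Crude protein % (as fed)
#' times as-fed intake equals CP (DM) times DM intake, so the as-fed product
#' is used directly.
#'
#' @param ibw,fbw Initial and final mean body weight, g.
#' @param fi Feed intake, g/fish as fed.
#' @param diet A [diet_spec()] (its `crude_protein`, % as fed, is used).
#' @return PER (g gain per g crude protein).
#' @examples
#' d <- diet_spec("ORG", dm = 96.9, ash = 7, crude_protein = 51.05,
#'                crude_fat = 17.9, total_p = 1.02, gross_energy = 22.2,
#'                marker = 0.02)
#' per(14.1, 42.6, 34.7, d) # about 1.61
#' @export
per <- function(ibw, fbw, fi, diet) {
  stopifnot(inherits(diet, "diet_spec"))
  cp_intake <- fi * diet$crude_protein / 100
  if (any(cp_intake <= 0)) {
    stop("crude-protein intake must be positive", call. = FALSE)
  }
  (fbw - ibw) / cp_intake
}

#' Somatic indices from individual morphometry
#'
#' VSI = 100 x viscera/body weight; HSI = 100 x liver/body weight;
#' Fulton condition factor K = 100 x body weight / length^3 (g, cm).
#'
#' @param fish A morphometry data frame (see [fish_morphometry()]).
#' @return The input tibble with columns `vsi`, `hsi`, `k` appended
#'   (NA where the needed organ weight is absent).
#' @export
somatic_indices <- function(fish) {
  fish <- fish_morphometry(fish)
  fish$k <- 100 * fish$body_weight / fish$total_length^3
  fish$vsi <- if ("viscera_weight" %in% names(fish)) {
    100 * fish$viscera_weight / fish$body_weight
  } else NA_real_
  fish$hsi <- if ("liver_weight" %in% names(fish)) {
    100 * fish$liver_weight / fish$body_weight
  } else NA_real_
  fish
}

#' Weight gain and survival for a tank
#'
#' WG (% of initial biomass) = 100 x (final - initial biomass)/initial
#' biomass; survival = 100 x final count / initial count.
#'
#' @param tank A [tank_record()].
#' @return A list with `wg` (%) and `survival` (%).
#' @export
wg_survival <- function(tank) {
  stopifnot(inherits(tank, "tank_record"))
  if (tank$n_initial == 0) stop("n_initial must be positive", call. = FALSE)
  list(wg = 100 * (tank$biomass_final - tank$biomass_initial) /
         tank$biomass_initial,
       survival = 100 * tank$n_final / tank$n_initial)
}

#' Tank-level key performance indicators
#'
#' Computes per-tank IBW/FBW (biomass over count), WG, SGR, FI, FCR, PER
#' and survival, plus tank means of the somatic indices when individual
#' morphometry is available.
#'
#' @param trial A [trial_dataset()].
#' @param period Period to evaluate (default `"growth"`).
#' @return A tibble, one row per tank.
#' @export
trial_kpi <- function(trial, period = "growth") {
  stopifnot(inherits(trial, "trial_dataset"))
  tanks <- Filter(function(t) t$period == period, trial$tanks)
  if (!length(tanks)) stop("no tanks in period '", period, "'", call. = FALSE)
  purrr::map_dfr(tanks, function(t) {
    ibw <- t$biomass_initial / t$n_initial
    fbw <- t$biomass_final / t$n_final
    ff <- fcr_fi(t$feed_distributed, t$n_final, ibw, fbw)
    ws <- wg_survival(t)
    dspec <- trial$diets[[t$diet]]
    per_val <- per(ibw, fbw, ff$fi, dspec)
    out <- tibble::tibble(
      tank_id = t$tank_id, diet = t$diet,
      ibw = ibw, fbw = fbw, wg = ws$wg,
      sgr = sgr(ibw, fbw, t$days),
      fi = ff$fi, fcr = ff$fcr,
      per = per_val,
      survival = ws$survival,
      vsi = NA_real_, hsi = NA_real_, k = NA_real_)
    m <- trial$morphometry[[t$tank_id]]
    if (!is.null(m)) {
      si <- somatic_indices(m)
      out$vsi <- mean(si$vsi)
      out$hsi <- mean(si$hsi)
      out$k <- mean(si$k)
    }
    out
  })
}

#' Treatment-level performance summary
#'
#' Mean and SD over tank-level values within each diet — never over pooled
#' fish, the tank being the experimental unit. Somatic indices enter as the
#' per-tank fish means from [trial_kpi()].
#'
#' @param kpi Tibble from [trial_kpi()].
#' @return Tibble with one row per diet x indicator: `diet`, `indicator`
#'   (unit carried in the name, e.g. `sgr_per_day`), `mean`, `sd`, `n`.
#' @export
summarize_performance <- function(kpi) {
  unit_names <- c(ibw = "ibw_g", fbw = "fbw_g", wg = "wg_pct_ibw",
                  sgr = "sgr_per_day", fi = "fi_g_per_fish", fcr = "fcr",
                  per = "per", survival = "survival_pct", vsi = "vsi_pct",
                  hsi = "hsi_pct", k = "k")
  kpi |>
    tidyr::pivot_longer(dplyr::all_of(names(unit_names)),
                        names_to = "indicator", values_to = "value") |>
    dplyr::mutate(indicator = unit_names[.data$indicator]) |>
    dplyr::group_by(.data$diet, .data$indicator) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}
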