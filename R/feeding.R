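#' Fit a thermal growth coefficient
#'
#' Classical cube-root TGC: the cube root of body weight grows linearly in
#' accumulated temperature-days,
#' \deqn{TGC = (FBW^{1/3} - IBW^{1/3}) / \sum_d T_d .}
#' The exponent is configurable so daily-increment variants can be swapped
#' in without code change.
#'
#' @param ibw,fbw Initial and final body weight, g.
#' @param temperatures Daily water temperature series, degrees C.
#' @param exponent Allometric exponent (default 1/3).
#' @return TGC, weight-unit^exponent per degree-day.
#' @examples
#' fit_tgc(14.1, 47.8, rep(23.5, 65)) # about 7.95e-4
#' @export
fit_tgc <- function(ibw, fbw, temperatures, exponent = 1 / 3) {
  stopifnot(ibw > 0, fbw > 0)
  td <- sum(temperatures)
  if (td <= 0) stop("temperature-day sum must be positive", call. = FALSE)
  (fbw^exponent - ibw^exponent) / td
}

#' Project daily weight under the TGC model
#'
#' \deqn{w_d = (IBW^{1/3} + TGC \sum_{k \le d} T_k)^3}
#' Exact inverse of [fit_tgc()]: projecting at the fitted TGC over the same
#' temperature series ends at FBW to numerical precision.
#'
#' @param ibw Initial body weight, g.
#' @param temperatures Daily temperature series, degrees C.
#' @param tgc Thermal growth coefficient.
#' @param exponent Allometric exponent matching the fit.
#' @return Numeric vector of projected weights, one per day (after each
#'   day's growth).
#' @export
project_weight <- function(ibw, temperatures, tgc, exponent = 1 / 3) {
  stopifnot(ibw > 0)
  base <- ibw^exponent + tgc * cumsum(temperatures)
  if (any(base <= 0)) {
    stop("projection reached non-positive weight (negative TGC too large)",
         call. = FALSE)
  }
  base^(1 / exponent)
}

#' Construct a feeding-rate table
#'
#' A grid of feeding rates (% of biomass per day) over body-weight and
#' temperature classes, the kind of tailored ration guideline bioenergetic
#' tools output. Classes are half-open `[min, max)` intervals.
#'
#' @param df Data frame with columns `weight_min`, `weight_max`,
#'   `temp_min`, `temp_max`, `rate` (% biomass/day).
#' @return An object of class `feeding_table`.
#' @export
feeding_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("weight_min", "weight_max", "temp_min", "temp_max", "rate")
  stopifnot(all(need %in% names(df)))
  if (any(df$rate <= 0)) stop("feeding rates must be positive", call. = FALSE)
  if (any(df$weight_min >= df$weight_max) || any(df$temp_min >= df$temp_max)) {
    stop("class intervals must have min < max", call. = FALSE)
  }
  structure(df, class = c("feeding_table", class(df)))
}

lookup_rate <- function(table, weight, temp, day) {
  hit <- table$weight_min <= weight & weight < table$weight_max &
    table$temp_min <= temp & temp < table$temp_max
  if (!any(hit)) {
    stop("feeding table does not cover weight ", signif(weight, 4),
         " g at ", signif(temp, 4), " degC (day ", day, ")", call. = FALSE)
  }
  table$rate[which(hit)[1]]
}

#' Build a daily feeding plan
#'
#' Projects mean weight with the TGC model, converts to tank biomass via
#' the fish count, looks up the feeding rate for the day's weight and
#' temperature class and sets the ration to biomass x rate/100. At each
#' anchor day (intermediate bulk weighing) the projection restarts from the
#' measured biomass — re-anchoring with the projected value itself leaves
#' the plan unchanged.
#'
#' @param tank A [tank_record()] (its count, initial biomass and
#'   temperature series are used).
#' @param table A [feeding_table()].
#' @param tgc Thermal growth coefficient to project with.
#' @param anchors Optional data frame with columns `day` and `biomass` (g):
#'   measured bulk weights that re-anchor the projection from that day on.
#' @param exponent Allometric exponent of the TGC model.
#' @return A tibble, one row per day: `day`, `temp`, `mean_weight`,
#'   `biomass`, `rate`, `ration` (g), plus an `anchored` flag.
#' @export
build_feeding_plan <- function(tank, table, tgc, anchors = NULL,
                               exponent = 1 / 3) {
  stopifnot(inherits(tank, "tank_record"), inherits(table, "feeding_table"))
  n <- tank$n_initial
  temps <- tank$temperatures
  days <- tank$days
  anchor_map <- numeric(0)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    anchor_map <- stats::setNames(anchors$biomass, anchors$day)
  }
  w <- tank$biomass_initial / n
  out <- vector("list", days)
  for (d in seq_len(days)) {
    anchored <- FALSE
    if (as.character(d) %in% names(anchor_map)) {
      w <- anchor_map[[as.character(d)]] / n
      anchored <- TRUE
    }
    # grow through day d, feed on the day's projected weight
    w <- (w^exponent + tgc * temps[d])^(1 / exponent)
    biomass <- w * n
    rate <- lookup_rate(table, w, temps[d], d)
    out[[d]] <- tibble::tibble(day = d, temp = temps[d], mean_weight = w,
                               biomass = biomass, rate = rate,
                               ration = biomass * rate / 100,
                               anchored = anchored)
  }
  dplyr::bind_rows(out)
}
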