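#' Construct a diet specification
#'
#' A `diet_spec` bundles everything the pipeline needs to know about one
#' experimental feed: the ingredient formulation (inclusion levels as % of
#' feed mass, optionally with per-ingredient global-warming-potential
#' factors), the proximate composition on an as-fed basis, the inert-marker
#' level, and an optional amino-acid profile.
#'
#' All percentages are on the 0--100 scale. Proximate composition is as fed;
#' conversion to a dry-matter basis (needed for digestibility arithmetic
#' against freeze-dried faeces) is done downstream via [as_dm_basis()].
#'
#' @param name Diet label (e.g. `"CTRL"`).
#' @param ingredients Data frame with columns `ingredient`, `inclusion`
#'   (% of feed mass) and optionally `gwp_factor` (kg CO2-eq per tonne of
#'   ingredient). May be `NULL` for composition-only uses.
#' @param dm,ash,crude_protein,crude_fat,total_p Proximate composition,
#'   % as fed.
#' @param gross_energy Gross energy, kJ/g as fed.
#' @param marker Inert marker (yttrium oxide) level, % as fed.
#' @param aa_profile Optional data frame with columns `amino_acid`, `class`
#'   (`"essential"` or `"nonessential"`) and `mg_per_g_dm` (mg amino acid
#'   per g dry weight).
#'
#' @return An object of class `diet_spec`.
#' @examples
#' d <- diet_spec("CTRL",
#'   ingredients = data.frame(ingredient = c("fishmeal", "wheat"),
#'                            inclusion = c(40, 60)),
#'   dm = 94.3, ash = 7.8, crude_protein = 50.6, crude_fat = 17.7,
#'   total_p = 1.10, gross_energy = 21.8, marker = 0.02)
#' validate_formulation(d)
#' @export
diet_spec <- function(name, ingredients = NULL, dm, ash, crude_protein,
                      crude_fat, total_p, gross_energy, marker,
                      aa_profile = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(ingredients)) {
    ingredients <- tibble::as_tibble(ingredients)
    need <- c("ingredient", "inclusion")
    if (!all(need %in% names(ingredients))) {
      stop("`ingredients` must have columns 'ingredient' and 'inclusion'",
           call. = FALSE)
    }
    if (!"gwp_factor" %in% names(ingredients)) {
      ingredients$gwp_factor <- NA_real_
    }
  }
  comp <- c(dm = dm, ash = ash, crude_protein = crude_protein,
            crude_fat = crude_fat, total_p = total_p)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 100)) {
    stop("proximate composition fields must be percentages in [0, 100]",
         call. = FALSE)
  }
  if (any(comp[c("ash", "crude_protein", "crude_fat")] > dm)) {
    stop("no as-fed constituent can exceed the dry-matter content",
         call. = FALSE)
  }
  if (!is.finite(gross_energy) || gross_energy <= 0) {
    stop("`gross_energy` must be positive (kJ/g as fed)", call. = FALSE)
  }
  if (!is.finite(marker) || marker <= 0) {
    stop("`marker` must be positive (% as fed)", call. = FALSE)
  }
  if (!is.null(aa_profile)) aa_profile <- tibble::as_tibble(aa_profile)
  structure(
    list(name = name, ingredients = ingredients,
         dm = dm, ash = ash, crude_protein = crude_protein,
         crude_fat = crude_fat, total_p = total_p,
         gross_energy = gross_energy, marker = marker,
         aa_profile = aa_profile),
    class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("<diet_spec> ", x$name, "\n", sep = "")
  cat(sprintf("  DM %.2f%% | CP %.2f%% | CF %.2f%% | ash %.2f%% | P %.2f%% | GE %.2f kJ/g | marker %.3f%%\n",
              x$dm, x$crude_protein, x$crude_fat, x$ash, x$total_p,
              x$gross_energy, x$marker))
  if (!is.null(x$ingredients)) {
    cat("  ", nrow(x$ingredients), " ingredients, inclusion sum ",
        sprintf("%.2f", sum(x$ingredients$inclusion)), "%\n", sep = "")
  }
  invisible(x)
}

#' Validate a diet formulation
#'
#' Checks that ingredient inclusions sum to 100 (within 0.01), that every
#' inclusion and composition field lies in range, and lists ingredients
#' lacking a GWP factor. This is a reporting operation: it never throws.
#'
#' @param diet A [diet_spec()].
#' @param tol Tolerance on the inclusion sum, percentage points.
#' @return A list of class `formulation_report` with elements
#'   `inclusion_sum`, `pass`, `out_of_range` (character vector of offending
#'   ingredients) and `missing_gwp_factors`.
#' @export
validate_formulation <- function(diet, tol = 0.01) {
  stopifnot(inherits(diet, "diet_spec"))
  if (is.null(diet$ingredients)) {
    return(structure(list(diet = diet$name, inclusion_sum = NA_real_,
                          pass = FALSE, out_of_range = character(),
                          missing_gwp_factors = character(),
                          message = "no ingredient table"),
                     class = "formulation_report"))
  }
  inc <- diet$ingredients
  s <- sum(inc$inclusion)
  bad <- inc$ingredient[inc$inclusion < 0 | inc$inclusion > 100]
  missing_gwp <- inc$ingredient[is.na(inc$gwp_factor)]
  pass <- abs(s - 100) <= tol && length(bad) == 0L
  structure(list(diet = diet$name, inclusion_sum = s, pass = pass,
                 out_of_range = as.character(bad),
                 missing_gwp_factors = as.character(missing_gwp),
                 message = if (pass) "ok" else "formulation check failed"),
            class = "formulation_report")
}

#' @export
print.formulation_report <- function(x, ...) {
  cat("<formulation_report> ", x$diet, ": ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  cat(sprintf("  inclusion sum: %.2f%%\n", x$inclusion_sum))
  if (length(x$out_of_range)) {
    cat("  out of range:", paste(x$out_of_range, collapse = ", "), "\n")
  }
  if (length(x$missing_gwp_factors)) {
    cat("  missing GWP factors:",
        paste(x$missing_gwp_factors, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert as-fed constituent levels to a dry-matter basis
#'
#' Faecal analyses are performed on freeze-dried material, so the
#' diet-side terms of the digestibility ratios must be expressed per unit
#' dry matter: `value_dm = value_as_fed / (dm/100)`.
#'
#' @param value Constituent level, as-fed basis (% or kJ/g).
#' @param dm Dry-matter content of the feed, % as fed.
#' @return The level on a DM basis. The conversion is the identity when
#'   `dm = 100`, and applying it twice with `dm = 100` changes nothing
#'   (idempotent on already-DM values).
#' @export
as_dm_basis <- function(value, dm) {
  stopifnot(all(dm > 0), all(dm <= 100))
  value / (dm / 100)
}

#' Amino-acid totals by class
#'
#' Sums a diet's amino-acid profile (mg AA per g dry weight) within the
#' essential and non-essential classes.
#'
#' @param diet A [diet_spec()] carrying an `aa_profile`.
#' @return A tibble with columns `class` and `total_mg_per_g_dm`.
#' @export
aa_totals <- function(diet) {
  stopifnot(inherits(diet, "diet_spec"))
  if (is.null(diet$aa_profile)) {
    stop("diet '", diet$name, "' has no amino-acid profile", call. = FALSE)
  }
  diet$aa_profile |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(total_mg_per_g_dm = sum(.data$mg_per_g_dm),
                     .groups = "drop")
}
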