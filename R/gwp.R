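#' Diet global warming potential
#'
#' Aggregates a feed's GWP (kg CO2-eq per tonne of feed) from per-ingredient
#' life-cycle factors: each ingredient contributes its factor weighted by
#' its inclusion level, and contributions are summed. Factors must already
#' carry any economic allocation and transport/processing burden — the
#' life-cycle database work happens upstream of this function.
#'
#' @param diet A [diet_spec()] whose ingredient table carries `gwp_factor`
#'   (kg CO2-eq per tonne of ingredient), or `factors` supplied separately.
#' @param factors Optional data frame with columns `ingredient` and
#'   `gwp_factor` overriding/supplying factors by ingredient name.
#' @return An object of class `gwp_result`: list with `diet`, `total`
#'   (kg CO2-eq/tonne feed; sum over ingredients with known factors),
#'   `contributions` (tibble ingredient/inclusion/factor/contribution),
#'   `missing_factors` (character) and `partial` (TRUE when any factor is
#'   missing).
#' @examples
#' d <- diet_spec("demo",
#'   ingredients = data.frame(ingredient = c("a", "b"),
#'                            inclusion = c(50, 50),
#'                            gwp_factor = c(1000, 2000)),
#'   dm = 94, ash = 7, crude_protein = 50, crude_fat = 18, total_p = 1,
#'   gross_energy = 22, marker = 0.02)
#' diet_gwp(d)$total # 1500
#' @export
diet_gwp <- function(diet, factors = NULL) {
  stopifnot(inherits(diet, "diet_spec"))
  if (is.null(diet$ingredients)) {
    stop("diet '", diet$name, "' has no ingredient table", call. = FALSE)
  }
  inc <- diet$ingredients
  if (!is.null(factors)) {
    factors <- tibble::as_tibble(factors)
    stopifnot(all(c("ingredient", "gwp_factor") %in% names(factors)))
    idx <- match(inc$ingredient, factors$ingredient)
    supplied <- !is.na(idx)
    inc$gwp_factor[supplied] <- factors$gwp_factor[idx[supplied]]
  }
  if (any(inc$gwp_factor < 0, na.rm = TRUE)) {
    stop("negative GWP factor for: ",
         paste(inc$ingredient[!is.na(inc$gwp_factor) & inc$gwp_factor < 0],
               collapse = ", "), call. = FALSE)
  }
  inc$contribution <- (inc$inclusion / 100) * inc$gwp_factor
  missing <- inc$ingredient[is.na(inc$gwp_factor)]
  structure(
    list(diet = diet$name,
         total = sum(inc$contribution, na.rm = TRUE),
         contributions = inc[, c("ingredient", "inclusion", "gwp_factor",
                                 "contribution")],
         missing_factors = as.character(missing),
         partial = length(missing) > 0L),
    class = "gwp_result")
}

#' @export
print.gwp_result <- function(x, ...) {
  cat(sprintf("<gwp_result> %s: %.1f kg CO2-eq/tonne feed%s\n", x$diet,
              x$total, if (x$partial) " (partial: missing factors)" else ""))
  if (length(x$missing_factors)) {
    cat("  missing:", paste(x$missing_factors, collapse = ", "), "\n")
  }
  invisible(x)
}
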