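#' Arcsine square-root transform for percentage data
#'
#' \eqn{y = \arcsin(\sqrt{x/100})}, mapping 0--100% onto 0--pi/2 radians.
#' The classical variance-stabilising transform for proportions observed as
#' percentages (survival, ADCs, somatic indices, body composition,
#' retentions).
#'
#' @param x Percentages in \[0, 100\].
#' @return Transformed values in radians.
#' @examples
#' arcsine_sqrt(c(0, 50, 100))
#' @export
arcsine_sqrt <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop("arcsine square-root transform needs percentages in [0, 100]",
         call. = FALSE)
  }
  asin(sqrt(x / 100))
}

#' Box-Cox transform with maximum-likelihood lambda
#'
#' Profiles the Box-Cox log-likelihood of an intercept-only model over a
#' fixed lambda grid and applies
#' \eqn{(x^\lambda - 1)/\lambda} (or \eqn{\log x} at \eqn{\lambda = 0}) at
#' the maximising value. The transform is monotone for any lambda.
#'
#' @param x Positive numeric series.
#' @param lambda Optional fixed lambda; when `NULL` it is estimated on
#'   `grid`.
#' @param grid Lambda grid for the likelihood profile.
#' @return A list with `y` (transformed series), `lambda`, and `degenerate`
#'   (TRUE for a constant input, which carries no information about lambda;
#'   the series is then returned log-transformed with lambda = 0 and the
#'   flag set).
#' @export
boxcox_transform <- function(x, lambda = NULL,
                             grid = seq(-2, 2, by = 0.05)) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop("Box-Cox transform needs strictly positive values", call. = FALSE)
  }
  degenerate <- stats::sd(x, na.rm = TRUE) == 0 || sum(!is.na(x)) < 3
  if (is.null(lambda)) {
    if (degenerate) {
      lambda <- 0
    } else {
      xx <- x[!is.na(x)]
      n <- length(xx)
      slog <- sum(log(xx))
      # profile log-likelihood of the intercept-only normal model
      ll <- vapply(grid, function(lam) {
        y <- if (abs(lam) < 1e-10) log(xx) else (xx^lam - 1) / lam
        -n / 2 * log(sum((y - mean(y))^2) / n) + (lam - 1) * slog
      }, numeric(1))
      lambda <- grid[which.max(ll)]
    }
  }
  y <- if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
  list(y = y, lambda = lambda, degenerate = degenerate)
}
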