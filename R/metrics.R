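#' Angular deviation between two vectors
#'
#' The positive angle \eqn{\cos^{-1}(v_1^\top v_2 / \lVert v_1\rVert
#' \lVert v_2\rVert)} in degrees, in \eqn{[0, 180]}.  The cosine argument is
#' clamped to \eqn{[-1, 1]} before the arccosine.
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return angle in degrees.
#' @export
angular_deviation <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("angular deviation undefined for a zero vector", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Angular errors of a set of axis estimates
#'
#' For each fit, the global sign that makes the first axis agree with the
#' truth (AD at most 90 degrees) is selected and applied to both estimated
#' axes -- so the second axis's error can reach 180 degrees, which flags a
#' wrong sign pairing.  `rmsae()` is the root mean square over all
#' per-axis errors (2M values for M fits) and `maxae()` their maximum.
#'
#' @param fits a single `axis_fit` or a list of them.
#' @param true_j1,true_j2 the true unit axes.
#' @return `axis_errors()`: a tibble with one row per fit, columns `ad1`,
#'   `ad2` (degrees) and `wrong_pairing` (`ad2 > 90`).
#' @export
axis_errors <- function(fits, true_j1, true_j2) {
  if (inherits(fits, "axis_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    s <- if (angular_deviation(f$j1_hat, true_j1) <= 90) 1 else -1
    ad1 <- angular_deviation(s * f$j1_hat, true_j1)
    ad2 <- angular_deviation(s * f$j2_hat, true_j2)
    tibble::tibble(ad1 = ad1, ad2 = ad2, wrong_pairing = ad2 > 90)
  })
}

#' @rdname axis_errors
#' @return `rmsae()`, `maxae()`: a scalar in degrees.
#' @export
rmsae <- function(fits, true_j1, true_j2) {
  e <- axis_errors(fits, true_j1, true_j2)
  sqrt(mean(c(e$ad1, e$ad2)^2))
}

#' @rdname axis_errors
#' @export
maxae <- function(fits, true_j1, true_j2) {
  e <- axis_errors(fits, true_j1, true_j2)
  max(c(e$ad1, e$ad2))
}
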