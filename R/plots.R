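#' Plot a streaming calibration run
#'
#' Shows the per-axis local uncertainty metric (\eqn{\mu_z + 2\sigma_z})
#' and the sequential angular deviation over batch time, against the
#' acceptance threshold; the acceptance time, if any, is marked.
#'
#' @param object a `hinge_calibration` from [run_acceptance()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hinge_calibration
#' @export
autoplot.hinge_calibration <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    dplyr::select(h, "t", "local1", "local2", "seqad"),
    cols = c("local1", "local2", "seqad"),
    names_to = "metric", values_to = "degrees")
  long$metric <- dplyr::recode(long$metric,
                               local1 = "local, axis 1",
                               local2 = "local, axis 2",
                               seqad = "sequential AD")
  long$degrees <- pmin(long$degrees, 180)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$degrees,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$unc_cfg$e_max,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [s]", y = "uncertainty [deg]",
                  colour = NULL,
                  title = "Local and global uncertainty over the stream")
  if (object$accepted) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_accept,
                                 linetype = "dotted")
  }
  p
}

#' Plot a weight sweep
#'
#' RMSAE versus the weight ratio `w0` on logarithmic axes, one line per
#' motion preset.
#'
#' @param object a `weight_sweep` tibble from [experiment_weight_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot weight_sweep
#' @export
autoplot.weight_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$w0, y = .data$rmsae,
                               colour = factor(.data$motion))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(w[0]), y = "RMSAE [deg]",
                  colour = "motion",
                  title = "Robustness to the residual weight ratio")
}

#' @importFrom rlang .data
NULL
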