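#' Uncertainty-quantification configuration
#'
#' @param mc_samples number of Monte-Carlo draws `L` for propagating the
#'   parameter covariance to angular deviations.
#' @param e_max maximum acceptable uncertainty, degrees.
#' @param n_min number of consecutive estimates whose sequential angular
#'   deviation must stay below `e_max` before an estimate is accepted.
#' @return a list of class `uncertainty_config`.
#' @export
uncertainty_config <- function(mc_samples = 1000, e_max = 3, n_min = 10) {
  stopifnot(mc_samples >= 2, e_max > 0, n_min >= 1)
  structure(list(mc_samples = as.integer(mc_samples), e_max = e_max,
                 n_min = as.integer(n_min)), class = "uncertainty_config")
}

#' Local covariance of the axis parameters
#'
#' The large-sample Gaussian approximation of the estimation-error
#' covariance: \eqn{P_x \approx (J_s^\top J_s)^{-1}}, where \eqn{J_s} is
#' the residual Jacobian at the estimate with all gyroscope rows divided by
#' the sample standard deviation of the gyroscope residuals and all
#' accelerometer rows by that of the accelerometer residuals (standard
#' deviations floored at 1e-12 so a perfect fit does not divide by zero).
#' A singular scaled normal matrix -- non-informative data -- yields a
#' matrix of `Inf` rather than an error, which downstream counts as
#' unbounded local uncertainty.
#'
#' @param data the recording or [hinge_data()] the estimate was fitted on.
#' @param x_hat estimated parameter vector.
#' @param w0 residual weight ratio used in the fit.
#' @return a 4x4 symmetric positive-semidefinite matrix (or all-`Inf`).
#' @export
local_covariance <- function(data, x_hat, w0 = 50) {
  d <- hinge_data(data)
  jj <- joint_jacobian(d, x_hat, w0)
  ng <- d$n_gyro
  scale_rows <- function(rows) {
    if (length(rows) < 2L) return(1)
    max(sd(rows), 1e-12)
  }
  s_g <- scale_rows(jj$e[seq_len(ng)])
  s_a <- scale_rows(jj$e[seq_len(length(jj$e) - ng) + ng])
  Js <- jj$J / c(rep(s_g, ng), rep(s_a, nrow(jj$J) - ng))
  H <- crossprod(Js)
  Px <- tryCatch({
    if (!all(is.finite(H)) || rcond(H) < 1e-14) NULL else solve(H)
  }, error = function(e) NULL)
  if (is.null(Px)) matrix(Inf, 4L, 4L) else (Px + t(Px)) / 2
}

#' Monte-Carlo propagation to angular deviations
#'
#' Draws `L` parameter vectors from \eqn{N(\hat x, P_x)} (sampling through
#' the eigendecomposition, with negative eigenvalues clipped at zero so a
#' numerically indefinite input is repaired rather than rejected), maps
#' each draw to the angular deviations of its two axes from the estimate's
#' axes, and returns the sample mean and the per-axis standard deviation
#' from the unbiased sample covariance.
#'
#' @param x_hat estimated parameter vector.
#' @param Px 4x4 covariance of the parameter errors.
#' @param L number of draws.
#' @param seed optional integer; when given, draws use an isolated seeded
#'   RNG stream, otherwise the current stream.
#' @return a list with `mu` and `sigma`, 2-vectors in degrees (both `Inf`
#'   when `Px` is non-finite).
#' @export
monte_carlo_ad <- function(x_hat, Px, L = 1000, seed = NULL) {
  if (!all(is.finite(Px))) {
    return(list(mu = c(Inf, Inf), sigma = c(Inf, Inf)))
  }
  draw <- function() {
    eg <- eigen((Px + t(Px)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    Z <- matrix(rnorm(4L * L), L, 4L)
    X <- Z %*% (t(eg$vectors) * sqrt(lam))
    X <- sweep(X, 2L, as.numeric(x_hat)[1:4], "+")
    ax <- params_to_axes(x_hat)
    j1s <- spherical_to_axis(X[, 1L], X[, 2L])
    j2s <- spherical_to_axis(X[, 3L], X[, 4L])
    Zad <- cbind(
      acos(pmin(1, pmax(-1, drop(rbind(j1s) %*% ax$j1)))) * 180 / pi,
      acos(pmin(1, pmax(-1, drop(rbind(j2s) %*% ax$j2)))) * 180 / pi
    )
    list(mu = colMeans(Zad), sigma = sqrt(diag(cov(Zad))))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sign-consistent alignment of sequential estimates
#'
#' Applies the global sign (\eqn{+} or \eqn{-}, the same to both axes) that
#' makes the better-matching axis most consistent with the previous
#' estimate.  Only one axis is forced consistent; a sign-pairing flip of
#' the other axis is deliberately preserved so the sequential deviation can
#' detect it.  With no previous estimate the input is returned unchanged.
#'
#' @param j_hat a list with unit axes `j1`, `j2`.
#' @param prev the previous aligned estimate (same shape) or `NULL`.
#' @return a list with (possibly globally negated) `j1`, `j2`.
#' @export
sign_consistent <- function(j_hat, prev = NULL) {
  if (is.null(prev)) return(j_hat)
  score <- function(s) {
    min(angular_deviation(s * j_hat$j1, prev$j1),
        angular_deviation(s * j_hat$j2, prev$j2))
  }
  if (score(-1) < score(1)) {
    list(j1 = -j_hat$j1, j2 = -j_hat$j2)
  } else {
    j_hat
  }
}

#' Sequential angular deviation
#'
#' The larger of the two per-axis angular deviations between consecutive
#' sign-aligned estimates; 180 degrees when no previous estimate exists.
#' Consecutive agreement of randomly initialized estimates is evidence
#' that the solver keeps finding the same (global) minimum.
#'
#' @param current a list with unit axes `j1`, `j2`.
#' @param previous the previous aligned estimate or `NULL`.
#' @return degrees in `[0, 180]`.
#' @export
seqad <- function(current, previous = NULL) {
  if (is.null(previous)) return(180)
  max(angular_deviation(current$j1, previous$j1),
      angular_deviation(current$j2, previous$j2))
}

#' Streaming calibration with acceptance testing
#'
#' The full plug-and-play loop: the recording is consumed in cumulative
#' batches of `batch_seconds`; each batch updates the sample selection,
#' re-estimates the axes from a fresh area-uniform random initialization,
#' sign-aligns the estimate with its predecessor, and computes the local
#' uncertainty metric \eqn{\mu_z + 2\sigma_z} (per axis, Monte-Carlo) and
#' the sequential angular deviation.  The estimate is accepted -- and the
#' loop stops -- as soon as both axes' local metrics are below `e_max` and
#' the last `n_min` sequential deviations are all below `e_max`.  A
#' non-finite local metric (non-identifiable data) simply fails the local
#' criterion.
#'
#' @param recording a recording tibble.
#' @param sel_cfg a [selection_config()]; `NULL` disables sample selection
#'   (all observed samples are used).
#' @param est_cfg an [estimator_config()].
#' @param unc_cfg an [uncertainty_config()].
#' @param batch_seconds batch granularity in seconds.
#' @param seed optional integer seed covering the whole run (random starts
#'   and Monte-Carlo draws).
#' @return an object of class `hinge_calibration`: `accepted`, the aligned
#'   axes `j1`, `j2` (of the accepted or last estimate), `t_accept`
#'   (`NA` if the stream was exhausted), a per-batch `history` tibble and
#'   the configuration echoes.
#' @export
run_acceptance <- function(recording, sel_cfg = selection_config(),
                           est_cfg = estimator_config(),
                           unc_cfg = uncertainty_config(),
                           batch_seconds = 1, seed = NULL) {
  body <- function() {
    assert_recording(recording)
    t_rel <- recording$t - recording$t[1L]
    t_total <- t_rel[length(t_rel)]
    ends <- seq(batch_seconds, t_total + batch_seconds, by = batch_seconds)
    state <- selection_state()
    prev <- NULL
    seqads <- numeric(0)
    hist <- list()
    accepted <- FALSE
    j_out <- NULL
    t_accept <- NA_real_
    for (te in ends) {
      m <- sum(t_rel < te)
      if (m < 2L) next
      cum <- recording[seq_len(m), ]
      if (!is.null(sel_cfg)) {
        state <- update_selection(state, cum, sel_cfg)
        gi <- state$gyro_retained
        ai <- state$accel_retained
      } else {
        gi <- seq_len(m)
        ai <- seq_len(m)
      }
      if (length(gi) + length(ai) == 0L) next
      d <- hinge_data(cum, gi, ai)
      fit <- estimate_joint_axis(d, random_start(), est_cfg)
      aligned <- sign_consistent(list(j1 = fit$j1_hat, j2 = fit$j2_hat), prev)
      sq <- seqad(aligned, prev)
      prev <- aligned
      seqads <- c(seqads, sq)
      Px <- local_covariance(d, fit$x_hat, est_cfg$w0)
      mc <- monte_carlo_ad(fit$x_hat, Px, unc_cfg$mc_samples)
      local_metric <- mc$mu + 2 * mc$sigma
      local_ok <- all(is.finite(local_metric)) &&
        all(local_metric < unc_cfg$e_max)
      global_ok <- length(seqads) >= unc_cfg$n_min &&
        all(tail(seqads, unc_cfg$n_min) < unc_cfg$e_max)
      hist[[length(hist) + 1L]] <- tibble::tibble(
        t = te, cost = fit$final_cost,
        local1 = local_metric[1L], local2 = local_metric[2L],
        seqad = sq, n_gyro = length(gi), n_accel = length(ai),
        pairing_ambiguous = fit$pairing_ambiguous,
        local_ok = local_ok, global_ok = global_ok
      )
      j_out <- aligned
      if (local_ok && global_ok) {
        accepted <- TRUE
        t_accept <- te
        break
      }
    }
    structure(list(
      accepted = accepted,
      j1 = j_out$j1, j2 = j_out$j2, t_accept = t_accept,
      history = dplyr::bind_rows(hist),
      sel_cfg = sel_cfg, est_cfg = est_cfg, unc_cfg = unc_cfg,
      batch_seconds = batch_seconds, seed = seed,
      selection = if (is.null(sel_cfg)) NULL else state
    ), class = "hinge_calibration")
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' @export
print.hinge_calibration <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("Calibration accepted at t = %g s\n", x$t_accept))
    cat(sprintf("  j1 = (%.4f, %.4f, %.4f)\n", x$j1[1L], x$j1[2L], x$j1[3L]))
    cat(sprintf("  j2 = (%.4f, %.4f, %.4f)\n", x$j2[1L], x$j2[2L], x$j2[3L]))
  } else {
    cat("Stream exhausted without an acceptable estimate\n")
  }
  cat(sprintf("  %d batches processed\n", nrow(x$history)))
  invisible(x)
}

#' @rdname run_acceptance
#' @param x a `hinge_calibration`.
#' @param ... unused.
#' @return `tidy()`: the per-batch history tibble; `glance()`: a one-row
#'   summary.
#' @method tidy hinge_calibration
#' @export
tidy.hinge_calibration <- function(x, ...) x$history

#' @rdname run_acceptance
#' @method glance hinge_calibration
#' @export
glance.hinge_calibration <- function(x, ...) {
  tibble::tibble(
    accepted = x$accepted,
    t_accept = x$t_accept,
    batches = nrow(x$history),
    final_seqad = if (nrow(x$history)) tail(x$history$seqad, 1L) else NA_real_
  )
}
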