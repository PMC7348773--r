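#' Residual weights from the gyro/accelerometer weight ratio
#'
#' A single dimensionless ratio `w0` controls the relative weighting of the
#' two constraint residuals: the gyroscope residual is scaled by
#' \eqn{w_\omega = \sqrt{w_0}} and the accelerometer residual by
#' \eqn{w_a = 1/\sqrt{w_0}}, so that \eqn{w_0 = w_\omega / w_a}.  The default
#' `w0 = 50` reflects that angular rates (rad/s) are numerically smaller than
#' accelerations (around 9.82 m/s^2) and that the angular-velocity constraint
#' holds exactly for a rigid hinge while the acceleration constraint is only
#' approximate.
#'
#' @param w0 strictly positive weight ratio.
#' @return a list with components `w_omega` and `w_a`.
#' @export
hinge_weights <- function(w0 = 50) {
  stopifnot(is.numeric(w0), length(w0) == 1L, is.finite(w0), w0 > 0)
  list(w0 = w0, w_omega = sqrt(w0), w_a = 1 / sqrt(w0))
}

#' Rigid-body rotational acceleration operator
#'
#' The 3x3 matrix \eqn{K(\omega, \dot\omega)} such that
#' \eqn{K(\omega,\dot\omega)\, r = \omega \times (\omega \times r) +
#' \dot\omega \times r}: the centripetal plus tangential acceleration of a
#' point at constant body-frame offset `r` from the rotation centre.
#'
#' @param omega angular velocity, rad/s 3-vector.
#' @param omega_dot angular acceleration, rad/s^2 3-vector.
#' @return a 3x3 numeric matrix; symmetric when `omega_dot` is zero.
#' @export
rotation_operator <- function(omega, omega_dot = c(0, 0, 0)) {
  wx <- omega[1L]; wy <- omega[2L]; wz <- omega[3L]
  dx <- omega_dot[1L]; dy <- omega_dot[2L]; dz <- omega_dot[3L]
  matrix(c(
    -wy^2 - wz^2, wx * wy - dz, wx * wz + dy,
    wx * wy + dz, -wx^2 - wz^2, wy * wz - dx,
    wx * wz - dy, wy * wz + dx, -wx^2 - wy^2
  ), nrow = 3L, byrow = TRUE)
}

# --- internal sample containers ---------------------------------------------

rec_channel_names <- c("g1x", "g1y", "g1z", "a1x", "a1y", "a1z",
                       "g2x", "g2y", "g2z", "a2x", "a2y", "a2z")

assert_recording <- function(recording) {
  miss <- setdiff(c("t", rec_channel_names), names(recording))
  if (length(miss) > 0L) {
    stop("recording is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(recording)
}

#' Assemble the sample set used by the estimator
#'
#' Splits a recording into the gyroscope and accelerometer sample subsets the
#' cost function sums over.  By default every sample contributes to both
#' channels; after sample selection the two channels typically retain
#' different subsets.
#'
#' @param recording a tibble with columns `t`, `g1x..g1z`, `a1x..a1z`,
#'   `g2x..g2z`, `a2x..a2z` (SI units: s, rad/s, m/s^2).
#' @param gyro_idx,accel_idx integer row indices of the samples each channel
#'   retains; `NULL` keeps all rows.
#' @return an object of class `hinge_data` holding the per-channel
#'   measurement matrices.
#' @export
hinge_data <- function(recording, gyro_idx = NULL, accel_idx = NULL) {
  if (inherits(recording, "hinge_data")) return(recording)
  assert_recording(recording)
  m <- as.matrix(recording[, rec_channel_names])
  if (is.null(gyro_idx)) gyro_idx <- seq_len(nrow(m))
  if (is.null(accel_idx)) accel_idx <- seq_len(nrow(m))
  G1 <- m[gyro_idx, 1:3, drop = FALSE]
  G2 <- m[gyro_idx, 7:9, drop = FALSE]
  structure(list(
    G1 = G1, G2 = G2,
    A1 = m[accel_idx, 4:6, drop = FALSE],
    A2 = m[accel_idx, 10:12, drop = FALSE],
    gg1 = rowSums(G1 * G1), gg2 = rowSums(G2 * G2),
    n_gyro = length(gyro_idx), n_accel = length(accel_idx)
  ), class = "hinge_data")
}

# --- residuals, cost, Jacobian ----------------------------------------------

#' Hinge-joint constraint residuals
#'
#' For a candidate axis pair \eqn{x} the gyroscope residual of sample \eqn{k}
#' is \eqn{e_\omega = w_\omega\,(\lVert y_{\omega,1}\times j_1\rVert -
#' \lVert y_{\omega,2}\times j_2\rVert)} and the accelerometer residual is
#' \eqn{e_a = w_a\,(j_1^\top y_{a,1} - j_2^\top y_{a,2})}.  Both vanish at
#' the true axes for ideal hinge motion (the acceleration residual exactly so
#' only when the joint-centre offsets contribute nothing along the axis).
#'
#' @param data a recording tibble or a [hinge_data()] object.
#' @param x parameter vector `(theta1, phi1, theta2, phi2)`.
#' @param w0 residual weight ratio, see [hinge_weights()].
#' @return `joint_residuals()`: a list with numeric vectors `gyro` and
#'   `accel` and the stacked vector `e` (all gyro residuals first, then all
#'   accelerometer residuals).
#' @export
joint_residuals <- function(data, x, w0 = 50) {
  d <- hinge_data(data)
  w <- hinge_weights(w0)
  ax <- params_to_axes(x)
  # Lagrange identity: ||y x j||^2 = ||y||^2 - (y.j)^2 for unit j
  p1 <- drop(d$G1 %*% ax$j1)
  p2 <- drop(d$G2 %*% ax$j2)
  eg <- w$w_omega * (sqrt(pmax(d$gg1 - p1 * p1, 0)) -
                     sqrt(pmax(d$gg2 - p2 * p2, 0)))
  ea <- w$w_a * (drop(d$A1 %*% ax$j1) - drop(d$A2 %*% ax$j2))
  list(gyro = eg, accel = ea, e = c(eg, ea))
}

#' @rdname joint_residuals
#' @return `joint_cost()`: the scalar sum of squared residuals over both
#'   channels (non-negative; 0 for an empty sample set).
#' @export
joint_cost <- function(data, x, w0 = 50) {
  r <- joint_residuals(data, x, w0)
  sum(r$e^2)
}

# derivative of j(theta, phi) wrt (theta, phi): 3 x 2 matrix
d_axis_d_angles <- function(theta, phi) {
  cbind(c(-sin(theta) * cos(phi), -sin(theta) * sin(phi), cos(theta)),
        c(-cos(theta) * sin(phi), cos(theta) * cos(phi), 0))
}

#' @rdname joint_residuals
#' @details `joint_jacobian()` returns the analytic Jacobian of the stacked
#'   residual vector with respect to `x`: a `(n_gyro + n_accel) x 4` matrix,
#'   gyro rows first, columns ordered `(theta1, phi1, theta2, phi2)`.  At
#'   samples where \eqn{\lVert y_{\omega,i}\times j_i\rVert = 0} the norm is
#'   not differentiable; that sensor's contribution to the row is set to 0
#'   (a valid subgradient, and the choice that avoids NaN propagation on
#'   stationary samples).
#' @return `joint_jacobian()`: a list with the Jacobian matrix `J` and the
#'   stacked residual vector `e`.
#' @export
joint_jacobian <- function(data, x, w0 = 50) {
  d <- hinge_data(data)
  w <- hinge_weights(w0)
  ax <- params_to_axes(x)
  D1 <- d_axis_d_angles(x[[1L]], x[[2L]])
  D2 <- d_axis_d_angles(x[[3L]], x[[4L]])

  # gyro rows: d||y x j||/dj = ((y x j) x y) / ||y x j||, 0 where the norm
  # is 0; the numerator expands to j ||y||^2 - y (y.j)
  p1 <- drop(d$G1 %*% ax$j1)
  p2 <- drop(d$G2 %*% ax$j2)
  n1 <- sqrt(pmax(d$gg1 - p1 * p1, 0))
  n2 <- sqrt(pmax(d$gg2 - p2 * p2, 0))
  eg <- w$w_omega * (n1 - n2)
  inv1 <- ifelse(n1 > 0, 1 / n1, 0)
  inv2 <- ifelse(n2 > 0, 1 / n2, 0)
  g1 <- (tcrossprod(d$gg1, ax$j1) - d$G1 * p1) * inv1
  g2 <- (tcrossprod(d$gg2, ax$j2) - d$G2 * p2) * inv2
  Jg <- cbind(w$w_omega * (g1 %*% D1), -w$w_omega * (g2 %*% D2))

  # accelerometer rows
  ea <- w$w_a * (drop(d$A1 %*% ax$j1) - drop(d$A2 %*% ax$j2))
  Ja <- cbind(w$w_a * (d$A1 %*% D1), -w$w_a * (d$A2 %*% D2))

  J <- rbind(Jg, Ja)
  colnames(J) <- names(axis_params())
  list(J = J, e = c(eg, ea))
}
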