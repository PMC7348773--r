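#' Spherical parametrization of a unit joint axis
#'
#' The joint axis in each sensor frame is a unit vector encoded by two
#' spherical angles, \eqn{j(\theta,\phi) = (\cos\theta\cos\phi,
#' \cos\theta\sin\phi, \sin\theta)}.  A full calibration parameter vector
#' stacks both axes: \eqn{x = (\theta_1, \phi_1, \theta_2, \phi_2)}.
#'
#' @param theta,phi elevation and azimuth angles in radians; vectorized.
#' @return `spherical_to_axis()`: a numeric matrix with one row per input
#'   angle pair and columns `x`, `y`, `z` (a plain named vector when a single
#'   pair is given).  Rows always have unit Euclidean norm.
#' @examples
#' spherical_to_axis(0, pi / 2)     # the y axis
#' axis_to_spherical(c(0, 0, 1))    # the pole: theta = pi/2, phi = 0
#' @export
spherical_to_axis <- function(theta, phi) {
  out <- cbind(x = cos(theta) * cos(phi),
               y = cos(theta) * sin(phi),
               z = sin(theta))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' @rdname spherical_to_axis
#' @param j a unit 3-vector (or 3-column matrix of unit rows).
#' @details `axis_to_spherical()` inverts the map with the conventions
#'   \eqn{\theta \in [-\pi/2, \pi/2]}, \eqn{\phi \in (-\pi, \pi]}, and
#'   \eqn{\phi = 0} at the poles (where \eqn{\cos\theta < 10^{-12}} the
#'   azimuth is undefined).
#' @return `axis_to_spherical()`: a numeric vector `c(theta, phi)` (or a
#'   two-column matrix for matrix input).
#' @export
axis_to_spherical <- function(j) {
  j <- rbind(j)
  theta <- asin(pmin(1, pmax(-1, j[, 3L])))
  phi <- atan2(j[, 2L], j[, 1L])
  phi[cos(theta) < 1e-12] <- 0
  out <- cbind(theta = theta, phi = phi)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Build and inspect calibration parameter vectors
#'
#' `axis_params()` assembles the 4-parameter vector from the two spherical
#' angle pairs (or from two unit axes); `params_to_axes()` maps a parameter
#' vector to the two unit axes.
#'
#' @param theta1,phi1,theta2,phi2 spherical angles in radians.
#' @return `axis_params()`: a named numeric vector of length 4.
#' @export
axis_params <- function(theta1 = 0, phi1 = 0, theta2 = 0, phi2 = 0) {
  c(theta1 = unname(theta1), phi1 = unname(phi1),
    theta2 = unname(theta2), phi2 = unname(phi2))
}

#' @rdname axis_params
#' @param j1,j2 unit 3-vectors; alternative construction of the parameters.
#' @export
axes_to_params <- function(j1, j2) {
  a1 <- axis_to_spherical(j1)
  a2 <- axis_to_spherical(j2)
  axis_params(a1[["theta"]], a1[["phi"]], a2[["theta"]], a2[["phi"]])
}

#' @rdname axis_params
#' @param x a parameter vector `(theta1, phi1, theta2, phi2)`.
#' @return `params_to_axes()`: a list with unit vectors `j1` and `j2`.
#' @export
params_to_axes <- function(x) {
  list(j1 = spherical_to_axis(x[[1L]], x[[2L]]),
       j2 = spherical_to_axis(x[[3L]], x[[4L]]))
}

#' @rdname axis_params
#' @details `flip_pairing()` maps \eqn{(\theta_1, \phi_1, \theta_2, \phi_2)}
#'   to \eqn{(\theta_1, \phi_1, -\theta_2, \phi_2 + \pi)}, which negates
#'   \eqn{j_2} while leaving \eqn{j_1} unchanged -- the reinitialization used
#'   to probe the opposite sign pairing.
#' @export
flip_pairing <- function(x) {
  axis_params(x[[1L]], x[[2L]], -x[[3L]], wrap_pi(x[[4L]] + pi))
}

# wrap angle(s) to (-pi, pi]
wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' @rdname axis_params
#' @details `normalize_params()` wraps \eqn{\theta} into
#'   \eqn{[-\pi/2,\pi/2]} (with the compensating \eqn{\phi} shift) and
#'   \eqn{\phi} into \eqn{(-\pi,\pi]}.  The wrap only affects reporting; the
#'   cost is \eqn{2\pi}-periodic in all four angles.
#' @export
normalize_params <- function(x) {
  fix1 <- function(theta, phi) {
    theta <- wrap_pi(theta)
    if (theta > pi / 2) {
      theta <- pi - theta
      phi <- phi + pi
    } else if (theta < -pi / 2) {
      theta <- -pi - theta
      phi <- phi + pi
    }
    c(theta, wrap_pi(phi))
  }
  a <- fix1(x[[1L]], x[[2L]])
  b <- fix1(x[[3L]], x[[4L]])
  axis_params(a[1L], a[2L], b[1L], b[2L])
}

# row-wise cross product of an n x 3 matrix with a fixed 3-vector (m x v),
# or of two n x 3 matrices
cross_rows <- function(m, v) {
  if (is.matrix(v)) {
    cbind(m[, 2L] * v[, 3L] - m[, 3L] * v[, 2L],
          m[, 3L] * v[, 1L] - m[, 1L] * v[, 3L],
          m[, 1L] * v[, 2L] - m[, 2L] * v[, 1L])
  } else {
    cbind(m[, 2L] * v[3L] - m[, 3L] * v[2L],
          m[, 3L] * v[1L] - m[, 1L] * v[3L],
          m[, 1L] * v[2L] - m[, 2L] * v[1L])
  }
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

row_norms <- function(m) sqrt(rowSums(m * m))
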