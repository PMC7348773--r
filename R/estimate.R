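#' Estimator configuration
#'
#' Tuning parameters of the Gauss--Newton solver for the joint-axis
#' least-squares problem.
#'
#' @param w0 residual weight ratio, see [hinge_weights()].
#' @param v_tol stopping tolerance on the absolute change of the cost
#'   between accepted iterations.
#' @param max_iters iteration cap per Gauss--Newton run (safety net; the
#'   primary stopping rule is `v_tol`).
#' @param beta backtracking shrink factor for the line search, in (0,1).
#' @param c_armijo Armijo sufficient-decrease constant, in (0,1).
#' @param min_alpha smallest step length tried before the line search is
#'   declared failed.
#' @return a list of class `estimator_config`.
#' @export
estimator_config <- function(w0 = 50, v_tol = 1e-10, max_iters = 200,
                             beta = 0.5, c_armijo = 1e-4,
                             min_alpha = 1e-8) {
  stopifnot(w0 > 0, v_tol > 0, max_iters >= 1,
            beta > 0, beta < 1, c_armijo > 0, c_armijo < 1, min_alpha > 0)
  structure(list(w0 = w0, v_tol = v_tol, max_iters = max_iters,
                 beta = beta, c_armijo = c_armijo, min_alpha = min_alpha),
            class = "estimator_config")
}

#' Gauss--Newton solver for the joint-axis cost
#'
#' Minimizes the sum of squared hinge-constraint residuals over the
#' 4-parameter spherical encoding of the two axes.  The normal equations are
#' solved with a small Tikhonov damping (1e-12 times the mean diagonal of
#' \eqn{J^\top J}) so that non-informative data, where \eqn{J^\top J} is
#' singular along the unidentifiable directions, degrades gracefully instead
#' of failing.  Step lengths come from Armijo backtracking, so the cost
#' sequence is non-increasing; iteration stops when the cost change drops
#' below `v_tol`, the line search fails, or `max_iters` is reached.
#'
#' @param data a recording tibble or [hinge_data()] object (non-empty).
#' @param x0 initial parameter vector `(theta1, phi1, theta2, phi2)`.
#' @param cfg an [estimator_config()].
#' @return a list: `x` (solution), `cost`, `iterations`, `converged`
#'   (`TRUE` when stopped by the `v_tol` rule), `cost_path`.
#' @export
gauss_newton <- function(data, x0, cfg = estimator_config()) {
  d <- hinge_data(data)
  if (d$n_gyro + d$n_accel == 0L) stop("empty sample set", call. = FALSE)
  x <- axis_params(x0[[1L]], x0[[2L]], x0[[3L]], x0[[4L]])
  V <- joint_cost(d, x, cfg$w0)
  if (!is.finite(V)) stop("non-finite residuals: corrupt input", call. = FALSE)
  path <- V
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iters)) {
    jj <- joint_jacobian(d, x, cfg$w0)
    JtJ <- crossprod(jj$J)
    g <- drop(crossprod(jj$J, jj$e))          # = grad(V)/2
    damp <- 1e-12 * sum(diag(JtJ)) / 4
    step <- tryCatch(solve(JtJ + diag(damp, 4L), g), error = function(e) NULL)
    if (is.null(step)) {                       # pseudo-inverse fallback
      sv <- svd(JtJ + diag(damp, 4L))
      pos <- sv$d > max(sv$d) * 1e-14
      step <- drop(sv$v[, pos, drop = FALSE] %*%
                     (crossprod(sv$u[, pos, drop = FALSE], g) / sv$d[pos]))
    }
    # Armijo backtracking along the descent direction -step
    slope <- -2 * sum(g * step)                # directional derivative of V
    alpha <- 1
    accepted <- FALSE
    while (alpha >= cfg$min_alpha) {
      x_new <- x - alpha * step
      V_new <- joint_cost(d, x_new, cfg$w0)
      if (is.finite(V_new) && V_new <= V + cfg$c_armijo * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * cfg$beta
    }
    if (!accepted) break                       # line search failed
    iters <- it
    dV <- V - V_new
    x <- axis_params(x_new[[1L]], x_new[[2L]], x_new[[3L]], x_new[[4L]])
    V <- V_new
    path <- c(path, V)
    if (abs(dV) < cfg$v_tol) {
      converged <- TRUE
      break
    }
  }
  list(x = x, cost = V, iterations = iters, converged = converged,
       cost_path = path)
}

#' Estimate the hinge-joint axis pair
#'
#' Runs Gauss--Newton from `x0`, then reinitializes at the opposite sign
#' pairing (\eqn{j_2 \to -j_2}, via [flip_pairing()]) and runs again; the
#' candidate with the smaller cost is returned.  This resolves the sign
#' pairing: \eqn{(+j_1,+j_2)} and \eqn{(-j_1,-j_2)} describe the same
#' physical axis while \eqn{(\pm j_1, \mp j_2)} reverses one sensor's
#' rotation sense.  When the two candidate costs are numerically
#' indistinguishable (within `1e-12 * max(1, V)`) the first candidate is
#' returned and `pairing_ambiguous` is set -- the pairing cannot be decided
#' from such data.
#'
#' @param data a recording tibble or [hinge_data()] object.
#' @param x0 initial parameter vector; defaults to the axis pair
#'   \eqn{j_1 = j_2 = (1,0,0)}.
#' @param cfg an [estimator_config()].
#' @return an object of class `axis_fit`: fields `x_hat`, `j1_hat`,
#'   `j2_hat`, `final_cost`, `iterations`, `converged`, `candidate_costs`
#'   (both local minima), `pairing_ambiguous`, `w0`.
#' @export
estimate_joint_axis <- function(data, x0 = axis_params(),
                                cfg = estimator_config()) {
  d <- hinge_data(data)
  r1 <- gauss_newton(d, x0, cfg)
  r2 <- gauss_newton(d, flip_pairing(r1$x), cfg)
  tie <- abs(r1$cost - r2$cost) < 1e-12 * max(1, r1$cost, r2$cost)
  best <- if (!tie && r2$cost < r1$cost) r2 else r1
  x_hat <- normalize_params(best$x)
  ax <- params_to_axes(x_hat)
  structure(list(
    x_hat = x_hat, j1_hat = ax$j1, j2_hat = ax$j2,
    final_cost = best$cost,
    iterations = c(r1$iterations, r2$iterations),
    converged = c(r1$converged, r2$converged),
    candidate_costs = c(r1$cost, r2$cost),
    pairing_ambiguous = tie,
    w0 = cfg$w0
  ), class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat("Hinge-joint axis estimate\n")
  cat(sprintf("  j1 = (%.4f, %.4f, %.4f)\n", x$j1_hat[1L], x$j1_hat[2L],
              x$j1_hat[3L]))
  cat(sprintf("  j2 = (%.4f, %.4f, %.4f)\n", x$j2_hat[1L], x$j2_hat[2L],
              x$j2_hat[3L]))
  cat(sprintf("  cost %.4g after %d+%d Gauss-Newton iterations (w0 = %g)\n",
              x$final_cost, x$iterations[1L], x$iterations[2L], x$w0))
  if (x$pairing_ambiguous) {
    cat("  note: sign pairing ambiguous (candidate costs numerically equal)\n")
  }
  invisible(x)
}

#' @rdname estimate_joint_axis
#' @param x an `axis_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per sensor with the axis components and
#'   spherical angles; `glance()`: a one-row tibble of fit diagnostics.
#' @method tidy axis_fit
#' @export
tidy.axis_fit <- function(x, ...) {
  fit <- x
  tibble::tibble(
    sensor = c(1L, 2L),
    x = c(fit$j1_hat[[1L]], fit$j2_hat[[1L]]),
    y = c(fit$j1_hat[[2L]], fit$j2_hat[[2L]]),
    z = c(fit$j1_hat[[3L]], fit$j2_hat[[3L]]),
    theta = c(fit$x_hat[[1L]], fit$x_hat[[3L]]),
    phi = c(fit$x_hat[[2L]], fit$x_hat[[4L]])
  )
}

#' @rdname estimate_joint_axis
#' @method glance axis_fit
#' @export
glance.axis_fit <- function(x, ...) {
  tibble::tibble(
    final_cost = x$final_cost,
    iterations = sum(x$iterations),
    converged = all(x$converged),
    pairing_ambiguous = x$pairing_ambiguous,
    w0 = x$w0
  )
}

#' Deterministic and random initializations
#'
#' `grid_initializations()` returns the 36 parameter vectors formed by all
#' pairs of the six axis-aligned unit vectors (\eqn{\pm e_x, \pm e_y,
#' \pm e_z}) for \eqn{j_1} and \eqn{j_2}; every sign pairing is represented
#' equally often.  `random_start()` draws an area-uniform random axis pair
#' (uniform on the unit sphere for each axis, via \eqn{\sin\theta \sim
#' U(-1,1)}, \eqn{\phi \sim U(-\pi,\pi]}).
#'
#' @return `grid_initializations()`: a 36-row tibble with columns
#'   `theta1, phi1, theta2, phi2`.
#' @export
grid_initializations <- function() {
  units <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- expand.grid(i = 1:6, j = 1:6)
  purrr::map2_dfr(idx$i, idx$j, function(i, j) {
    p <- axes_to_params(units[i, ], units[j, ])
    tibble::as_tibble(as.list(p))
  })
}

#' @rdname grid_initializations
#' @return `random_start()`: a parameter vector drawn from the current RNG
#'   stream.
#' @export
random_start <- function() {
  axis_params(asin(runif(1, -1, 1)), runif(1, -pi, pi),
              asin(runif(1, -1, 1)), runif(1, -pi, pi))
}
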