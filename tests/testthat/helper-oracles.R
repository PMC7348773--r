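# Independent oracles and small fixture builders shared across tests.

# central finite differences of the stacked residual vector; the oracle for
# the analytic Jacobian
fd_jacobian <- function(data, x, w0, h = 1e-6) {
  e0 <- hingecal::joint_residuals(data, x, w0)$e
  J <- matrix(0, length(e0), 4L)
  for (i in 1:4) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    J[, i] <- (hingecal::joint_residuals(data, xp, w0)$e -
                 hingecal::joint_residuals(data, xm, w0)$e) / (2 * h)
  }
  J
}

# a recording tibble of pure i.i.d. noise channels (no physics), for
# exercising the algebra on arbitrary inputs
random_recording <- function(n, accel_scale = 3) {
  tibble::tibble(
    t = (seq_len(n) - 1) / 50,
    g1x = rnorm(n), g1y = rnorm(n), g1z = rnorm(n),
    a1x = rnorm(n, 0, accel_scale), a1y = rnorm(n, 0, accel_scale),
    a1z = rnorm(n, 0, accel_scale),
    g2x = rnorm(n), g2y = rnorm(n), g2z = rnorm(n),
    a2x = rnorm(n, 0, accel_scale), a2y = rnorm(n, 0, accel_scale),
    a2z = rnorm(n, 0, accel_scale)
  )
}

# a recording with explicit channel matrices (rows = samples)
recording_from_channels <- function(g1, a1, g2, a2) {
  n <- nrow(g1)
  tibble::tibble(
    t = (seq_len(n) - 1) / 50,
    g1x = g1[, 1], g1y = g1[, 2], g1z = g1[, 3],
    a1x = a1[, 1], a1y = a1[, 2], a1z = a1[, 3],
    g2x = g2[, 1], g2y = g2[, 2], g2z = g2[, 3],
    a2x = a2[, 1], a2y = a2[, 2], a2z = a2[, 3]
  )
}

# concatenate motion presets into one stream with continuous time and fresh
# noise per piece
make_stream <- function(motions, durations, cfg = hingecal::sim_config(),
                        seed0 = 100) {
  pieces <- purrr::map2(motions, seq_along(motions), function(m, i) {
    ci <- cfg
    ci$seed <- seed0 + i
    hingecal::simulate_motion(m, ci, durations[[min(i, length(durations))]])
  })
  out <- dplyr::bind_rows(pieces)
  out$t <- (seq_len(nrow(out)) - 1) / cfg$sample_rate
  out
}

# wrap a calibration's axes so the error metrics accept them
as_fit <- function(j1, j2) {
  structure(list(j1_hat = j1, j2_hat = j2), class = "axis_fit")
}
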