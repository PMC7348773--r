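test_that("spherical parametrization maps angles to unit axes", {
  expect_equal(unname(spherical_to_axis(0, 0)), c(1, 0, 0))
  expect_equal(unname(spherical_to_axis(pi / 2, 0)), c(0, 0, 1))
  expect_equal(unname(spherical_to_axis(0, pi / 2)), c(0, 1, 0))

  grid <- expand.grid(theta = seq(-pi, pi, length.out = 13),
                      phi = seq(-pi, pi, length.out = 13))
  j <- spherical_to_axis(grid$theta, grid$phi)
  expect_true(all(abs(rowSums(j * j) - 1) < 1e-12))
})

test_that("axis_to_spherical inverts the map with pole conventions", {
  p <- axis_to_spherical(c(0, 0, 1))
  expect_equal(unname(p), c(pi / 2, 0))
  expect_equal(unname(axis_to_spherical(c(0, 1, 0))), c(0, pi / 2))

  withr::with_seed(42, {
    for (i in 1:100) {
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      p <- axis_to_spherical(v)
      expect_true(p[["theta"]] >= -pi / 2 && p[["theta"]] <= pi / 2)
      expect_true(p[["phi"]] > -pi && p[["phi"]] <= pi)
      expect_lt(max(abs(spherical_to_axis(p[["theta"]], p[["phi"]]) - v)),
                1e-9)
    }
  })
})

test_that("flip map negates j2 and leaves j1 unchanged", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- random_start()
      ax <- params_to_axes(x)
      axf <- params_to_axes(flip_pairing(x))
      expect_equal(axf$j1, ax$j1, tolerance = 1e-12)
      expect_equal(axf$j2, -ax$j2, tolerance = 1e-12)
    }
  })
})

test_that("rotation operator reproduces the double cross product", {
  expect_equal(rotation_operator(c(0, 0, 0), c(0, 0, 0)),
               matrix(0, 3, 3))
  expect_equal(rotation_operator(c(0, 0, 1), c(0, 0, 0)),
               diag(c(-1, -1, 0)))
  cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  withr::with_seed(8, {
    for (i in 1:25) {
      w <- rnorm(3); wd <- rnorm(3); r <- rnorm(3)
      oracle <- cross(w, cross(w, r)) + cross(wd, r)
      expect_equal(drop(rotation_operator(w, wd) %*% r), oracle,
                   tolerance = 1e-10)
    }
  })
  # omega_dot = 0 gives a symmetric (pure centripetal) matrix
  K <- rotation_operator(c(0.3, -1.2, 0.7))
  expect_equal(K, t(K))
})

test_that("constraint residuals vanish exactly where the hinge model says", {
  w1 <- hinge_weights(1)
  # identical gyro readings with identical axes
  rec <- recording_from_channels(
    g1 = rbind(c(1, 2, 3)), a1 = rbind(c(0, 9.82, 0)),
    g2 = rbind(c(1, 2, 3)), a2 = rbind(c(0, 9.82, 0)))
  x_same <- axes_to_params(c(0, 1, 0), c(0, 1, 0))
  r <- joint_residuals(rec, x_same, w0 = 1)
  expect_equal(r$gyro, 0, tolerance = 1e-12)
  expect_equal(r$accel, 0, tolerance = 1e-12)

  # unit gyro orthogonal to j1, sensor 2 silent: ||(1,0,0) x (0,1,0)|| = 1
  rec2 <- recording_from_channels(
    g1 = rbind(c(1, 0, 0)), a1 = rbind(c(0, 0, 0)),
    g2 = rbind(c(0, 0, 0)), a2 = rbind(c(0, 0, 0)))
  r2 <- joint_residuals(rec2, axes_to_params(c(0, 1, 0), c(0, 0, 1)), w0 = 1)
  expect_equal(r2$gyro, 1, tolerance = 1e-12)

  # accelerometer example: projections agree for axis-matched readings
  rec3 <- recording_from_channels(
    g1 = rbind(c(0, 0, 0)), a1 = rbind(c(0, 9.82, 0)),
    g2 = rbind(c(0, 0, 0)), a2 = rbind(c(9.82, 0, 0)))
  r3 <- joint_residuals(rec3, axes_to_params(c(0, 1, 0), c(1, 0, 0)), w0 = 1)
  expect_equal(r3$accel, 0, tolerance = 1e-12)

  # stiff-joint pair: gyro2 = R gyro1 with transported axis j2 = R j1 gives a
  # zero gyro residual for any j1
  withr::with_seed(9, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- hingecal:::rot_about(ax, 1.1)
    for (i in 1:10) {
      g1 <- matrix(rnorm(15), 5, 3)
      j1 <- rnorm(3); j1 <- j1 / sqrt(sum(j1^2))
      rec4 <- recording_from_channels(
        g1 = g1, a1 = matrix(0, 5, 3),
        g2 = g1 %*% t(R), a2 = matrix(0, 5, 3))
      r4 <- joint_residuals(rec4, axes_to_params(j1, drop(R %*% j1)), w0 = 1)
      expect_lt(max(abs(r4$gyro)), 1e-10)
    }
  })
})

test_that("cost is the sum of squared residuals and is pairing-symmetric", {
  empty <- random_recording(0)
  expect_equal(joint_cost(empty, axis_params()), 0)

  withr::with_seed(10, {
    rec <- random_recording(30)
    x <- random_start()
    r <- joint_residuals(rec, x, 50)
    expect_equal(joint_cost(rec, x, 50), sum(r$e^2), tolerance = 1e-12)

    # (-j1, -j2) image: theta -> -theta, phi -> phi + pi for both axes
    x_neg <- axis_params(-x[1], x[2] + pi, -x[3], x[4] + pi)
    expect_equal(joint_cost(rec, x_neg, 50), joint_cost(rec, x, 50),
                 tolerance = 1e-10)
  })
})

test_that("analytic Jacobian agrees with central finite differences", {
  withr::with_seed(11, {
    for (i in 1:10) {
      rec <- random_recording(12)
      x <- random_start()
      jj <- joint_jacobian(rec, x, 50)
      expect_lt(max(abs(jj$J - fd_jacobian(rec, x, 50))), 1e-6)
    }
  })
})

test_that("degenerate Jacobian rows are zeroed, not NaN", {
  # zero gyro readings on both sensors: the gyro row is identically zero
  rec <- recording_from_channels(
    g1 = rbind(c(0, 0, 0)), a1 = rbind(c(1, 2, 3)),
    g2 = rbind(c(0, 0, 0)), a2 = rbind(c(3, 2, 1)))
  jj <- joint_jacobian(rec, random_start(), 50)
  expect_equal(unname(jj$J[1, ]), rep(0, 4))
  expect_true(all(is.finite(jj$J)))

  # zero accel channels zero the accel rows
  rec2 <- recording_from_channels(
    g1 = rbind(c(1, 0.5, 0)), a1 = rbind(c(0, 0, 0)),
    g2 = rbind(c(0, 1, 0.2)), a2 = rbind(c(0, 0, 0)))
  jj2 <- joint_jacobian(rec2, random_start(), 50)
  expect_equal(unname(jj2$J[2, ]), rep(0, 4))
})

test_that("weight convention splits w0 between the two channels", {
  w <- hinge_weights(50)
  expect_equal(w$w_omega, sqrt(50))
  expect_equal(w$w_a, 1 / sqrt(50))
  expect_equal(w$w_omega / w$w_a, 50)
  expect_error(hinge_weights(-1))
})
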