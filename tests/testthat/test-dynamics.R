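params_med <- system_params(pendulum_length = 0.6)

test_that("solved-form accelerations match hand-derived cases", {
  # equilibrium
  expect_equal(
    unname(accelerations(c(x = 0, v = 0, theta = 0, omega = 0),
                         params_med, 0)),
    c(0, 0))
  # force on the cup with the ball hanging: denominator is the cup mass
  a <- accelerations(c(x = 0, v = 0, theta = 0, omega = 0), params_med, 3)
  expect_equal(unname(a[1]), 3 / 2.4, tolerance = 1e-12)
  expect_equal(unname(a[2]), -(3 / 2.4) / 0.6, tolerance = 1e-12)
  # horizontal ball: gravity coupling vanishes, pure pendulum fall
  a90 <- accelerations(c(x = 0, v = 0, theta = pi / 2, omega = 0),
                       params_med, 0)
  expect_equal(unname(a90[1]), 0, tolerance = 1e-12)
  expect_equal(unname(a90[2]), -9.81 / 0.6, tolerance = 1e-12)
})

test_that("accelerations satisfy the implicit equations of motion", {
  for (st in random_states(25)) {
    f <- runif(1, -10, 10)
    a <- accelerations(st, params_med, f)
    mc <- params_med$cup_mass; mb <- params_med$ball_mass
    l <- params_med$pendulum_length; g <- params_med$gravity
    th <- st[["theta"]]; om <- st[["omega"]]
    # cart equation: (mc+mb) xdd = mb l (om^2 sin - thdd cos) + F
    res1 <- (mc + mb) * a[["cup_acc"]] -
      (mb * l * (om^2 * sin(th) - a[["ball_acc"]] * cos(th)) + f)
    # ball equation: thdd = -xdd cos/l - g sin/l
    res2 <- a[["ball_acc"]] -
      (-a[["cup_acc"]] * cos(th) / l - g * sin(th) / l)
    expect_lt(abs(res1), 1e-10)
    expect_lt(abs(res2), 1e-12)
  }
})

test_that("accelerations are odd under state and force negation", {
  for (st in random_states(10, seed = 2)) {
    f <- runif(1, -10, 10)
    a <- accelerations(st, params_med, f)
    an <- accelerations(-st, params_med, -f)
    expect_equal(unname(an), -unname(a), tolerance = 1e-12)
  }
  expect_error(accelerations(c(x = NaN, v = 0, theta = 0, omega = 0),
                             params_med, 0),
               class = "cupball_invalid_input")
})

test_that("impedance force restores toward the desired trajectory", {
  ctrl <- controller_spec(stiffness = 40, damping = 70, amplitude = 0.3,
                          frequency = 0.5)
  d <- desired_trajectory(0.37, ctrl)
  # on the desired trajectory the force vanishes
  expect_equal(impedance_force(c(x = d$x_d, v = d$v_d), ctrl, 0.37), 0)
  # 0.1 m displacement at K = 40 -> 4 N restoring
  expect_equal(impedance_force(c(x = d$x_d - 0.1, v = d$v_d), ctrl, 0.37),
               4)
  # pure damping: 0.2 m/s velocity lag at B = 70 -> 14 N
  ctrl0 <- controller_spec(stiffness = 0, damping = 70, amplitude = 0.3,
                           frequency = 0.5)
  expect_equal(impedance_force(c(x = 0.2, v = d$v_d - 0.2), ctrl0, 0.37),
               14)
})

test_that("rk4_step fixes the equilibrium and converges at 4th order", {
  st <- c(x = 0, v = 0, theta = 0, omega = 0)
  out <- rk4_step(st, params_med, function(y, t) 0, 0, 0.01)
  expect_equal(unname(out), unname(st))

  # halving dt shrinks the one-period error ~16x (order 4)
  ctrl0 <- controller_spec(stiffness = 0, damping = 0, amplitude = 0,
                           frequency = 0.5)
  period <- 2 * pi * sqrt(0.6 / 9.81) * sqrt(2.4 / 3.0)
  final_angle <- function(dt_div) {
    s <- simulate_trial(params_med, ctrl0, 20, 0, duration = period,
                        dt = period / dt_div)
    utils::tail(s$ball_angle_deg, 1)
  }
  ref <- final_angle(6400)
  e1 <- abs(final_angle(64) - ref)
  e2 <- abs(final_angle(128) - ref)
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 40)
})

test_that("small-angle period matches the coupled linearization", {
  # cart recoil shortens the period by sqrt(mc / (mc + mb))
  ctrl0 <- controller_spec(stiffness = 0, damping = 0, amplitude = 0,
                           frequency = 0.5)
  s <- simulate_trial(params_med, ctrl0, 2, 0, duration = 10, dt = 0.001)
  th <- s$ball_angle_deg
  crossings <- which(diff(sign(th)) != 0)
  measured <- 2 * mean(diff(s$time_s[crossings]))
  predicted <- 2 * pi * sqrt(0.6 / 9.81) * sqrt(2.4 / (2.4 + 0.6))
  expect_equal(measured, predicted, tolerance = 1e-3)
})

test_that("simulate_trial stays at rest without excitation and matches an
           independent stiff integrator", {
  ctrl0 <- controller_spec(stiffness = 40, damping = 70, amplitude = 0,
                           frequency = 0.5)
  s <- simulate_trial(params_med, ctrl0, 0, 0, duration = 2)
  expect_lt(max(abs(s$cup_pos_m)), 1e-12)
  expect_lt(max(abs(s$ball_angle_deg)), 1e-12)

  skip_if_not_installed("deSolve")
  ctrl <- controller_spec(frequency = 0.5)
  rhs <- function(t, y, p) {
    fap <- impedance_force(c(x = y[1], v = y[2]), ctrl, t)
    a <- accelerations(c(x = y[1], v = y[2], theta = y[3], omega = y[4]),
                       params_med, fap)
    list(c(y[2], a[[1]], y[4], a[[2]]))
  }
  out <- deSolve::ode(c(-0.3, 0, -25 * pi / 180, -4 * pi / 180),
                      seq(0, 5, 0.01), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  sim <- simulate_trial(params_med, ctrl, -25, duration = 5)
  expect_lt(max(abs(out[, 2] - sim$cup_pos_m)), 1e-5)
  expect_lt(max(abs(out[, 4] * 180 / pi - sim$ball_angle_deg)), 1e-3)
})

test_that("unforced mechanical energy is conserved over 15 s", {
  ctrl0 <- controller_spec(stiffness = 0, damping = 0, amplitude = 0,
                           frequency = 0.5)
  s <- simulate_trial(params_med, ctrl0, 40, 10, duration = 15, dt = 0.01)
  e <- mechanical_energy(s)
  expect_lt(max(abs(e - e[1])) / e[1], 1e-3)
})

test_that("non-finite states raise a divergence error naming the step", {
  expect_error(
    simulate_trial(params_med, controller_spec(frequency = 0.5), 10,
                   duration = 1, extra_force = rep(1e308, 100)),
    class = "cupball_divergence")
})
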