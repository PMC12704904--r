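t15 <- seq(0, 14 - 0.01, by = 0.01)  # 7 full cycles at 0.5 Hz

test_that("instantaneous phase of a cosine has the analytic slope", {
  ph <- instantaneous_phase(cos(2 * pi * 0.5 * t15), 0.01)
  i <- 200:1300  # interior, away from transform edge effects
  slope <- stats::coef(stats::lm(ph$phase_rad[i] ~ ph$time_s[i]))[2]
  expect_equal(unname(slope), 2 * pi * 0.5, tolerance = 0.01)

  # quadrature pair: sin lags cos by pi/2
  ps <- instantaneous_phase(sin(2 * pi * 0.5 * t15), 0.01)
  offs <- ph$phase_rad[i] - ps$phase_rad[i]
  expect_lt(max(abs(offs - pi / 2)), 0.02)

  expect_error(instantaneous_phase(rep(0, 100), 0.01),
               class = "cupball_degenerate_signal")
})

test_that("relative phase distinguishes in-phase and anti-phase signals", {
  x <- cos(2 * pi * 0.5 * t15)
  i <- 200:1300
  same <- relative_phase(x, x, 0.01)$rel_phase_rad
  expect_lt(max(abs(same[i])), 1e-6)
  anti <- relative_phase(x, -x, 0.01)$rel_phase_rad
  expect_lt(max(abs(abs(anti[i]) - pi)), 0.02)
  expect_error(relative_phase(x, x[-1], 0.01),
               class = "cupball_invalid_input")
})

test_that("circular variance closed forms and invariances hold", {
  expect_equal(circular_variance(rep(0.7, 50)), 0)
  for (n in c(2, 3, 8)) {
    expect_equal(circular_variance(2 * pi * (0:(n - 1)) / n), 1,
                 tolerance = 1e-12)
  }
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  set.seed(4)
  ang <- runif(40, -pi, pi)
  cv <- circular_variance(ang)
  expect_equal(circular_variance(ang + 1.3), cv, tolerance = 1e-12)
  expect_equal(circular_variance(sample(ang)), cv, tolerance = 1e-12)
  expect_true(cv >= 0 && cv <= 1)
  expect_error(circular_variance(numeric(0)),
               class = "cupball_invalid_input")
})

test_that("instantaneous frequency tracks constant and chirped rhythms", {
  fr <- instantaneous_frequency(cos(2 * pi * 0.5 * t15), 0.01)
  i <- 200:1300
  expect_lt(max(abs(fr$freq_hz[i] - 0.5)), 0.005)

  # linear chirp 0.3 -> 0.7 Hz: interior estimate increases monotonically
  f_inst <- 0.3 + (0.7 - 0.3) * t15 / 15
  chirp <- cos(2 * pi * cumsum(f_inst) * 0.01)
  fc <- instantaneous_frequency(chirp, 0.01)$freq_hz[i]
  fit <- stats::coef(stats::lm(fc ~ seq_along(fc)))[2]
  expect_gt(unname(fit), 0)
  expect_equal(stats::cor(fc, seq_along(fc)), 1, tolerance = 0.05)
})

test_that("mean absolute force matches closed forms", {
  expect_equal(mean_absolute_force(rep(2, 100)), 2)
  expect_equal(mean_absolute_force(rep(0, 100)), 0)
  tt <- seq(0, 4 - 1e-3, by = 1e-3)  # integer cycles at 1 Hz
  expect_equal(mean_absolute_force(5 * sin(2 * pi * tt)), 10 / pi,
               tolerance = 1e-4)
})

test_that("log dimensionless jerk: closed form, scaling and reversal", {
  f <- 0.5; dur <- 14
  tt <- seq(0, dur, by = 0.002)
  force <- sin(2 * pi * f * tt)
  ldj <- log_dimensionless_jerk(force, 0.002)
  expect_equal(ldj, -log(dur^4 * (2 * pi * f)^4 / 2), tolerance = 0.01)
  expect_equal(log_dimensionless_jerk(3.7 * force, 0.002), ldj,
               tolerance = 1e-9)
  expect_equal(log_dimensionless_jerk(rev(force), 0.002), ldj,
               tolerance = 1e-9)
  # high-frequency noise makes the force less smooth (lower value)
  set.seed(1)
  noisy <- force + rnorm(length(force), 0, 0.05)
  expect_lt(log_dimensionless_jerk(noisy, 0.002), ldj)
  expect_error(log_dimensionless_jerk(rep(0, 100), 0.01),
               class = "cupball_invalid_input")
})

test_that("escape risk boundary cases follow the energy margin", {
  p <- system_params(pendulum_length = 0.6)
  n <- 501
  # ball resting at the bottom: margin is the full escape energy
  expect_equal(risk_of_escape(rep(0, n), rep(0, n), p, 0.01)$risk, 0)
  # ball resting at the rim: zero margin throughout
  expect_equal(risk_of_escape(rep(60, n), rep(0, n), p, 0.01)$risk, 1,
               tolerance = 1e-12)
  # half the escape energy -> risk 1/2 (potential-only construction)
  th_half <- acos(1 - 0.5 * (1 - cos(pi / 3))) * 180 / pi
  expect_equal(risk_of_escape(rep(th_half, n), rep(0, n), p, 0.01)$risk,
               0.5, tolerance = 1e-12)
  # time reversal leaves the integral unchanged
  set.seed(2)
  th <- 30 * sin(seq(0, 6 * pi, length.out = n))
  om <- 20 * cos(seq(0, 6 * pi, length.out = n))
  expect_equal(risk_of_escape(rev(th), rev(om), p, 0.01)$risk,
               risk_of_escape(th, om, p, 0.01)$risk, tolerance = 1e-12)
})

test_that("steady-state cup frequency follows the controller rhythm", {
  traj <- reference_trial()
  fr <- instantaneous_frequency(traj$cup_pos_m, 0.01)
  i <- 300:1200
  expect_lt(abs(mean(fr$freq_hz[i]) - 0.5) / 0.5, 0.02)
})

test_that("relative phase shifts from in-phase to anti-phase across the
           pendulum resonance", {
  p <- system_params(pendulum_length = 0.6)
  rp_mean <- function(th0, f) {
    s <- simulate_trial(p, controller_spec(frequency = f), th0)
    rp <- relative_phase(s$cup_pos_m, s$ball_angle_deg, 0.01)$rel_phase_rad
    abs(rad2deg(circular_mean(trim_series(rp, 0.01, f, 1))))
  }
  # the stable solutions mirror in theta0: in-phase below resonance
  # (~0.64 Hz for the medium pendulum), anti-phase above it
  expect_lt(rp_mean(-20, 0.40), 45)
  expect_gt(rp_mean(60, 0.75), 135)
})

test_that("stage parsing finds the last velocity zero before box entry", {
  # synthetic trajectory: rest, jiggle, then a rightward transport
  dt <- 1 / 120
  t1 <- seq(0, 3, by = dt)
  x1 <- -0.15 + 0.02 * sin(2 * pi * 1 * t1) * sin(pi * t1 / 3)^2
  v1 <- c(0, diff(x1)) / dt
  t2 <- seq(dt, 5, by = dt)
  x2 <- -0.15 + 0.3 * sin(2 * pi * 0.25 * t2 / 2)^2
  v2 <- c(diff(c(x1[length(x1)], x2))) / dt
  traj <- tibble::tibble(time_s = c(t1, 3 + t2), cup_pos_m = c(x1, x2),
                         cup_vel_m_s = c(v1, v2))
  b <- parse_stages(traj)
  expect_equal(b, length(t1), tolerance = 2)

  # monotone motion with no zero crossing errors out
  mono <- tibble::tibble(time_s = t1, cup_pos_m = seq(0.2, 0.5,
                                                      length.out = length(t1)),
                         cup_vel_m_s = rep(0.5, length(t1)))
  expect_error(parse_stages(mono), class = "cupball_boundary_not_found")
  # never entering the box region errors out
  left <- tibble::tibble(time_s = t1, cup_pos_m = rep(-0.15, length(t1)),
                         cup_vel_m_s = rep(0, length(t1)))
  expect_error(parse_stages(left), class = "cupball_boundary_not_found")
})

test_that("time to stable phase honors its conventions", {
  rec <- generate_trial(participant_model(), "blocked", 0.6,
                        tibble::tibble(theta0_deg = -30, freq_hz = 0.5),
                        seed = 9)
  traj <- rec$trajectory
  b <- rec$true_boundary_index
  # threshold 1 can never be exceeded: stable from trial start, flagged
  t1 <- time_to_stable_phase(traj, threshold = 1, boundary_index = b)
  expect_equal(as.numeric(t1), 0)
  expect_true(attr(t1, "stable_from_start"))
  # preparation shorter than the window is undefined
  tu <- time_to_stable_phase(traj, boundary_index = 10L)
  expect_true(is.na(tu) && isTRUE(attr(tu, "undefined")))
  # noisy-then-locked preparation: stabilization near mid-preparation
  ts <- as.numeric(time_to_stable_phase(traj, boundary_index = b))
  d <- rec$true_prep_duration
  expect_gt(ts, 0.2 * d)
  expect_lt(ts, 0.65 * d)
})

test_that("preparation duration reads the stage boundary", {
  rec <- generate_trial(participant_model(), "blocked", 0.6,
                        tibble::tibble(theta0_deg = -30, freq_hz = 0.5),
                        seed = 10)
  traj <- rec$trajectory
  expect_equal(preparation_duration(traj, rec$true_boundary_index),
               rec$true_prep_duration, tolerance = 1 / 120 + 1e-9)
  expect_equal(preparation_duration(traj, 1L), 0)
  expect_equal(preparation_duration(traj, nrow(traj)),
               max(traj$time_s))
})
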