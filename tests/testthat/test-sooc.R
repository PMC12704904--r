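cfg_blocked <- sooc_config(pendulum_uncertainty("blocked"),
                           frequency = 0.5, theta_star_deg = -25)

test_that("pendulum-length uncertainty encodes the protocol statistics", {
  mom <- pendulum_length_moments()
  expect_equal(mom$mean, 0.7)
  expect_equal(mom$sd, sqrt(0.14), tolerance = 1e-12)
  u <- pendulum_uncertainty("random")
  expect_equal(u$l_mean, 0.7)
  expect_equal(u$sigma_l, sqrt(0.14))
  # stationary-variance relation sigma_ou^2 = 2 alpha sigma_l^2
  expect_equal(u$sigma_ou^2, 2 * u$alpha * u$sigma_l^2)
  b <- pendulum_uncertainty("blocked", blocked_length = 1.2)
  expect_equal(b$l_mean, 1.2)
  expect_equal(b$sigma_l, 0.1)
})

test_that("drift matches hand-derived cases", {
  cfg <- cfg_blocked
  # controller at rest on its preparation set point: nothing moves
  m_eq <- c(-cfg$amplitude, 0, 0, 0, cfg$uncertainty$l_mean, 0, 25, 0, 0)
  expect_equal(sooc_drift(m_eq, c(0, 0), 1, cfg), rep(0, 9))
  # OU reversion on the length state
  m_l <- m_eq; m_l[5] <- cfg$uncertainty$l_mean + 0.2
  expect_equal(sooc_drift(m_l, c(0, 0), 1, cfg)[5], -100 * 0.2)
  # feedforward force through the cart inertia (K = 0)
  m_f <- m_eq; m_f[6] <- 3; m_f[7] <- 0
  expect_equal(sooc_drift(m_f, c(0, 0), 1, cfg)[2], 3 / 2.4)
  # pseudo-controls drive the double-integrator chains
  d <- sooc_drift(m_eq, c(1.5, -2.5), 1, cfg)
  expect_equal(d[8], -2.5)  # ddF_ff
  expect_equal(d[9], 1.5)   # ddK
})

test_that("analytic Jacobian agrees with finite differences", {
  cfg <- cfg_blocked
  J <- sooc_jacobian(c(-0.1, 0.05, -0.3, 0.2, 0.65, 1, 25, 0.5, 2), 3, cfg)
  # integrator-chain rows are exact 0/1 patterns
  expect_equal(J[1, ], c(0, 1, rep(0, 7)))
  expect_equal(J[3, ], c(0, 0, 0, 1, rep(0, 5)))
  expect_equal(J[6, ], c(rep(0, 7), 1, 0))
  expect_equal(J[7, ], c(rep(0, 8), 1))
  expect_equal(J[5, 5], -100)
  set.seed(11)
  for (i in 1:5) {
    m <- c(runif(1, -0.3, 0.3), runif(1, -1, 1), runif(1, -1, 1),
           runif(1, -2, 2), runif(1, 0.4, 1), runif(1, -5, 5),
           runif(1, 0, 80), runif(1, -5, 5), runif(1, -20, 20))
    Ja <- sooc_jacobian(m, 2.5, cfg)
    Jf <- sooc_jacobian(m, 2.5, cfg, method = "fd")
    expect_lt(max(abs(Ja - Jf) / (abs(Ja) + 1)), 1e-5)
  }
})

test_that("mean-covariance dynamics: no noise, no growth; OU block is
           stationary at sigma_l^2", {
  quiet <- sooc_config(pendulum_uncertainty("blocked", sigma_blocked = 0),
                       frequency = 0.5, theta_star_deg = -25)
  rhs <- sooc_mean_cov_rhs(c(-0.15, 0, 0, 0, 0.6, 0, 10, 0, 0),
                           matrix(0, 9, 9), c(0, 0), 1, quiet)
  expect_equal(rhs$dP, matrix(0, 9, 9))

  # propagated P_ll stays at the stationary value
  cfg <- cfg_blocked
  t_grid <- seq(0, 2, by = cfg$dt)
  U <- matrix(0, 2, length(t_grid))
  m0 <- c(-cfg$amplitude, 0, 0, 0, cfg$uncertainty$l_mean, 0, 40, 0, 0)
  P0 <- matrix(0, 9, 9); P0[5, 5] <- cfg$uncertainty$sigma_l^2
  r <- sooc_propagate_cpp(U, m0, P0, cupball:::cfg_to_cpp(cfg), cfg$dt,
                          0L, TRUE, TRUE)
  expect_equal(r$P_diag[5, ], rep(cfg$uncertainty$sigma_l^2,
                                  ncol(r$P_diag)), tolerance = 1e-10)
})

test_that("simulated OU ensemble matches its closed-form moments", {
  u <- pendulum_uncertainty("blocked", blocked_length = 0.6)
  set.seed(12)
  n <- 600; dt <- 5e-4; nst <- 1000
  l <- rep(1.0, n)  # start displaced to watch the mean revert
  for (i in seq_len(nst)) {
    l <- l + dt * (-u$alpha * (l - u$l_mean)) +
      u$sigma_ou * sqrt(dt) * rnorm(n)
  }
  # mean reverts exponentially at rate alpha: after 0.5 s it is fully back
  expect_equal(mean(l), u$l_mean, tolerance = 0.02)
  # stationary variance sigma_ou^2 / (2 alpha), within sampling error
  expect_lt(abs(stats::var(l) - u$sigma_l^2) / u$sigma_l^2, 0.15)
})

test_that("stage and point costs follow the quadratic structure", {
  cfg <- cfg_blocked
  d <- cupball:::sooc_desired(3, cfg)
  m_on <- c(d$x_d, d$v_d, 0, 0, cfg$uncertainty$l_mean, 0, 20, 0, 0)
  P0 <- matrix(0, 9, 9)
  expect_equal(sooc_stage_cost(m_on, P0, c(0, 0), 3, cfg), 0)

  # doubling R doubles the control term exactly
  u <- c(3, -4)
  c1 <- sooc_stage_cost(m_on, P0, u, 3, cfg)
  cfg2 <- cfg; cfg2$weights$r <- 2 * cfg$weights$r
  expect_equal(sooc_stage_cost(m_on, P0, u, 3, cfg2), 2 * c1)

  # adding variance in a weighted coordinate raises cost by the trace term
  P1 <- P0; P1[1, 1] <- 0.01
  expect_equal(sooc_stage_cost(m_on, P1, c(0, 0), 3, cfg),
               cfg$weights$qvx * 0.01)

  # end-of-preparation point cost vanishes on the target state
  m_star <- c(-cfg$amplitude, 0, deg2rad(-25), 0, cfg$uncertainty$l_mean,
              0, 20, 0, 0)
  expect_equal(sooc_point_cost(m_star, P0, cfg, "prep_end"), 0)
  expect_gt(sooc_point_cost(m_on, P0, cfg, "prep_end"), 0)
})

test_that("covariance stays symmetric with nonnegative spectrum and the
           transcription is refinement-stable", {
  cfg <- cfg_blocked
  t_grid <- seq(0, 8, by = cfg$dt)
  t_nodes <- seq(0, 8, by = cfg$control_dt)
  U <- cupball:::interp_controls(cupball:::sooc_guess(cfg, t_nodes),
                                 t_nodes, t_grid)
  m0 <- cupball:::sooc_initial_state(cfg)
  P0 <- cupball:::sooc_initial_cov(cfg)
  r <- sooc_propagate_cpp(U, m0, P0, cupball:::cfg_to_cpp(cfg), cfg$dt,
                          0L, TRUE, TRUE)
  Pf <- r$P_f
  expect_equal(Pf, t(Pf), tolerance = 1e-12)
  expect_gt(min(eigen(Pf, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)

  # halving the integration step changes the cost by < 2 %
  cfg_h <- cfg; cfg_h$dt <- cfg$dt / 2
  t_grid_h <- seq(0, 8, by = cfg_h$dt)
  U_h <- cupball:::interp_controls(cupball:::sooc_guess(cfg, t_nodes),
                                   t_nodes, t_grid_h)
  r_h <- sooc_propagate_cpp(U_h, m0, P0, cupball:::cfg_to_cpp(cfg_h),
                            cfg_h$dt, 0L, FALSE, FALSE)
  expect_lt(abs(r_h$cost - r$cost) / r$cost, 0.02)
})

test_that("a quick optimization reaches the target state with rising,
           nonnegative stiffness", {
  cfg <- sooc_config(pendulum_uncertainty("blocked"), frequency = 0.5,
                     theta_star_deg = -25, control_dt = 0.5)
  fit <- sooc_optimize(cfg, maxit = 60)
  s <- tidy(fit)
  prep <- s[s$stage == "preparation", ]
  expect_equal(utils::tail(prep$theta_deg, 1), -25, tolerance = 3)
  expect_equal(utils::tail(prep$x, 1), -0.15, tolerance = 0.02)
  expect_gt(utils::tail(prep$k, 1), s$k[1])
  expect_gt(min(s$k), -2)  # nonnegativity up to the soft-penalty slack
  g <- glance(fit)
  expect_true(is.finite(g$cost))
})

test_that("the solver sweep emits landscape-compatible stiffness maps", {
  cfg <- sooc_config(pendulum_uncertainty("blocked"), frequency = 0.5,
                     theta_star_deg = -25, control_dt = 0.5)
  maps <- sweep_sooc(cfg, theta_range = c(-40, -10),
                     freq_range = c(0.4, 0.6), n_theta = 2, n_freq = 2,
                     maxit = 25)
  expect_s3_class(maps, "strategy_maps")
  expect_equal(nrow(maps), 4)
  expect_gte(mean(maps$converged), 0.75)
  sm <- as_strategy_map(maps, "sooc_stiffness")
  expect_true(all(is.finite(sm$value[maps$converged])))
})
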