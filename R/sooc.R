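#' Pendulum-length uncertainty specification
#'
#' Trial-to-trial uncertainty about the pendulum length is modeled as an
#' Ornstein-Uhlenbeck (OU) process on the length state,
#' `dl = -alpha (l - l_mean) dt + sigma_ou dW`, whose stationary variance
#' is `sigma_l^2 = sigma_ou^2 / (2 alpha)`. In the random protocol the
#' length is drawn from the discrete set of experimental lengths with equal
#' probability, giving `l_mean = 0.7` m and `sigma_l = 0.37` m; in the
#' blocked protocol the mean is the block's length with a smaller
#' `sigma_l = 0.1` m.
#'
#' @param protocol `"random"` or `"blocked"`.
#' @param blocked_length Pendulum length of the block (m), used when
#'   `protocol = "blocked"`.
#' @param pendulum_lengths The discrete experimental lengths (m).
#' @param sigma_blocked Length SD in the blocked protocol (m).
#' @param reversion_rate OU reversion rate alpha in 1/s (default 100).
#' @return An object of class `uncertainty_spec` with fields `l_mean`,
#'   `sigma_l`, `alpha`, `sigma_ou`, `protocol`.
#' @export
#' @examples
#' pendulum_uncertainty("random")   # l_mean 0.7, sigma_l ~ 0.374
pendulum_uncertainty <- function(protocol = c("random", "blocked"),
                                 blocked_length = 0.6,
                                 pendulum_lengths = c(0.3, 0.6, 1.2),
                                 sigma_blocked = 0.1,
                                 reversion_rate = 100) {
  protocol <- match.arg(protocol)
  mom <- pendulum_length_moments(pendulum_lengths)
  if (protocol == "random") {
    l_mean <- mom$mean
    sigma_l <- mom$sd
  } else {
    l_mean <- blocked_length
    sigma_l <- sigma_blocked
  }
  structure(list(l_mean = l_mean, sigma_l = sigma_l,
                 alpha = reversion_rate,
                 sigma_ou = sqrt(2 * reversion_rate * sigma_l^2),
                 protocol = protocol),
            class = "uncertainty_spec")
}

#' Moments of the discrete pendulum-length distribution
#'
#' Mean and population standard deviation of the equiprobable discrete
#' length set used in the random protocol.
#'
#' @param lengths Pendulum lengths in m.
#' @return A list with `mean` and `sd` (m).
#' @export
pendulum_length_moments <- function(lengths = c(0.3, 0.6, 1.2)) {
  m <- mean(lengths)
  list(mean = m, sd = sqrt(mean((lengths - m)^2)))
}

#' Configuration of the stochastic open-loop optimal control problem
#'
#' Assembles the plant, uncertainty, task timing and cost weights for
#' [sooc_optimize()]. The controller is
#' `F_applied = K (xd - x) + kb K (vd - v) + F_ff` with stiffness `K` and
#' feedforward force `F_ff` evolving as double integrators driven by the
#' pseudo-controls (their second derivatives). The cost penalizes cup
#' tracking error and cup state variance during the rhythmic stage, the
#' end-of-preparation state (soft constraint on x, v, theta, omega), and
#' pseudo-control effort; preparation-stage states are otherwise free.
#'
#' @param uncertainty An [pendulum_uncertainty()] spec.
#' @param frequency Desired cup frequency f in Hz.
#' @param theta_star_deg Target initial ball angle at the end of
#'   preparation, degrees.
#' @param params A [system_params()] (its `pendulum_length` is replaced by
#'   the uncertainty mean).
#' @param kb Viscosity/stiffness ratio (default 0.2).
#' @param amplitude Desired cup amplitude A in m (default 0.15, the box
#'   spacing).
#' @param t_prep,t_rhythmic Stage durations in s (defaults 2 and 6).
#' @param dt Integration step in s (default 0.05).
#' @param control_dt Spacing of the pseudo-control nodes in s (default
#'   0.25); controls are linearly interpolated between nodes.
#' @param k0 Initial stiffness state K(0) in N/m (default 10).
#' @param weights Named list overriding any default cost weight: `qx`,
#'   `qv` (rhythmic tracking), `qvx`, `qvv` (rhythmic variance), `r`
#'   (pseudo-control effort), `qk` (co-contraction effort, a small
#'   quadratic cost on the stiffness level that keeps the optimal
#'   stiffness finite), `wp_x`, `wp_v`, `wp_th`, `wp_om`
#'   (end-of-preparation state), `wpv_x`, `wpv_v` (end-of-preparation
#'   variance), `wf_x`, `wf_v`, `wfv_x`, `wfv_v` (terminal), `kneg`
#'   (negative-stiffness penalty).
#' @param cov_method Covariance integration scheme. The OU reversion makes
#'   the covariance dynamics stiff (`alpha * dt` >> 1 at the default
#'   step), so the default `"exact"` uses the per-step Van Loan discrete
#'   propagation of the frozen linearization, which is unconditionally
#'   stable; `"rk4"` and `"euler"` are plain explicit schemes that require
#'   `alpha * dt` small (use them only with a fine `dt`).
#' @return An object of class `sooc_config`.
#' @export
sooc_config <- function(uncertainty = pendulum_uncertainty("blocked"),
                        frequency = 0.5, theta_star_deg = -25,
                        params = system_params(), kb = 0.2,
                        amplitude = 0.15, t_prep = 2, t_rhythmic = 6,
                        dt = 0.05, control_dt = 0.25, k0 = 10,
                        weights = list(),
                        cov_method = c("exact", "rk4", "euler")) {
  cov_method <- match.arg(cov_method)
  w <- list(qx = 2000, qv = 500, qvx = 40000, qvv = 10000, r = 1e-4,
            qk = 1e-4,
            wp_x = 1e4, wp_v = 1e3, wp_th = 1e4, wp_om = 1e3,
            wpv_x = 1e4, wpv_v = 1e3,
            wf_x = 100, wf_v = 25, wfv_x = 100, wfv_v = 25,
            kneg = 1e4)
  bad <- setdiff(names(weights), names(w))
  if (length(bad) > 0) {
    abort(paste0("unknown weight(s): ", paste(bad, collapse = ", ")),
          class = "cupball_invalid_input")
  }
  w[names(weights)] <- weights
  if (any(unlist(w) < 0) || w$r <= 0) {
    abort("weights must be nonnegative and `r` positive",
          class = "cupball_invalid_input")
  }
  if (t_prep < 0 || t_rhythmic <= 0 || dt <= 0 || control_dt < dt) {
    abort("invalid timing configuration", class = "cupball_invalid_input")
  }
  params$pendulum_length <- uncertainty$l_mean
  structure(list(uncertainty = uncertainty, params = params,
                 frequency = frequency,
                 theta_star_deg = theta_star_deg, kb = kb,
                 amplitude = amplitude, t_prep = t_prep,
                 t_rhythmic = t_rhythmic, dt = dt, control_dt = control_dt,
                 k0 = k0, weights = w, cov_method = cov_method),
            class = "sooc_config")
}

cfg_to_cpp <- function(cfg) {
  c(list(mc = cfg$params$cup_mass, mb = cfg$params$ball_mass,
         g = cfg$params$gravity, kb = cfg$kb,
         lmean = cfg$uncertainty$l_mean, alpha = cfg$uncertainty$alpha,
         sigma_ou = cfg$uncertainty$sigma_ou, A = cfg$amplitude,
         f = cfg$frequency, t_prep = cfg$t_prep,
         theta_star = deg2rad(cfg$theta_star_deg)),
    cfg$weights)
}

sooc_initial_state <- function(cfg) {
  c(x = -cfg$amplitude, v = 0, theta = 0, omega = 0,
    l = cfg$uncertainty$l_mean, f_ff = 0, k = cfg$k0, df_ff = 0, dk = 0)
}

sooc_initial_cov <- function(cfg) {
  P0 <- matrix(0, 9, 9)
  P0[5, 5] <- cfg$uncertainty$sigma_l^2  # length starts at its stationary spread
  P0
}

#' Drift of the augmented SOOC state
#'
#' Deterministic part of the 9-dimensional augmented dynamics
#' (x, v, theta, omega, l, F_ff, K, dF_ff, dK) under pseudo-controls
#' `u = (ddK, ddF_ff)`.
#'
#' @param m Augmented state (length 9).
#' @param u Pseudo-control vector (length 2).
#' @param t Time in s.
#' @param cfg A [sooc_config()].
#' @return Length-9 derivative vector.
#' @export
sooc_drift <- function(m, u, t, cfg) {
  as.numeric(sooc_drift_cpp(as.numeric(m), as.numeric(u), t,
                            cfg_to_cpp(cfg)))
}

#' State Jacobian of the SOOC drift
#'
#' @inheritParams sooc_drift
#' @param method `"analytic"` (closed form) or `"fd"` (central finite
#'   differences, used as a self-consistency oracle).
#' @param h Finite-difference step.
#' @return 9 x 9 Jacobian matrix.
#' @export
sooc_jacobian <- function(m, t, cfg, method = c("analytic", "fd"),
                          u = c(0, 0), h = 1e-6) {
  method <- match.arg(method)
  if (method == "analytic") {
    return(sooc_jacobian_cpp(as.numeric(m), t, cfg_to_cpp(cfg)))
  }
  m <- as.numeric(m)
  J <- matrix(0, 9, 9)
  for (j in 1:9) {
    mp <- m; mm <- m
    mp[j] <- mp[j] + h
    mm[j] <- mm[j] - h
    J[, j] <- (sooc_drift(mp, u, t, cfg) - sooc_drift(mm, u, t, cfg)) /
      (2 * h)
  }
  J
}

#' Mean and covariance dynamics of the SOOC state
#'
#' First-order (linearized) propagation: `dm/dt = f(m, u, t)` and
#' `dP/dt = F P + P F' + G G'` with `F` the state Jacobian of the drift at
#' the mean and `G` the noise input vector (OU noise on the length state).
#'
#' @inheritParams sooc_drift
#' @param P 9 x 9 state covariance.
#' @return A list with `dm` (length 9) and `dP` (9 x 9).
#' @export
sooc_mean_cov_rhs <- function(m, P, u, t, cfg) {
  Fm <- sooc_jacobian(m, t, cfg)
  GG <- matrix(0, 9, 9)
  GG[5, 5] <- cfg$uncertainty$sigma_ou^2
  list(dm = sooc_drift(m, u, t, cfg), dP = Fm %*% P + P %*% t(Fm) + GG)
}

sooc_desired <- function(t, cfg) {
  w <- 2 * pi * cfg$frequency
  rhythmic <- t >= cfg$t_prep
  tt <- pmax(t - cfg$t_prep, 0)
  list(x_d = ifelse(rhythmic, -cfg$amplitude * cos(w * tt), -cfg$amplitude),
       v_d = ifelse(rhythmic, cfg$amplitude * w * sin(w * tt), 0))
}

#' Running (stage) cost of the SOOC problem
#'
#' `(m - Xd)' Qt (m - Xd) + Tr(Qv P) + u' R u` per unit time: quadratic cup
#' tracking and cup-state variance during the rhythmic stage plus
#' pseudo-control effort (always active).
#'
#' @inheritParams sooc_mean_cov_rhs
#' @return Scalar cost rate (1/s).
#' @export
sooc_stage_cost <- function(m, P, u, t, cfg) {
  w <- cfg$weights
  d <- sooc_desired(t, cfg)
  track <- 0
  if (t >= cfg$t_prep) {
    track <- w$qx * (m[1] - d$x_d)^2 + w$qv * (m[2] - d$v_d)^2 +
      w$qvx * P[1, 1] + w$qvv * P[2, 2]
  }
  track + w$r * sum(u^2) + w$kneg * min(m[7], 0)^2
}

#' End-of-preparation and terminal point costs of the SOOC problem
#'
#' The end-of-preparation cost softly constrains the cup to the left box
#' (`x = -A`, `v = 0`) and the ball to the target initial angle
#' (`theta = theta*`, `omega = 0`), plus cup-state variance; the terminal
#' cost penalizes tracking error and variance at the final time.
#'
#' @inheritParams sooc_mean_cov_rhs
#' @param which `"prep_end"` or `"terminal"`.
#' @return Scalar cost.
#' @export
sooc_point_cost <- function(m, P, cfg, which = c("prep_end", "terminal")) {
  which <- match.arg(which)
  w <- cfg$weights
  if (which == "prep_end") {
    w$wp_x * (m[1] + cfg$amplitude)^2 + w$wp_v * m[2]^2 +
      w$wp_th * (m[3] - deg2rad(cfg$theta_star_deg))^2 +
      w$wp_om * m[4]^2 + w$wpv_x * P[1, 1] + w$wpv_v * P[2, 2]
  } else {
    d <- sooc_desired(cfg$t_prep + cfg$t_rhythmic, cfg)
    w$wf_x * (m[1] - d$x_d)^2 + w$wf_v * (m[2] - d$v_d)^2 +
      w$wfv_x * P[1, 1] + w$wfv_v * P[2, 2]
  }
}

# Interpolate coarse control nodes onto the integration grid (2 x (n+1)).
interp_controls <- function(u_nodes, t_nodes, t_grid) {
  rbind(approx(t_nodes, u_nodes[1, ], t_grid, rule = 2)$y,
        approx(t_nodes, u_nodes[2, ], t_grid, rule = 2)$y)
}

sooc_guess <- function(cfg, t_nodes) {
  # ddK = 0 everywhere; ddF_ff from forward-simulating the plain impedance
  # controller with a small gain K = 10 over the rhythmic stage.
  guess <- matrix(0, 2, length(t_nodes))
  ctrl <- controller_spec(stiffness = cfg$k0, damping = cfg$kb * cfg$k0,
                          amplitude = cfg$amplitude,
                          frequency = cfg$frequency)
  sim <- tryCatch(
    simulate_trial(cfg$params, ctrl, cfg$theta_star_deg,
                   duration = cfg$t_rhythmic, dt = cfg$dt),
    cupball_divergence = function(e) NULL)
  if (!is.null(sim)) {
    f <- sim$applied_force_N
    n <- length(f)
    fdd <- numeric(n)
    i <- 2:(n - 1)
    fdd[i] <- (f[i + 1] - 2 * f[i] + f[i - 1]) / cfg$dt^2
    in_rhythmic <- t_nodes >= cfg$t_prep
    guess[2, in_rhythmic] <- approx(sim$time_s + cfg$t_prep, fdd,
                                    t_nodes[in_rhythmic], rule = 2)$y
  }
  guess
}

#' Solve the stochastic open-loop optimal control problem
#'
#' Direct transcription: the pseudo-controls (second derivatives of
#' stiffness and feedforward force) are decision variables at coarse time
#' nodes, linearly interpolated onto the integration grid; the mean state
#' is propagated with RK4 and the covariance with the linearized
#' (Lyapunov) dynamics; the total cost is minimized with a quasi-Newton
#' bounded optimizer (L-BFGS-B) using finite-difference gradients.
#' Nonnegativity of stiffness is enforced through a quadratic penalty
#' (the `kneg` weight).
#'
#' @param cfg A [sooc_config()].
#' @param maxit Maximum optimizer iterations (default 200).
#' @param init Optional initial control-node matrix (2 x n_nodes).
#' @return An object of class `sooc_fit`: `config`, `states` (tibble of
#'   the mean trajectory and state SDs over time, plus the applied force
#'   along the mean), `controls`, `cost`, `cost_parts`, `convergence`.
#' @export
sooc_optimize <- function(cfg, maxit = 200, init = NULL) {
  t_total <- cfg$t_prep + cfg$t_rhythmic
  t_grid <- seq(0, t_total, by = cfg$dt)
  t_nodes <- seq(0, t_total, by = cfg$control_dt)
  if (t_nodes[length(t_nodes)] < t_total) t_nodes <- c(t_nodes, t_total)
  m0 <- sooc_initial_state(cfg)
  P0 <- sooc_initial_cov(cfg)
  ccfg <- cfg_to_cpp(cfg)
  cov_code <- match(cfg$cov_method, c("exact", "rk4", "euler")) - 1L

  nn <- length(t_nodes)
  obj <- function(par) {
    U <- interp_controls(matrix(par, 2, nn), t_nodes, t_grid)
    J <- sooc_propagate_cpp(U, m0, P0, ccfg, cfg$dt, cov_code, FALSE,
                            FALSE)$cost
    if (!is.finite(J)) 1e12 else J
  }
  grad <- function(par) {
    # forward differences: one objective call per decision variable
    f0 <- obj(par)
    h <- 1e-2
    vapply(seq_along(par), function(j) {
      pj <- par
      pj[j] <- pj[j] + h
      (obj(pj) - f0) / h
    }, numeric(1))
  }
  u_init <- init %||% sooc_guess(cfg, t_nodes)
  opt <- optim(as.numeric(u_init), obj, gr = grad, method = "L-BFGS-B",
               control = list(maxit = maxit))
  U_opt <- interp_controls(matrix(opt$par, 2, nn), t_nodes, t_grid)
  sol <- sooc_propagate_cpp(U_opt, m0, P0, ccfg, cfg$dt, cov_code, TRUE,
                            TRUE)
  M <- sol$M
  Pd <- pmax(sol$P_diag, 0)
  d <- sooc_desired(t_grid, cfg)
  f_applied <- M[7, ] * (d$x_d - M[1, ]) +
    cfg$kb * M[7, ] * (d$v_d - M[2, ]) + M[6, ]
  states <- tibble::tibble(
    time_s = t_grid, stage = ifelse(t_grid < cfg$t_prep, "preparation",
                                    "rhythmic"),
    x = M[1, ], v = M[2, ], theta_deg = rad2deg(M[3, ]),
    omega_deg_s = rad2deg(M[4, ]), l = M[5, ], f_ff = M[6, ], k = M[7, ],
    f_applied = f_applied,
    sd_x = sqrt(Pd[1, ]), sd_v = sqrt(Pd[2, ]),
    sd_theta_deg = rad2deg(sqrt(Pd[3, ])), sd_l = sqrt(Pd[5, ]))
  structure(list(config = cfg, states = states,
                 controls = tibble::tibble(time_s = t_grid,
                                           ddk = U_opt[1, ],
                                           ddf_ff = U_opt[2, ]),
                 cost = sol$cost, cost_parts = sol$parts,
                 P_f = sol$P_f,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    counts = opt$counts,
                                    converged = opt$convergence %in%
                                      c(0L, 1L))),
            class = "sooc_fit")
}

#' @export
print.sooc_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sooc_fit> %s protocol, theta* = %g deg, f = %g Hz\n  J = %.4g, mean rhythmic K = %.3g N/m, mean |F| = %.3g N, converged: %s\n",
    x$config$uncertainty$protocol, x$config$theta_star_deg,
    x$config$frequency, g$cost, g$mean_stiffness_rhythmic,
    g$mean_abs_force, g$converged))
  invisible(x)
}

#' @export
#' @method tidy sooc_fit
tidy.sooc_fit <- function(x, ...) {
  x$states
}

#' @export
#' @method glance sooc_fit
glance.sooc_fit <- function(x, ...) {
  s <- x$states
  rhy <- s[s$stage == "rhythmic", ]
  tibble::tibble(
    cost = x$cost,
    converged = x$convergence$converged,
    mean_stiffness_rhythmic = mean(rhy$k),
    mean_abs_force = mean(abs(s$f_applied)),
    mean_abs_f_ff = mean(abs(s$f_ff)),
    k_start = s$k[1],
    k_prep_end = s$k[which.min(abs(s$time_s - x$config$t_prep))],
    protocol = x$config$uncertainty$protocol,
    sigma_l = x$config$uncertainty$sigma_l,
    theta_star_deg = x$config$theta_star_deg,
    frequency = x$config$frequency)
}

#' @export
#' @method autoplot sooc_fit
autoplot.sooc_fit <- function(object, ...) {
  s <- object$states
  long <- tidyr::pivot_longer(
    s[c("time_s", "x", "theta_deg", "k", "f_applied")],
    -"time_s", names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal,
                        levels = c("x", "theta_deg", "k", "f_applied"),
                        labels = c("cup position (m)", "ball angle (deg)",
                                   "stiffness K (N/m)",
                                   "applied force (N)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$config$t_prep,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Sweep SOOC solutions over target angle and frequency
#'
#' Runs [sooc_optimize()] for each combination of desired initial ball
#' angle and cup frequency and maps the mean rhythmic-stage stiffness and
#' mean absolute feedforward force. Non-converged cells are flagged and
#' masked (NA).
#'
#' @param cfg A [sooc_config()] template (its `theta_star_deg` and
#'   `frequency` are overridden per cell).
#' @param theta_range Target-angle range in degrees (default c(-70, 70)).
#' @param freq_range Frequency range in Hz (default c(0.3, 0.8)).
#' @param n_theta,n_freq Grid resolution (default 8 x 6).
#' @param maxit Optimizer iterations per cell.
#' @return A tibble of class `strategy_maps` with `theta0_deg`, `freq_hz`,
#'   `sooc_stiffness`, `sooc_force`, `converged`.
#' @export
sweep_sooc <- function(cfg, theta_range = c(-70, 70),
                       freq_range = c(0.3, 0.8), n_theta = 8, n_freq = 6,
                       maxit = 100) {
  grid <- strategy_grid(theta_range, freq_range, n_theta, n_freq)
  cells <- grid_cells(grid)
  res <- purrr::pmap(cells, function(theta0_deg, freq_hz) {
    cc <- cfg
    cc$theta_star_deg <- theta0_deg
    cc$frequency <- freq_hz
    fit <- tryCatch(sooc_optimize(cc, maxit = maxit),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(sooc_stiffness = NA_real_,
                            sooc_force = NA_real_, converged = FALSE))
    }
    g <- glance(fit)
    tibble::tibble(
      sooc_stiffness = ifelse(g$converged, g$mean_stiffness_rhythmic,
                              NA_real_),
      sooc_force = ifelse(g$converged, g$mean_abs_f_ff, NA_real_),
      converged = g$converged)
  })
  out <- dplyr::bind_cols(cells, purrr::list_rbind(res))
  structure(out, class = c("strategy_maps", class(tibble::tibble())),
            grid = grid, config = cfg)
}
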