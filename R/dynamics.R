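#' Solved-form accelerations of the cart-pendulum
#'
#' The cart and ball equations of motion are mutually implicit (each
#' acceleration appears in the other's equation). Solving them
#' simultaneously gives
#' \deqn{\ddot x = \frac{m_b (l \omega^2 \sin\theta + g \sin\theta
#'   \cos\theta) + F}{m_c + m_b \sin^2\theta}, \qquad
#'   \ddot\theta = -\frac{\ddot x \cos\theta}{l} - \frac{g \sin\theta}{l}.}
#' The denominator is bounded below by the cart mass, so the accelerations
#' are finite for every finite state.
#'
#' @param state Named numeric vector or list with `x` (m), `v` (m/s),
#'   `theta` (rad), `omega` (rad/s).
#' @param params A [system_params()].
#' @param applied_force External force on the cup in N.
#'
#' @return Named numeric vector with `cup_acc` (m/s^2) and `ball_acc`
#'   (rad/s^2).
#' @export
#' @examples
#' accelerations(c(x = 0, v = 0, theta = 0, omega = 0), system_params(), 3)
accelerations <- function(state, params, applied_force) {
  state <- as.list(state)
  check_finite(c(state$x, state$v, state$theta, state$omega, applied_force),
               "state/applied_force")
  s <- sin(state$theta)
  co <- cos(state$theta)
  l <- params$pendulum_length
  denom <- params$cup_mass + params$ball_mass * s^2
  cup_acc <- (params$ball_mass *
                (l * state$omega^2 * s + params$gravity * s * co) +
                applied_force) / denom
  ball_acc <- -cup_acc * co / l - params$gravity * s / l
  c(cup_acc = cup_acc, ball_acc = ball_acc)
}

#' Impedance-controller force
#'
#' Restoring force toward the desired trajectory:
#' `F = K (xd - x) + B (vd - v)`. A 0.1 m displacement from the equilibrium
#' trajectory at K = 40 produces a 4 N restoring force.
#'
#' @inheritParams accelerations
#' @param ctrl A [controller_spec()].
#' @param t Time in s (fixes the desired state on the cosine trajectory).
#' @return Force in N.
#' @export
impedance_force <- function(state, ctrl, t) {
  state <- as.list(state)
  check_finite(c(state$x, state$v, t), "state/t")
  d <- desired_trajectory(t, ctrl)
  ctrl$stiffness * (d$x_d - state$x) + ctrl$damping * (d$v_d - state$v)
}

#' One classic Runge-Kutta (RK4) step of the cart-pendulum
#'
#' @inheritParams accelerations
#' @param force_fn Function `(state, t) -> force N` evaluated at the RK4
#'   stage times.
#' @param t Step start time in s.
#' @param dt Step size in s.
#' @return Updated state (named numeric vector).
#' @export
rk4_step <- function(state, params, force_fn, t, dt) {
  if (dt <= 0) abort("`dt` must be > 0", class = "cupball_invalid_input")
  y <- c(x = unname(state[["x"]]), v = unname(state[["v"]]),
         theta = unname(state[["theta"]]), omega = unname(state[["omega"]]))
  deriv <- function(y, tt) {
    acc <- accelerations(y, params, force_fn(y, tt))
    c(y[["v"]], acc[["cup_acc"]], y[["omega"]], acc[["ball_acc"]])
  }
  k1 <- deriv(y, t)
  k2 <- deriv(y + dt / 2 * setNames(k1, names(y)), t + dt / 2)
  k3 <- deriv(y + dt / 2 * setNames(k2, names(y)), t + dt / 2)
  k4 <- deriv(y + dt * setNames(k3, names(y)), t + dt)
  y + dt / 6 * setNames(k1 + 2 * k2 + 2 * k3 + k4, names(y))
}

#' Forward-simulate an impedance-controlled trial
#'
#' Integrates the cart-pendulum driven by the impedance controller with a
#' fixed-step RK4 scheme. The cup starts on the desired trajectory
#' (`x0 = xd(0) = -A`, `v0 = 0`) so the controller begins with zero error.
#'
#' @inheritParams accelerations
#' @param ctrl A [controller_spec()].
#' @param theta0_deg Initial ball angle in degrees.
#' @param omega0_deg_s Initial ball angular velocity in deg/s (default -4,
#'   the mean initial ball velocity at the start of the rhythmic stage).
#' @param duration Trial duration in s (default 15).
#' @param dt Integration step in s (default 0.01).
#' @param x0,v0 Initial cup position/velocity; default `xd(0)` and 0.
#' @param extra_force Optional per-step additive force in N (length
#'   `duration/dt`), e.g. motor noise; held constant within each step.
#'
#' @return A tibble of class `cupball_trajectory` with columns `time_s`,
#'   `cup_pos_m`, `cup_vel_m_s`, `ball_angle_deg`, `ball_vel_deg_s`,
#'   `applied_force_N`. Attributes: `params`, `ctrl`, `dt`,
#'   `stage_boundary_index` (1 for a rhythmic-only trajectory).
#' @export
#' @examples
#' traj <- simulate_trial(system_params(), controller_spec(frequency = 0.5),
#'                        theta0_deg = -25, duration = 5)
simulate_trial <- function(params, ctrl, theta0_deg,
                           omega0_deg_s = -4, duration = 15, dt = 0.01,
                           x0 = NULL, v0 = 0, extra_force = numeric(0)) {
  if (duration <= 0 || dt <= 0) {
    abort("`duration` and `dt` must be > 0", class = "cupball_invalid_input")
  }
  if (is.null(x0)) x0 <- -ctrl$amplitude
  res <- tryCatch(
    simulate_trial_cpp(params$cup_mass, params$ball_mass,
                       params$pendulum_length, params$gravity,
                       ctrl$stiffness, ctrl$damping, ctrl$amplitude,
                       ctrl$frequency, x0, v0, deg2rad(theta0_deg),
                       deg2rad(omega0_deg_s), duration, dt, extra_force),
    error = function(e) {
      abort(conditionMessage(e), class = "cupball_divergence")
    })
  out <- tibble::tibble(
    time_s = res$time_s,
    cup_pos_m = res$x,
    cup_vel_m_s = res$v,
    ball_angle_deg = rad2deg(res$theta),
    ball_vel_deg_s = rad2deg(res$omega),
    applied_force_N = res$force)
  new_trajectory(out, params = params, ctrl = ctrl, dt = dt,
                 stage_boundary_index = 1L)
}

new_trajectory <- function(df, params, ctrl, dt, stage_boundary_index = 1L) {
  structure(df,
            class = c("cupball_trajectory", class(tibble::tibble())),
            params = params, ctrl = ctrl, dt = dt,
            stage_boundary_index = as.integer(stage_boundary_index))
}

#' Total mechanical energy of the cart + ball system
#'
#' Used as an integration oracle: with no applied force the energy
#' \deqn{E = \tfrac12 (m_c + m_b) v^2 + m_b l v \omega \cos\theta +
#'   \tfrac12 m_b l^2 \omega^2 + m_b g l (1 - \cos\theta)}
#' is conserved.
#'
#' @param traj A `cupball_trajectory` (or data frame with the trajectory
#'   columns).
#' @param params A [system_params()]; defaults to the trajectory attribute.
#' @return Numeric vector of energies in J, one per sample.
#' @export
mechanical_energy <- function(traj, params = NULL) {
  params <- params %||% attr(traj, "params")
  v <- traj$cup_vel_m_s
  th <- deg2rad(traj$ball_angle_deg)
  om <- deg2rad(traj$ball_vel_deg_s)
  l <- params$pendulum_length
  mb <- params$ball_mass
  0.5 * (params$cup_mass + mb) * v^2 + mb * l * v * om * cos(th) +
    0.5 * mb * l^2 * om^2 + mb * params$gravity * l * (1 - cos(th))
}

#' @export
#' @method autoplot cupball_trajectory
autoplot.cupball_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_s", "cup_pos_m", "ball_angle_deg",
                                "applied_force_N")],
    -"time_s", names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal,
                        levels = c("cup_pos_m", "ball_angle_deg",
                                   "applied_force_N"),
                        labels = c("cup position (m)", "ball angle (deg)",
                                   "applied force (N)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
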