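#' Physical parameters of the cup-and-ball (cart-pendulum) system
#'
#' The cup sliding on a horizontal line with a ball rolling inside it is
#' mechanically a cart with a suspended pendulum: the ball is the pendulum
#' bob and the cup rim sits at `rim_angle_deg` from the downward vertical.
#'
#' @param cup_mass Cart (cup) mass in kg.
#' @param ball_mass Pendulum bob (ball) mass in kg.
#' @param pendulum_length Pendulum length in m. The experimental conditions
#'   use 0.3 (short), 0.6 (medium) and 1.2 (long).
#' @param gravity Gravitational acceleration in m/s^2.
#' @param rim_angle_deg Cup rim angle in degrees; the ball escapes beyond it.
#'
#' @return An object of class `system_params`.
#' @export
#' @examples
#' system_params(pendulum_length = 0.6)
system_params <- function(cup_mass = 2.4, ball_mass = 0.6,
                          pendulum_length = 0.6, gravity = 9.81,
                          rim_angle_deg = 60) {
  vals <- c(cup_mass = cup_mass, ball_mass = ball_mass,
            pendulum_length = pendulum_length, gravity = gravity,
            rim_angle_deg = rim_angle_deg)
  check_finite(vals, "system_params")
  if (any(vals <= 0)) {
    abort("all system parameters must be strictly positive",
          class = "cupball_invalid_input")
  }
  if (rim_angle_deg > 90) {
    abort("`rim_angle_deg` must lie in (0, 90]",
          class = "cupball_invalid_input")
  }
  structure(list(cup_mass = cup_mass, ball_mass = ball_mass,
                 pendulum_length = pendulum_length, gravity = gravity,
                 rim_angle_deg = rim_angle_deg),
            class = "system_params")
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf(
    "<system_params> mc=%.3g kg, mb=%.3g kg, l=%.3g m, g=%.3g m/s^2, rim=%.3g deg\n",
    x$cup_mass, x$ball_mass, x$pendulum_length, x$gravity, x$rim_angle_deg))
  invisible(x)
}

#' Equilibrium-trajectory impedance controller specification
#'
#' The simulated hand applies a restoring force toward a desired rhythmic
#' trajectory, `F = K (xd - x) + B (vd - v)` with
#' `xd(t) = -A cos(2 pi f t)`. Stiffness `K` and damping `B` map deviation
#' from the equilibrium trajectory to force.
#'
#' @param stiffness Stiffness K in N/m (default 40, the landscape-sweep
#'   value).
#' @param damping Damping B in N s/m (default 70).
#' @param amplitude Desired-trajectory amplitude A in m. The default 0.3 is
#'   the stated forward-sweep value; the target boxes sit at +/-0.15 m, so
#'   the reading of A is ambiguous and configurable.
#' @param frequency Desired cup oscillation frequency f in Hz.
#'
#' @return An object of class `controller_spec`.
#' @export
#' @examples
#' controller_spec(frequency = 0.5)
controller_spec <- function(stiffness = 40, damping = 70, amplitude = 0.3,
                            frequency = 0.5) {
  vals <- c(stiffness, damping, amplitude, frequency)
  check_finite(vals, "controller_spec")
  if (stiffness < 0 || damping < 0) {
    abort("`stiffness` and `damping` must be >= 0",
          class = "cupball_invalid_input")
  }
  if (frequency <= 0) {
    abort("`frequency` must be > 0", class = "cupball_invalid_input")
  }
  structure(list(stiffness = stiffness, damping = damping,
                 amplitude = amplitude, frequency = frequency),
            class = "controller_spec")
}

#' @export
print.controller_spec <- function(x, ...) {
  cat(sprintf(
    "<controller_spec> K=%.3g N/m, B=%.3g N s/m, A=%.3g m, f=%.3g Hz\n",
    x$stiffness, x$damping, x$amplitude, x$frequency))
  invisible(x)
}

#' Desired cup trajectory of the impedance controller
#'
#' @param t Time(s) in s.
#' @param ctrl A [controller_spec()].
#' @return A tibble with `time_s`, `x_d` (m) and `v_d` (m/s).
#' @export
desired_trajectory <- function(t, ctrl) {
  w <- 2 * pi * ctrl$frequency
  tibble::tibble(time_s = t,
                 x_d = -ctrl$amplitude * cos(w * t),
                 v_d = ctrl$amplitude * w * sin(w * t))
}
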