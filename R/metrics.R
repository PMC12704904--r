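#' Circular variance of a set of angles
#'
#' `1 - R` where `R` is the length of the mean resultant vector of the unit
#' vectors `exp(i phi)`. Lies in `[0, 1]`: 0 for perfectly concentrated
#' angles, 1 for a vanishing resultant (e.g. equally spaced angles).
#'
#' @param angles Angles in rad.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' circular_variance(c(0, pi / 2)) # 1 - sqrt(2)/2
circular_variance <- function(angles) {
  if (length(angles) == 0) {
    abort("`angles` must be non-empty", class = "cupball_invalid_input")
  }
  check_finite(angles, "angles")
  1 - Mod(mean(exp(1i * angles)))
}

#' Circular mean of a set of angles
#'
#' @inheritParams circular_variance
#' @return Angle in rad in `(-pi, pi]`.
#' @export
circular_mean <- function(angles) {
  Arg(mean(exp(1i * angles)))
}

#' Relative-phase variability of a trial
#'
#' Circular variance of the cup-ball Hilbert relative phase over the
#' rhythmic stage, the package's proxy for dynamic stability. One nominal
#' period (`1/f`) is trimmed from each end of the phase series before the
#' statistic to suppress analytic-signal edge artifacts (configurable).
#'
#' @param traj A `cupball_trajectory` or data frame with `cup_pos_m` and
#'   `ball_angle_deg` columns.
#' @param dt Sample interval in s; defaults to the trajectory attribute.
#' @param frequency Nominal cup frequency in Hz used for the edge trim;
#'   defaults to the controller attribute.
#' @param trim_periods Number of nominal periods trimmed from each end
#'   (default 1).
#' @return Scalar relative-phase variability in `[0, 1]`.
#' @export
relative_phase_variability <- function(traj, dt = NULL, frequency = NULL,
                                       trim_periods = 1) {
  dt <- dt %||% attr(traj, "dt")
  frequency <- frequency %||% attr(traj, "ctrl")$frequency
  rp <- relative_phase(traj$cup_pos_m, traj$ball_angle_deg, dt)$rel_phase_rad
  circular_variance(trim_series(rp, dt, frequency, trim_periods))
}

trim_series <- function(x, dt, frequency, trim_periods) {
  n <- length(x)
  k <- round(trim_periods * (1 / frequency) / dt)
  if (2 * k >= n - 2) k <- 0  # series too short to trim
  if (k > 0) x[(k + 1):(n - k)] else x
}

#' Mean absolute applied force
#'
#' @param force Force series in N.
#' @return Mean of `|force|` in N.
#' @export
mean_absolute_force <- function(force) {
  check_finite(force, "force")
  mean(abs(force))
}

#' Log dimensionless jerk of a force profile
#'
#' Scale-invariant smoothness measure
#' \deqn{-\log\!\left(\frac{(t_{end}-t_0)^3}{F_{peak}^2}
#'   \int \ddot F^2 \, dt\right)}
#' with the second derivative taken by central differences (second-order
#' one-sided formulas at the ends). Larger (less negative) values mean a
#' smoother force. Invariant under amplitude scaling and time reversal.
#'
#' @param force Force series in N (length >= 5, not all zero).
#' @param dt Sample interval in s.
#' @return Dimensionless scalar.
#' @export
log_dimensionless_jerk <- function(force, dt) {
  check_finite(force, "force")
  n <- length(force)
  if (n < 5) abort("`force` must have length >= 5",
                   class = "cupball_invalid_input")
  fpeak <- max(abs(force))
  if (fpeak == 0) {
    abort("all-zero force: log dimensionless jerk is undefined",
          class = "cupball_invalid_input")
  }
  dd <- numeric(n)
  i <- 2:(n - 1)
  dd[i] <- (force[i + 1] - 2 * force[i] + force[i - 1]) / dt^2
  dd[1] <- (2 * force[1] - 5 * force[2] + 4 * force[3] - force[4]) / dt^2
  dd[n] <- (2 * force[n] - 5 * force[n - 1] + 4 * force[n - 2] -
              force[n - 3]) / dt^2
  duration <- (n - 1) * dt
  -log(duration^3 / fpeak^2 * sum(dd^2) * dt)
}

#' Risk of the ball escaping the cup
#'
#' Energy-margin risk measure. The ball's total energy is
#' `E_total = 1/2 mb l^2 omega^2 + mb g l (1 - cos theta)`; the escape
#' energy is the potential energy at the rim,
#' `E_escape = mb g l (1 - cos theta_rim)`. The risk over a trial of
#' duration `T` is `1 - (1 / (T E_escape)) * integral of E_margin dt` with
#' `E_margin = E_escape - E_total`: 0 for a ball resting at the bottom, 1
#' for a ball holding exactly the escape energy throughout.
#'
#' @param theta_deg Ball angle series in degrees.
#' @param omega_deg_s Ball angular velocity series in deg/s.
#' @param params A [system_params()].
#' @param dt Sample interval in s.
#' @return A list of class `risk_result` with `escape_energy` (J),
#'   `margin` (J series) and `risk` (dimensionless).
#' @export
risk_of_escape <- function(theta_deg, omega_deg_s, params, dt) {
  if (length(theta_deg) != length(omega_deg_s)) {
    abort("`theta_deg` and `omega_deg_s` must have equal length",
          class = "cupball_invalid_input")
  }
  th <- deg2rad(theta_deg)
  om <- deg2rad(omega_deg_s)
  mb <- params$ball_mass
  l <- params$pendulum_length
  g <- params$gravity
  e_total <- 0.5 * mb * l^2 * om^2 + mb * g * l * (1 - cos(th))
  e_escape <- mb * g * l * (1 - cos(deg2rad(params$rim_angle_deg)))
  margin <- e_escape - e_total
  duration <- (length(th) - 1) * dt
  # trapezoidal integral of the margin series
  int_margin <- sum((margin[-1] + margin[-length(margin)]) / 2) * dt
  structure(list(escape_energy = e_escape, margin = margin,
                 risk = 1 - int_margin / (duration * e_escape)),
            class = "risk_result")
}

#' Locate the preparation-to-rhythmic stage boundary
#'
#' The boundary is the last time the cup velocity is zero (sign change or
#' magnitude below `v_tol`) before the cup first enters the right target
#' box region (`cup_pos_m >= box_center - box_half_width`).
#'
#' @param traj A trajectory data frame with `cup_pos_m` and `cup_vel_m_s`.
#' @param box_center Right box center in m (default 0.15).
#' @param box_half_width Box half-width in m (default 0.05).
#' @param v_tol Velocity-zero tolerance in m/s (default 1e-3).
#' @return Integer sample index (1-based) of the stage boundary.
#' @export
parse_stages <- function(traj, box_center = 0.15, box_half_width = 0.05,
                         v_tol = 1e-3) {
  x <- traj$cup_pos_m
  v <- traj$cup_vel_m_s
  onset <- which(x >= box_center - box_half_width)[1]
  if (is.na(onset)) {
    abort("no rhythmic onset found: cup never enters the right box region",
          class = "cupball_boundary_not_found")
  }
  vv <- v[seq_len(onset)]
  zero <- abs(vv) < v_tol
  if (length(vv) > 1) {
    zero[-1] <- zero[-1] | (sign(vv[-1]) != sign(vv[-length(vv)]))
  }
  idx <- which(zero)
  if (length(idx) == 0) {
    abort("no cup-velocity zero crossing precedes the rhythmic onset",
          class = "cupball_boundary_not_found")
  }
  as.integer(max(idx))
}

#' Preparation duration of a trial
#'
#' Time from trial start to the preparation-to-rhythmic boundary.
#'
#' @param traj A trajectory data frame.
#' @param boundary_index Optional boundary sample index; estimated with
#'   [parse_stages()] when missing (falling back to the
#'   `stage_boundary_index` attribute).
#' @return Duration in s.
#' @export
preparation_duration <- function(traj, boundary_index = NULL) {
  boundary_index <- boundary_index %||% attr(traj, "stage_boundary_index")
  if (is.null(boundary_index)) boundary_index <- parse_stages(traj)
  traj$time_s[boundary_index] - traj$time_s[1]
}

#' Time to reach a stable relative phase during preparation
#'
#' Windowed procedure on the preparation-stage relative phase: the window's
#' right bound is fixed at the end of preparation and the left bound moves
#' backward one sample at a time; the returned time is the left-bound time
#' (relative to trial start) at which the in-window relative-phase
#' variability first exceeds `threshold`. If no window exceeds the
#' threshold the phase is considered stable from trial start and 0 is
#' returned, flagged with the attribute `stable_from_start = TRUE`. A
#' preparation shorter than `min_window` returns `NA` flagged
#' `undefined = TRUE`.
#'
#' @inheritParams preparation_duration
#' @param threshold Relative-phase-variability threshold (default 0.1, the
#'   value separating stable and unstable landscape regions).
#' @param min_window Minimum window length in s (default 0.5).
#' @param dt Sample interval in s; defaults to the trajectory attribute or
#'   the median time step.
#' @return Time in s (with flags as attributes).
#' @export
time_to_stable_phase <- function(traj, threshold = 0.1, min_window = 0.5,
                                 boundary_index = NULL, dt = NULL) {
  boundary_index <- boundary_index %||% attr(traj, "stage_boundary_index")
  if (is.null(boundary_index)) boundary_index <- parse_stages(traj)
  dt <- dt %||% attr(traj, "dt") %||% stats::median(diff(traj$time_s))
  n_min <- max(4L, as.integer(round(min_window / dt)))
  if (boundary_index <= n_min) {
    return(structure(NA_real_, undefined = TRUE))
  }
  prep <- traj[seq_len(boundary_index), ]
  rp <- relative_phase(prep$cup_pos_m, prep$ball_angle_deg, dt)$rel_phase_rad
  nb <- boundary_index
  for (left in seq(nb - n_min, 1L)) {
    if (circular_variance(rp[left:nb]) > threshold) {
      return(structure(traj$time_s[left] - traj$time_s[1],
                       stable_from_start = FALSE))
    }
  }
  structure(0, stable_from_start = TRUE)
}
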