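#' Per-trial dependent measures
#'
#' Computes the full behavioral-metric set for one trial: preparation
#' duration and time to stable relative phase (preparation stage), initial
#' ball angle at the stage boundary, mean cup frequency, relative-phase
#' variability, mean absolute applied force, log dimensionless jerk of the
#' applied force, energy-margin risk, and mean grip force when a grip
#' column is present.
#'
#' @param x A `trial_record` (see [generate_trial()]) or a
#'   `cupball_trajectory` (treated as rhythmic-only).
#' @param trial_id Identifier copied into the output.
#' @param trim_periods Edge trim (in nominal periods) for phase statistics.
#' @return A one-row tibble.
#' @export
analyze_trial <- function(x, trial_id = NA_character_, trim_periods = 1) {
  if (inherits(x, "trial_record")) {
    traj <- x$trajectory
    params <- x$params
    protocol <- x$protocol
    pendulum <- x$pendulum
    nominal_f <- x$choice$freq_hz
    boundary <- tryCatch(parse_stages(traj), error = function(e) NA_integer_)
  } else {
    traj <- x
    params <- attr(x, "params")
    protocol <- NA_character_
    pendulum <- params$pendulum_length
    nominal_f <- attr(x, "ctrl")$frequency
    boundary <- attr(x, "stage_boundary_index") %||% 1L
  }
  dt <- stats::median(diff(traj$time_s))
  n <- nrow(traj)

  if (is.na(boundary) || boundary <= 1L) {
    prep_dur <- 0
    t_stable <- NA_real_
    rhyth <- traj
  } else {
    prep_dur <- preparation_duration(traj, boundary)
    t_stable <- as.numeric(
      time_to_stable_phase(traj, boundary_index = boundary, dt = dt))
    rhyth <- traj[boundary:n, ]
  }

  freq <- instantaneous_frequency(rhyth$cup_pos_m, dt)$freq_hz
  nominal_f <- nominal_f %||% stats::median(freq)
  mean_freq <- mean(trim_series(freq, dt, nominal_f, trim_periods))

  rp <- relative_phase(rhyth$cup_pos_m, rhyth$ball_angle_deg,
                       dt)$rel_phase_rad
  rpv <- circular_variance(trim_series(rp, dt, nominal_f, trim_periods))

  risk <- risk_of_escape(rhyth$ball_angle_deg, rhyth$ball_vel_deg_s,
                         params, dt)$risk

  tibble::tibble(
    trial_id = trial_id,
    protocol = protocol,
    pendulum_m = pendulum,
    prep_duration_s = prep_dur,
    time_to_stable_s = t_stable,
    init_ball_angle_deg = traj$ball_angle_deg[max(boundary, 1L, na.rm = TRUE)],
    mean_freq_hz = mean_freq,
    rel_phase_var = rpv,
    mean_abs_force_N = mean_absolute_force(rhyth$applied_force_N),
    ldj_force = log_dimensionless_jerk(rhyth$applied_force_N, dt),
    risk = risk,
    mean_grip_N = if ("grip_force_N" %in% names(rhyth)) {
      mean(rhyth$grip_force_N)
    } else {
      NA_real_
    })
}

#' Metrics table for a set of trials
#'
#' @param trials A list of `trial_record`s (e.g. from [generate_cohort()])
#'   or a directory containing trial CSV files written by [write_trial()].
#' @inheritParams analyze_trial
#' @return A tibble with one row per trial.
#' @export
analyze_trials <- function(trials, trim_periods = 1) {
  if (is.character(trials)) {
    paths <- list.files(trials, pattern = "\\.csv$", full.names = TRUE)
    paths <- paths[!grepl("manifest", basename(paths))]
    trials <- lapply(paths, read_trial)
  }
  ids <- purrr::imap_chr(trials, function(tr, i) {
    tr$trial_id %||% as.character(i)
  })
  purrr::list_rbind(purrr::map2(trials, ids, analyze_trial,
                                trim_periods = trim_periods))
}

#' Cohort-level summary of trial metrics
#'
#' Mean of each metric by protocol and pendulum length.
#'
#' @param metrics A tibble from [analyze_trials()].
#' @return A summary tibble.
#' @export
summarize_cohort <- function(metrics) {
  metrics |>
    dplyr::group_by(.data$protocol, .data$pendulum_m) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_trials = dplyr::n(), .groups = "drop")
}
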