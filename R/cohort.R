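#' Participant model for the synthetic cohort
#'
#' Phenomenological description of one simulated participant: which stable
#' branch of the landscape they prefer, their frequency preference, how
#' sharply they sample strategies from the stability density, motor noise,
#' a grip-force model (baseline + uncertainty gain + load coupling) and
#' preparation timing. Encodes the qualitative structure the analysis
#' pipeline assumes, with no claim of physiological realism.
#'
#' @param preferred_branch `"in-phase"`, `"anti-phase"` or `"mixed"`.
#' @param freq_center,freq_spread Frequency preference (Hz).
#' @param temperature Softmin temperature used when sampling strategies
#'   from the stability map (lower = sharper choices).
#' @param motor_noise_sd Additive force noise SD in N.
#' @param grip_baseline Baseline grip force in N.
#' @param grip_uncertainty_gain Grip increase per unit pendulum-length SD
#'   (N per m).
#' @param grip_load_coupling Grip force per unit applied force
#'   (dimensionless).
#' @param grip_noise_sd Grip measurement noise SD in N.
#' @param prep_skill Mean preparation duration at zero uncertainty (s).
#' @param uncertainty_prep_penalty Extra preparation time in the random
#'   protocol (s).
#' @param prep_noise_sd Trial-to-trial preparation-duration SD (s).
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(preferred_branch = c("in-phase", "anti-phase",
                                                   "mixed"),
                              freq_center = 0.5, freq_spread = 0.1,
                              temperature = 0.03, motor_noise_sd = 0.5,
                              grip_baseline = 8,
                              grip_uncertainty_gain = 10,
                              grip_load_coupling = 0.3,
                              grip_noise_sd = 0.3,
                              prep_skill = 4,
                              uncertainty_prep_penalty = 1,
                              prep_noise_sd = 0.5) {
  preferred_branch <- match.arg(preferred_branch)
  vals <- c(freq_spread, temperature, motor_noise_sd, grip_baseline,
            grip_uncertainty_gain, grip_load_coupling, grip_noise_sd,
            prep_skill, uncertainty_prep_penalty, prep_noise_sd)
  if (any(vals < 0)) {
    abort("participant parameters must be nonnegative",
          class = "cupball_invalid_input")
  }
  structure(as.list(environment()), class = "participant_model")
}

#' Cohort configuration
#'
#' @param n_participants Number of simulated participants (default 12).
#' @param protocols Subset of `c("random", "blocked")`.
#' @param pendulums Pendulum lengths in m.
#' @param trials_per_condition Trials per pendulum per protocol (default
#'   40, the experimental count).
#' @param seed Master seed; every random stream in the cohort derives from
#'   it.
#' @param sample_rate_hz Output sampling rate (default 120, the recording
#'   rate the analysis code must handle).
#' @param rhythmic_duration Rhythmic-stage duration in s (default 15).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 12,
                          protocols = c("random", "blocked"),
                          pendulums = c(0.3, 0.6, 1.2),
                          trials_per_condition = 40, seed = 1,
                          sample_rate_hz = 120, rhythmic_duration = 15) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  if (n_participants < 1 || trials_per_condition < 1) {
    abort("cohort must have >= 1 participant and >= 1 trial",
          class = "cupball_invalid_input")
  }
  structure(list(n_participants = n_participants, protocols = protocols,
                 pendulums = pendulums,
                 trials_per_condition = trials_per_condition, seed = seed,
                 sample_rate_hz = sample_rate_hz,
                 rhythmic_duration = rhythmic_duration),
            class = "cohort_config")
}

#' Trial plan (manifest skeleton) for a cohort
#'
#' Full factorial participants x protocols x pendulums x trials with
#' per-trial derived seeds.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble with one row per planned trial.
#' @export
cohort_trial_plan <- function(cfg) {
  plan <- tidyr::expand_grid(
    participant = seq_len(cfg$n_participants),
    protocol = cfg$protocols,
    pendulum_m = cfg$pendulums,
    trial = seq_len(cfg$trials_per_condition))
  set.seed(cfg$seed)
  plan$trial_seed <- sample.int(.Machine$integer.max - 1, nrow(plan))
  plan$trial_id <- sprintf("p%02d_%s_l%03.0f_t%02d", plan$participant,
                           substr(plan$protocol, 1, 4),
                           plan$pendulum_m * 100, plan$trial)
  plan
}

#' Sample a strategy choice from a stability landscape
#'
#' Samples one or more (initial ball angle, cup frequency) choices from
#' the softmin density of the stability map at the participant's choice
#' temperature, weighted by the participant's frequency preference and
#' restricted to their preferred branch (via the circular mean of the
#' relative phase per cell); choices are jittered uniformly within the
#' chosen cell.
#'
#' @param participant A [participant_model()].
#' @param stability_map A `strategy_map` from [sweep_stability()] (with
#'   `mean_rel_phase_deg`).
#' @param n Number of choices to draw.
#' @return A tibble with `theta0_deg`, `freq_hz`.
#' @export
sample_choice <- function(participant, stability_map, n = 1) {
  dens <- map_to_density(stability_map, tau = participant$temperature)
  w <- dens$density
  # frequency preference
  w <- w * stats::dnorm(dens$freq_hz, participant$freq_center,
                        participant$freq_spread)
  # branch restriction
  if (participant$preferred_branch != "mixed" &&
      "mean_rel_phase_deg" %in% names(stability_map)) {
    in_phase <- abs(stability_map$mean_rel_phase_deg) < 90
    keep <- if (participant$preferred_branch == "in-phase") in_phase else
      !in_phase
    keep[is.na(keep)] <- FALSE
    if (any(keep)) w[!keep] <- 0
  }
  if (sum(w) == 0) w <- dens$density
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  th_ax <- sort(unique(dens$theta0_deg))
  f_ax <- sort(unique(dens$freq_hz))
  dth <- if (length(th_ax) > 1) min(diff(th_ax)) else 1
  df <- if (length(f_ax) > 1) min(diff(f_ax)) else 0.01
  tibble::tibble(
    theta0_deg = pmin(max(th_ax), pmax(min(th_ax),
      dens$theta0_deg[idx] + runif(n, -dth / 2, dth / 2))),
    freq_hz = pmin(max(f_ax), pmax(min(f_ax),
      dens$freq_hz[idx] + runif(n, -df / 2, df / 2))))
}

# Preparation-stage synthesis: a small-amplitude jiggle around the left
# box whose cup-ball relative phase is noisy during the first half and
# locked during the second half, ending at rest at the box center.
synth_preparation <- function(participant, choice, prep_duration, fs,
                              box_center = -0.15) {
  dt <- 1 / fs
  n <- max(8L, round(prep_duration * fs))
  t <- seq(0, by = dt, length.out = n)
  f_j <- max(choice$freq_hz, 0.8)  # jiggle faster than the transport rhythm
  # carrier aligned so it ends at phase 0 (peak) right at the boundary
  phase_c <- 2 * pi * f_j * (t - t[n])
  # jiggle amplitude ramps in, then decays (zero end slope) to a small but
  # nonzero value so the oscillation phase stays defined up to the
  # boundary; the offset keeps the final cup position at the box center
  ramp_in <- sin(pi * pmin(t / (0.2 * prep_duration), 1) / 2)^2
  s_out <- pmin(pmax((t - 0.8 * prep_duration) /
                       (0.2 * prep_duration), 0), 1)
  taper <- ramp_in * (1 - (2 / 3) * s_out^2 * (3 - 2 * s_out))
  amp <- 0.03 * taper
  x <- (box_center - amp[n]) + amp * cos(phase_c)
  # ball: same carrier with phase noise that switches off halfway, and an
  # envelope ramping to the chosen initial angle
  half <- floor(n / 2)
  psi <- c(rnorm(half, 0, 1.5), rep(0, n - half))
  offset <- if (participant$preferred_branch == "anti-phase") pi else 0
  env <- seq(0.3, 1, length.out = n) * choice$theta0_deg / cos(offset)
  theta <- env * cos(phase_c + offset + psi)
  v <- c(diff(x) / dt, 0)
  omega <- c(diff(theta) / dt, -4)
  tibble::tibble(time_s = t, cup_pos_m = x, cup_vel_m_s = v,
                 ball_angle_deg = theta, ball_vel_deg_s = omega)
}

#' Generate one synthetic participant trial
#'
#' A preparation stage (synthesized jiggle whose relative phase locks
#' halfway through) followed by a rhythmic stage forward-simulated with
#' the impedance controller at the chosen strategy plus motor noise on the
#' applied force; grip force is baseline + uncertainty gain x sigma_l +
#' load coupling x |applied force| + noise, rising through preparation.
#'
#' @param participant A [participant_model()].
#' @param protocol `"random"` or `"blocked"`.
#' @param pendulum Pendulum length in m.
#' @param choice One-row data frame with `theta0_deg`, `freq_hz`.
#' @param seed Trial seed.
#' @param fs Output sampling rate in Hz (default 120; internal simulation
#'   runs at 10 ms and is resampled).
#' @param rhythmic_duration Rhythmic-stage duration in s (default 15).
#' @param ctrl_template Controller used for the rhythmic simulation
#'   (amplitude 0.15 so the cup oscillates between the boxes).
#' @return An object of class `trial_record`: `trial_id`, `participant`,
#'   `protocol`, `pendulum`, `choice`, `params`, `trajectory` (tibble with
#'   grip column), `true_boundary_index`, `true_prep_duration`.
#' @export
generate_trial <- function(participant, protocol, pendulum, choice,
                           seed = 1, fs = 120, rhythmic_duration = 15,
                           ctrl_template = controller_spec(amplitude = 0.15)) {
  set.seed(seed)
  sigma_l <- if (protocol == "random") {
    pendulum_length_moments()$sd
  } else {
    0.1
  }
  prep_dur <- max(1.5, participant$prep_skill +
                    (protocol == "random") *
                    participant$uncertainty_prep_penalty +
                    rnorm(1, 0, participant$prep_noise_sd))
  prep <- synth_preparation(participant, choice, prep_dur, fs)

  params <- system_params(pendulum_length = pendulum)
  ctrl <- ctrl_template
  ctrl$frequency <- choice$freq_hz
  dt_sim <- 0.01
  n_sim <- round(rhythmic_duration / dt_sim)
  noise <- rnorm(n_sim, 0, participant$motor_noise_sd)
  sim <- simulate_trial(params, ctrl, choice$theta0_deg,
                        omega0_deg_s = -4,
                        duration = rhythmic_duration, dt = dt_sim,
                        extra_force = noise)
  # resample the simulation onto the recording rate
  t_out <- seq(0, rhythmic_duration, by = 1 / fs)
  rhy <- tibble::tibble(
    time_s = t_out + max(prep$time_s) + 1 / fs,
    cup_pos_m = approx(sim$time_s, sim$cup_pos_m, t_out)$y,
    cup_vel_m_s = approx(sim$time_s, sim$cup_vel_m_s, t_out)$y,
    ball_angle_deg = approx(sim$time_s, sim$ball_angle_deg, t_out)$y,
    ball_vel_deg_s = approx(sim$time_s, sim$ball_vel_deg_s, t_out)$y,
    applied_force_N = approx(sim$time_s, sim$applied_force_N, t_out)$y)
  # preparation applied force: cart inertia against the jiggle
  total_mass <- params$cup_mass + params$ball_mass
  acc_prep <- c(0, diff(prep$cup_vel_m_s)) * fs
  prep$applied_force_N <- total_mass * acc_prep +
    rnorm(nrow(prep), 0, participant$motor_noise_sd)
  traj <- dplyr::bind_rows(prep, rhy)
  boundary <- nrow(prep)
  # grip: ramps up through preparation toward its uncertainty-scaled level
  grip_level <- participant$grip_baseline +
    participant$grip_uncertainty_gain * sigma_l
  ramp <- c(seq(0.5, 1, length.out = boundary),
            rep(1, nrow(traj) - boundary))
  traj$grip_force_N <- grip_level * ramp +
    participant$grip_load_coupling * abs(traj$applied_force_N) +
    rnorm(nrow(traj), 0, participant$grip_noise_sd)
  structure(list(trial_id = NULL, participant = NA_integer_,
                 protocol = protocol, pendulum = pendulum,
                 choice = tibble::as_tibble(choice[c("theta0_deg",
                                                     "freq_hz")]),
                 params = params, trajectory = traj,
                 true_boundary_index = boundary,
                 true_prep_duration = max(prep$time_s),
                 seed = seed),
            class = "trial_record")
}

#' Generate a synthetic cohort
#'
#' Draws per-participant models, samples each trial's strategy from the
#' pendulum's stability landscape, and generates every trial of the full
#' factorial design. All randomness derives from the master seed, so a
#' fixed seed reproduces the cohort exactly.
#'
#' @param cfg A [cohort_config()].
#' @param stability_maps Optional named list of `strategy_map`s, one per
#'   pendulum length (names like `"0.3"`); computed at a 19 x 15 grid
#'   resolution when missing.
#' @param out_dir Optional directory: trials are written as CSV files (via
#'   [write_trial()]) instead of kept in memory.
#' @param participants Optional list of [participant_model()]s (length
#'   `n_participants`); drawn at random when missing.
#' @return A list with `manifest` (tibble mirroring the choice-set schema:
#'   participant, protocol, pendulum_m, theta0_deg, freq_hz, ...) and
#'   `trials` (list of `trial_record`s, or file paths when `out_dir` is
#'   given).
#' @export
generate_cohort <- function(cfg, stability_maps = NULL, out_dir = NULL,
                            participants = NULL) {
  plan <- cohort_trial_plan(cfg)
  set.seed(cfg$seed + 1)
  if (is.null(participants)) {
    participants <- lapply(seq_len(cfg$n_participants), function(i) {
      branch <- sample(c("in-phase", "anti-phase", "mixed"), 1,
                       prob = c(0.5, 0.25, 0.25))
      # frequency comfort zone sits on the preferred branch (in-phase
      # solutions live below the pendulum resonance, anti-phase above)
      fc <- switch(branch, "in-phase" = runif(1, 0.38, 0.52),
                   "anti-phase" = runif(1, 0.62, 0.78),
                   runif(1, 0.45, 0.65))
      participant_model(
        preferred_branch = branch,
        freq_center = fc,
        freq_spread = runif(1, 0.05, 0.12),
        temperature = runif(1, 0.02, 0.06),
        grip_baseline = runif(1, 6, 10),
        prep_skill = runif(1, 3, 5))
    })
  }
  if (is.null(stability_maps)) {
    # landscapes of the cohort's own controller (cup oscillating between
    # the boxes), so choices are stable under the executed dynamics
    grid <- strategy_grid(n_theta0 = 19, n_freq = 15)
    stability_maps <- lapply(cfg$pendulums, function(l) {
      sweep_stability(system_params(pendulum_length = l), grid,
                      ctrl = controller_spec(amplitude = 0.15))
    })
    names(stability_maps) <- as.character(cfg$pendulums)
  }
  # sample choices (seeded per trial, independent of generation order)
  choices <- purrr::pmap(plan, function(participant, protocol, pendulum_m,
                                        trial, trial_seed, trial_id) {
    set.seed(trial_seed)
    sample_choice(participants[[participant]],
                  stability_maps[[as.character(pendulum_m)]])
  })
  plan$theta0_deg <- purrr::map_dbl(choices, "theta0_deg")
  plan$freq_hz <- purrr::map_dbl(choices, "freq_hz")

  gen_one <- function(row, choice) {
    rec <- generate_trial(participants[[row$participant]], row$protocol,
                          row$pendulum_m, choice, seed = row$trial_seed + 1,
                          fs = cfg$sample_rate_hz,
                          rhythmic_duration = cfg$rhythmic_duration)
    rec$trial_id <- row$trial_id
    rec$participant <- row$participant
    rec
  }
  rows <- split(plan, seq_len(nrow(plan)))
  if (is.null(out_dir)) {
    trials <- purrr::map2(rows, choices, gen_one)
    names(trials) <- plan$trial_id
  } else {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    trials <- purrr::map2_chr(rows, choices, function(row, ch) {
      path <- file.path(out_dir, paste0(row$trial_id, ".csv"))
      write_trial(gen_one(row, ch), path)
      path
    })
    readr::write_csv(plan, file.path(out_dir, "manifest.csv"))
  }
  boundaries <- if (is.null(out_dir)) {
    purrr::map_int(trials, "true_boundary_index")
  } else {
    NA_integer_
  }
  plan$true_boundary_index <- boundaries
  list(manifest = plan, trials = trials, participants = participants,
       stability_maps = stability_maps)
}
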