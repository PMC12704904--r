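#' Strategy grid over initial ball angle and cup frequency
#'
#' Uniform grid over the preparation choice (initial ball angle) and the
#' interaction choice (cup oscillation frequency), defaulting to the swept
#' ranges theta0 in \[-90, 90\] deg and f in \[0.3, 1.0\] Hz.
#'
#' @param theta0_range Initial ball angle range in degrees.
#' @param freq_range Cup frequency range in Hz.
#' @param n_theta0,n_freq Number of grid nodes per axis (defaults 37 x 36,
#'   i.e. 5 deg x 0.02 Hz).
#' @return An object of class `strategy_grid` with strictly increasing
#'   `theta0_deg` and `freq_hz` axes.
#' @export
strategy_grid <- function(theta0_range = c(-90, 90),
                          freq_range = c(0.3, 1.0),
                          n_theta0 = 37, n_freq = 36) {
  if (n_theta0 < 2 || n_freq < 2) {
    abort("grid needs at least 2 nodes per axis",
          class = "cupball_invalid_input")
  }
  structure(list(theta0_deg = seq(theta0_range[1], theta0_range[2],
                                  length.out = n_theta0),
                 freq_hz = seq(freq_range[1], freq_range[2],
                               length.out = n_freq)),
            class = "strategy_grid")
}

grid_cells <- function(grid) {
  tidyr::expand_grid(theta0_deg = grid$theta0_deg, freq_hz = grid$freq_hz)
}

#' Sweep all objective landscapes over a strategy grid
#'
#' For each (initial ball angle, cup frequency) cell, forward-simulates a
#' 15 s trial with the impedance controller and computes relative-phase
#' variability (stability), mean absolute force (effort), log
#' dimensionless jerk (smoothness), energy-margin risk, and the circular
#' mean of the relative phase (branch label: in-phase vs anti-phase).
#' Cells whose simulation diverges get `rel_phase_var = 1` and are flagged.
#'
#' @param params A [system_params()].
#' @param grid A [strategy_grid()].
#' @param ctrl Controller template (a [controller_spec()]; its `frequency`
#'   is overridden per cell).
#' @param omega0_deg_s,duration,dt Forward-simulation settings.
#' @param trim_periods Edge trim for the phase statistics.
#' @return A tibble of class `strategy_maps` with one row per cell and
#'   columns `theta0_deg`, `freq_hz`, `rel_phase_var`, `mean_abs_force`,
#'   `ldj_force`, `risk`, `mean_rel_phase_deg`, `diverged`.
#' @export
sweep_strategy_maps <- function(params, grid, ctrl = controller_spec(),
                                omega0_deg_s = -4, duration = 15, dt = 0.01,
                                trim_periods = 1) {
  cells <- grid_cells(grid)
  res <- purrr::pmap(cells, function(theta0_deg, freq_hz) {
    cc <- ctrl
    cc$frequency <- freq_hz
    traj <- tryCatch(
      simulate_trial(params, cc, theta0_deg, omega0_deg_s, duration, dt),
      cupball_divergence = function(e) NULL)
    if (is.null(traj)) {
      return(tibble::tibble(rel_phase_var = 1, mean_abs_force = NA_real_,
                            ldj_force = NA_real_, risk = NA_real_,
                            mean_rel_phase_deg = NA_real_, diverged = TRUE))
    }
    rp <- relative_phase(traj$cup_pos_m, traj$ball_angle_deg,
                         dt)$rel_phase_rad
    rp_t <- trim_series(rp, dt, freq_hz, trim_periods)
    tibble::tibble(
      rel_phase_var = circular_variance(rp_t),
      mean_abs_force = mean_absolute_force(traj$applied_force_N),
      ldj_force = log_dimensionless_jerk(traj$applied_force_N, dt),
      risk = risk_of_escape(traj$ball_angle_deg, traj$ball_vel_deg_s,
                            params, dt)$risk,
      mean_rel_phase_deg = rad2deg(circular_mean(rp_t)),
      diverged = FALSE)
  })
  out <- dplyr::bind_cols(cells, purrr::list_rbind(res))
  structure(out, class = c("strategy_maps", class(tibble::tibble())),
            params = params, grid = grid, ctrl = ctrl)
}

map_metrics <- c("rel_phase_var", "mean_abs_force", "ldj_force", "risk",
                 "sooc_stiffness", "sooc_force")

#' Extract one metric from a multi-metric strategy sweep
#'
#' @param maps A `strategy_maps` tibble (from [sweep_strategy_maps()] or
#'   [sweep_sooc()]).
#' @param metric Column to extract.
#' @return A `strategy_map` tibble (`theta0_deg`, `freq_hz`, `value`).
#' @export
as_strategy_map <- function(maps, metric) {
  if (!metric %in% names(maps)) {
    abort(sprintf("metric `%s` not present", metric),
          class = "cupball_invalid_input")
  }
  out <- maps[c("theta0_deg", "freq_hz")]
  out$value <- maps[[metric]]
  if ("mean_rel_phase_deg" %in% names(maps)) {
    out$mean_rel_phase_deg <- maps$mean_rel_phase_deg
  }
  if ("diverged" %in% names(maps)) out$diverged <- maps$diverged
  structure(out, class = c("strategy_map", class(tibble::tibble())),
            metric = metric, grid = attr(maps, "grid"))
}

#' Stability landscape (relative-phase variability map)
#'
#' @inheritParams sweep_strategy_maps
#' @param ... Passed to [sweep_strategy_maps()].
#' @return A tibble of class `strategy_map` (`theta0_deg`, `freq_hz`,
#'   `value`, plus branch/divergence info).
#' @export
sweep_stability <- function(params, grid, ctrl = controller_spec(), ...) {
  as_strategy_map(sweep_strategy_maps(params, grid, ctrl, ...),
                  "rel_phase_var")
}

#' Alternative-objective landscape
#'
#' @inheritParams sweep_stability
#' @param metric One of `"mean_abs_force"`, `"ldj_force"`, `"risk"`.
#' @export
sweep_cost <- function(params, grid,
                       metric = c("mean_abs_force", "ldj_force", "risk"),
                       ctrl = controller_spec(), ...) {
  metric <- match.arg(metric)
  as_strategy_map(sweep_strategy_maps(params, grid, ctrl, ...), metric)
}

#' Convert a strategy map into a probability density
#'
#' Cost-like maps (low = preferred) are converted with a softmin,
#' `p ~ exp(-value / tau)`; already-positive preference maps can be
#' normalized directly. The default temperature is the sample standard
#' deviation of the map values (scale-aware, argmin-consistent as
#' `tau -> 0`). Non-finite cells receive zero mass; every cell is floored
#' at `floor` before normalization so Kullback-Leibler divergences stay
#' finite.
#'
#' @param map A `strategy_map` (or tibble with `theta0_deg`, `freq_hz`,
#'   `value`).
#' @param tau Softmin temperature; default `sd(value)`.
#' @param transform `"softmin"` (default) or `"normalize"`.
#' @param floor Density floor before normalization (default 1e-6).
#' @return A tibble with `theta0_deg`, `freq_hz`, `density` summing to 1.
#' @export
map_to_density <- function(map, tau = NULL,
                           transform = c("softmin", "normalize"),
                           floor = 1e-6) {
  transform <- match.arg(transform)
  v <- map$value
  ok <- is.finite(v)
  w <- numeric(length(v))
  if (transform == "softmin") {
    tau <- tau %||% sd(v[ok])
    if (!is.finite(tau) || tau <= 0) tau <- 1  # constant map -> uniform
    w[ok] <- exp(-(v[ok] - min(v[ok])) / tau)
  } else {
    if (any(v[ok] < 0)) {
      abort("`normalize` transform requires nonnegative values",
            class = "cupball_invalid_input")
    }
    w[ok] <- v[ok]
  }
  w <- w / sum(w)
  w <- pmax(w, floor)
  tibble::tibble(theta0_deg = map$theta0_deg, freq_hz = map$freq_hz,
                 density = w / sum(w))
}

#' 2D histogram of behavioral strategy choices on a grid
#'
#' Bins choices of (initial ball angle, cup frequency) into the strategy
#' grid's cells (edges midway between nodes; out-of-range choices are
#' clipped to the boundary cells), floors zero-count cells and normalizes.
#'
#' @param choices Data frame with `theta0_deg` and `freq_hz` columns (one
#'   row per trial).
#' @param grid A [strategy_grid()].
#' @param floor Count floor applied before normalization (default 1e-6).
#' @return A tibble with `theta0_deg`, `freq_hz`, `density` summing to 1.
#' @export
choices_histogram <- function(choices, grid, floor = 1e-6) {
  snap <- function(x, axis) axis[pmax(1, pmin(length(axis),
    findInterval(x, c(-Inf, axis[-1] - diff(axis) / 2)) ))]
  cells <- grid_cells(grid)
  counts <- choices |>
    dplyr::transmute(theta0_deg = snap(.data$theta0_deg, grid$theta0_deg),
                     freq_hz = snap(.data$freq_hz, grid$freq_hz)) |>
    dplyr::count(.data$theta0_deg, .data$freq_hz)
  out <- dplyr::left_join(cells, counts, by = c("theta0_deg", "freq_hz"))
  n <- ifelse(is.na(out$n), 0, out$n)
  w <- pmax(n / sum(n), floor)
  out$density <- w / sum(w)
  out[c("theta0_deg", "freq_hz", "density")]
}

#' Kullback-Leibler divergence between two densities on the same grid
#'
#' `sum p log(p / q)` in nats. By package convention `p` is the behavioral
#' choice histogram and `q` the model-derived density, so the divergence
#' measures how well the model density explains where the data mass lies.
#'
#' @param p,q Tibbles with `theta0_deg`, `freq_hz`, `density` on identical
#'   grids, both strictly positive (use the density floor).
#' @return Divergence in nats (>= 0).
#' @export
kl_divergence <- function(p, q) {
  m <- dplyr::inner_join(p, q, by = c("theta0_deg", "freq_hz"),
                         suffix = c("_p", "_q"))
  if (nrow(m) != nrow(p) || nrow(m) != nrow(q)) {
    abort("`p` and `q` must be defined on the same grid",
          class = "cupball_invalid_input")
  }
  if (any(m$density_p <= 0) || any(m$density_q <= 0)) {
    abort("densities must be strictly positive (apply a floor)",
          class = "cupball_invalid_input")
  }
  sum(m$density_p * log(m$density_p / m$density_q))
}

#' Rank objective landscapes by how well they explain choices
#'
#' Computes the KL divergence of one behavioral choice histogram against
#' the density of each objective map; a lower divergence means that
#' objective better explains where the choices concentrate.
#'
#' @param choices Data frame of choices (`theta0_deg`, `freq_hz`).
#' @param maps A `strategy_maps` tibble from [sweep_strategy_maps()] or a
#'   named list of `strategy_map`s.
#' @param metrics Which metrics to rank (default the four objective maps).
#' @param tau Optional softmin temperature passed to [map_to_density()].
#' @return A tibble with `metric` and `kl_nats`, sorted ascending.
#' @export
rank_objectives <- function(choices, maps,
                            metrics = c("rel_phase_var", "mean_abs_force",
                                        "ldj_force", "risk"),
                            tau = NULL) {
  if (inherits(maps, "strategy_maps")) {
    grid <- attr(maps, "grid")
    maps <- setNames(lapply(metrics, function(m) as_strategy_map(maps, m)),
                     metrics)
  } else {
    metrics <- names(maps)
    grid <- attr(maps[[1]], "grid")
  }
  hist <- choices_histogram(choices, grid)
  kl <- purrr::map_dbl(maps, function(m) {
    kl_divergence(hist, map_to_density(m, tau = tau))
  })
  dplyr::arrange(tibble::tibble(metric = names(kl), kl_nats = unname(kl)),
                 .data$kl_nats)
}

#' Connected low-variability branches of a stability map
#'
#' Thresholds the map at `threshold` and counts 8-connected components of
#' the below-threshold cells on the grid lattice; each branch is labeled
#' in-phase or anti-phase by the circular mean of its relative phase.
#'
#' @param map A `strategy_map` of `rel_phase_var` with a
#'   `mean_rel_phase_deg` column.
#' @param threshold Stability threshold (default 0.1).
#' @return A tibble with one row per branch: `branch`, `n_cells`,
#'   `mean_freq_hz`, `mean_abs_rel_phase_deg`, `phase_type`.
#' @export
stability_branches <- function(map, threshold = 0.1) {
  idx <- which(map$value < threshold)
  if (length(idx) == 0) {
    return(tibble::tibble(branch = integer(), n_cells = integer(),
                          mean_freq_hz = numeric(),
                          mean_abs_rel_phase_deg = numeric(),
                          phase_type = character()))
  }
  th_ax <- sort(unique(map$theta0_deg))
  f_ax <- sort(unique(map$freq_hz))
  ii <- match(map$theta0_deg[idx], th_ax)
  jj <- match(map$freq_hz[idx], f_ax)
  key <- paste(ii, jj)
  pos <- setNames(seq_along(idx), key)
  edges <- integer(0)
  for (k in seq_along(idx)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pos[paste(ii[k] + di, jj[k] + dj)]
      if (!is.na(nb) && nb > k) edges <- c(edges, k, nb)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  tibble::tibble(cell = idx, branch = comp,
                 freq_hz = map$freq_hz[idx],
                 rp = map$mean_rel_phase_deg[idx]) |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_freq_hz = mean(.data$freq_hz),
      mean_abs_rel_phase_deg = mean(abs(.data$rp)),
      .groups = "drop") |>
    dplyr::mutate(phase_type = ifelse(.data$mean_abs_rel_phase_deg < 90,
                                      "in-phase", "anti-phase")) |>
    dplyr::arrange(.data$mean_freq_hz)
}

#' @export
#' @method autoplot strategy_map
autoplot.strategy_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$theta0_deg, .data$freq_hz,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95",
                                 name = attr(object, "metric")) +
    ggplot2::labs(x = "initial ball angle (deg)", y = "cup frequency (Hz)")
}
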