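# Shared fixtures, computed lazily and memoized so expensive sweeps are
# run at most once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Medium-pendulum landscapes at the scaled-down 19 x 15 grid used across
# the landscape and recovery tests.
medium_maps <- function() {
  memoize("medium_maps", sweep_strategy_maps(
    system_params(pendulum_length = 0.6),
    strategy_grid(n_theta0 = 19, n_freq = 15)))
}

long_stability <- function() {
  memoize("long_stability", sweep_stability(
    system_params(pendulum_length = 1.2),
    strategy_grid(n_theta0 = 19, n_freq = 15)))
}

short_stability <- function() {
  memoize("short_stability", sweep_stability(
    system_params(pendulum_length = 0.3),
    strategy_grid(n_theta0 = 19, n_freq = 15)))
}

# The Fig-style single forward simulation: medium pendulum, theta0 = -25
# deg, f = 0.5 Hz, K = 40, B = 70, A = 0.3 m, 15 s at 10 ms.
reference_trial <- function() {
  memoize("reference_trial", simulate_trial(
    system_params(pendulum_length = 0.6),
    controller_spec(stiffness = 40, damping = 70, amplitude = 0.3,
                    frequency = 0.5),
    theta0_deg = -25))
}

random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c(x = runif(1, -0.5, 0.5), v = runif(1, -1, 1),
      theta = runif(1, -pi / 2, pi / 2), omega = runif(1, -3, 3))
  })
}
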