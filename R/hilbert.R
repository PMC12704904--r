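#' Analytic signal via the FFT
#'
#' Computes the analytic signal `x + i H[x]` by zeroing the negative
#' frequencies of the discrete Fourier transform (the standard one-sided
#' spectrum construction). The signal mean is removed first: a nonzero
#' offset corrupts the instantaneous phase.
#'
#' @param x Real numeric series (length >= 4).
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  check_finite(x, "x")
  n <- length(x)
  if (n < 4) abort("signal must have length >= 4",
                   class = "cupball_invalid_input")
  if (sd(x) == 0) {
    abort("constant (degenerate) signal has no instantaneous phase",
          class = "cupball_degenerate_signal")
  }
  x <- x - mean(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Unwrap a phase series
#'
#' Removes jumps larger than pi between consecutive samples by adding
#' multiples of 2 pi.
#'
#' @param phase Phase angles in rad.
#' @return Unwrapped phase in rad.
#' @export
unwrap_phase <- function(phase) {
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phase[1], d))
}

#' Instantaneous (Hilbert) phase of a signal
#'
#' @param signal Real numeric series.
#' @param dt Sample interval in s.
#' @return A tibble with `time_s` and unwrapped `phase_rad`.
#' @export
#' @examples
#' t <- seq(0, 15, by = 0.01)
#' ph <- instantaneous_phase(cos(2 * pi * 0.5 * t), 0.01)
instantaneous_phase <- function(signal, dt) {
  z <- analytic_signal(signal)
  tibble::tibble(time_s = (seq_along(signal) - 1) * dt,
                 phase_rad = unwrap_phase(Arg(z)))
}

#' Relative (Hilbert) phase between two signals
#'
#' Unwrapped analytic-signal phase of `cup` minus that of `ball`; 0
#' indicates in-phase and pi anti-phase motion.
#'
#' @param cup,ball Real numeric series of equal length.
#' @param dt Sample interval in s.
#' @return A tibble with `time_s` and `rel_phase_rad`.
#' @export
relative_phase <- function(cup, ball, dt) {
  if (length(cup) != length(ball)) {
    abort("`cup` and `ball` must have equal length",
          class = "cupball_invalid_input")
  }
  pc <- instantaneous_phase(cup, dt)
  pb <- instantaneous_phase(ball, dt)
  tibble::tibble(time_s = pc$time_s,
                 rel_phase_rad = pc$phase_rad - pb$phase_rad)
}

#' Instantaneous frequency of a signal
#'
#' Central difference of the unwrapped Hilbert phase divided by 2 pi; the
#' two edge samples (forward/backward differences) are dropped.
#'
#' @inheritParams instantaneous_phase
#' @return A tibble with `time_s` and `freq_hz` (length `n - 2`).
#' @export
instantaneous_frequency <- function(signal, dt) {
  ph <- instantaneous_phase(signal, dt)
  n <- nrow(ph)
  i <- 2:(n - 1)
  tibble::tibble(
    time_s = ph$time_s[i],
    freq_hz = (ph$phase_rad[i + 1] - ph$phase_rad[i - 1]) / (2 * dt) / (2 * pi))
}
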