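#' Low-activation resting state
#'
#' The smallest stable fixed point at constant drive `c` (default the
#' baseline `c0`); used as the default initial condition for simulations.
#' Falls back to the smallest fixed point when none is labelled stable.
#'
#' @param params A [switch_params()] object.
#' @param c Constant drive (default `params$c0`).
#' @return Scalar state value.
#' @export
low_state <- function(params, c = params$c0) {
  eq <- fixed_points(c, params$r, params$n, hill = params$hill)
  stab <- eq$x[eq$stability == "stable"]
  if (length(stab) == 0) stab <- eq$x
  min(stab)
}

new_trajectory <- function(t, x, eta = NULL, params, x0, extra = list()) {
  out <- if (is.null(eta)) tibble(t = t, x = x) else tibble(t = t, x = x, eta = eta)
  attr(out, "params") <- params
  attr(out, "x0") <- x0
  attr(out, "dt") <- stats::median(diff(t))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("switch_trajectory", class(out))
  out
}

integrate_impl <- function(params, signal, x0, eta = numeric(0), rvec = NULL) {
  stopifnot(inherits(params, "switch_params"), inherits(signal, "switch_signal"))
  if (is.null(x0)) x0 <- low_state(params)
  stopifnot(x0 >= 0)
  dt <- signal_dt(signal)
  n_grid <- nrow(signal)
  if (is.null(rvec)) rvec <- rep(params$r, n_grid)
  x <- rk4_core(signal$c, eta, rvec, params$n, params$T, dt, x0, params$hill)
  list(x = x, x0 = x0, dt = dt)
}

#' Integrate the switch equation along an input signal
#'
#' Classical 4th-order Runge-Kutta on `T dx/dt = f(x, c(t))` over the
#' signal's uniform time grid, with the drive interpolated at RK4
#' half-steps and the state floored at zero (the origin is repelling for
#' `c >= 0`, so the floor only guards round-off).
#'
#' @param params A [switch_params()] object.
#' @param signal A `switch_signal` (see e.g. [pulses_to_calcium()]).
#' @param x0 Initial state; defaults to the low stable state at `c0`.
#' @return A tibble of class `switch_trajectory` with columns `t`, `x`.
#' @examples
#' p <- switch_params(r = 0.7, c0 = 0.04)
#' sig <- sinusoidal_input(0.04, 0, duration = 1)
#' tail(simulate_switch(p, sig), 1)
#' @export
simulate_switch <- function(params, signal, x0 = NULL) {
  res <- integrate_impl(params, signal, x0)
  new_trajectory(signal$t, res$x, NULL, params, res$x0)
}

#' Integrate with additive Ornstein-Uhlenbeck noise on the drive
#'
#' The noise path `eta(t)` is advanced by stochastic Euler on the same grid
#' and held constant within each RK4 step; the total drive `c(t) + eta(t)`
#' is floored at zero before entering the drift (the fraction of floored
#' steps is recorded in `attr(, "floored_frac")`). With `sigma = 0` the
#' result is identical to [simulate_switch()].
#'
#' @inheritParams simulate_switch
#' @param sigma OU noise amplitude.
#' @param tau_eta OU correlation time in seconds.
#' @param bound Truncation of the driving Gaussian in standard deviations.
#' @param seed Optional integer seed for the noise stream.
#' @return A `switch_trajectory` tibble with columns `t`, `x`, `eta`.
#' @export
simulate_switch_noisy <- function(params, signal, sigma, tau_eta = 0.01,
                                  bound = 5, seed = NULL, x0 = NULL) {
  dt <- signal_dt(signal)
  duration <- (nrow(signal) - 1) * dt
  eta <- if (sigma == 0) {
    rep(0, nrow(signal))
  } else {
    ou_noise_path(sigma, tau_eta, duration, dt, bound, seed)$eta
  }
  res <- integrate_impl(params, signal, x0, eta = eta)
  new_trajectory(signal$t, res$x, eta, params, res$x0,
                 extra = list(sigma = sigma, tau_eta = tau_eta, seed = seed,
                              floored_frac = mean(signal$c + eta < 0)))
}

#' Integrate with a linear ramp on the negative-regulation rate
#'
#' `r(t)` increases (or decreases) linearly from `r_start` to `r_end` over
#' `[0, stim_end]` and stays at `r_end` afterwards, modelling slowly
#' accumulating phosphatase activity over the course of a stimulus.
#' With `r_start == r_end` the result is identical to [simulate_switch()]
#' at that fixed rate.
#'
#' @inheritParams simulate_switch
#' @param r_start,r_end Ramp endpoints (`>= 0`).
#' @param stim_end End of the ramp in seconds (default: end of the signal).
#' @return A `switch_trajectory` tibble.
#' @export
simulate_switch_ramped <- function(params, signal, r_start, r_end,
                                   stim_end = max(signal$t), x0 = NULL) {
  stopifnot(r_start >= 0, r_end >= 0, stim_end > 0)
  frac <- pmin(signal$t / stim_end, 1)
  rvec <- r_start + (r_end - r_start) * frac
  p0 <- params
  p0$r <- r_start
  res <- integrate_impl(p0, signal, x0, rvec = rvec)
  new_trajectory(signal$t, res$x, NULL, params, res$x0,
                 extra = list(r_start = r_start, r_end = r_end,
                              stim_end = stim_end))
}
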