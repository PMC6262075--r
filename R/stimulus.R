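new_switch_signal <- function(t, c, dt, c0, delta_c = NA_real_, kernel = "none",
                              extra = list()) {
  out <- tibble(t = t, c = c)
  attr(out, "dt") <- dt
  attr(out, "c0") <- c0
  attr(out, "delta_c") <- delta_c
  attr(out, "kernel") <- kernel
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("switch_signal", class(out))
  out
}

signal_dt <- function(signal) {
  attr(signal, "dt") %||% stats::median(diff(signal$t))
}

#' Poisson pulse train
#'
#' Homogeneous Poisson process of calcium pulse times on `[0, duration]`:
#' inter-pulse intervals are i.i.d. exponential with the given rate. With
#' `seed` supplied the train is reproducible and the global RNG state is
#' left untouched.
#'
#' @param rate Pulse rate in Hz (`>= 0`; 0 gives an empty train).
#' @param duration Train duration in seconds.
#' @param seed Optional integer seed.
#' @return A tibble of class `pulse_train` with column `time` (sorted pulse
#'   times in seconds); `rate`, `duration` and `seed` are kept as attributes.
#' @examples
#' poisson_pulse_train(8, 10, seed = 1)
#' @export
poisson_pulse_train <- function(rate, duration, seed = NULL) {
  stopifnot(rate >= 0, duration > 0)
  gen <- function() {
    if (rate == 0) return(numeric(0))
    # draw in blocks until past the horizon
    times <- numeric(0)
    last <- 0
    while (last <= duration) {
      gaps <- rexp(max(64, ceiling(rate * duration / 4)), rate)
      times <- c(times, last + cumsum(gaps))
      last <- times[length(times)]
    }
    times[times <= duration]
  }
  times <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble(time = times)
  attr(out, "rate") <- rate
  attr(out, "duration") <- duration
  attr(out, "seed") <- seed
  class(out) <- c("pulse_train", class(out))
  out
}

#' Regular (periodic) pulse train
#'
#' @param rate Pulse rate in Hz (`> 0`).
#' @param n_pulses Number of pulses; the first lands at `t = 0`.
#' @param duration Optional total duration (defaults to `n_pulses / rate`).
#' @return A `pulse_train` tibble, as from [poisson_pulse_train()].
#' @export
regular_pulse_train <- function(rate, n_pulses, duration = n_pulses / rate) {
  stopifnot(rate > 0, n_pulses >= 1)
  out <- tibble(time = (seq_len(n_pulses) - 1) / rate)
  attr(out, "rate") <- rate
  attr(out, "duration") <- duration
  attr(out, "seed") <- NULL
  class(out) <- c("pulse_train", class(out))
  out
}

# place pulses on the uniform grid as unit impulses (snapped to nearest point)
impulse_grid <- function(times, n_grid, dt) {
  imp <- numeric(n_grid)
  if (length(times) == 0) return(imp)
  idx <- pmin(pmax(round(times / dt) + 1, 1), n_grid)
  tab <- table(idx)
  imp[as.integer(names(tab))] <- as.numeric(tab)
  imp
}

#' Calcium signal from a pulse train via an alpha-function kernel
#'
#' Convolves the pulse train with the causal alpha kernel
#' `k(t) = (t - t_i) exp(-(t - t_i)/tau_c)` for `t >= t_i`, normalizes the
#' summed response to its realized maximum, scales by `delta_c`, and adds the
#' baseline: `c(t) = c0 + delta_c * g(t)/max(g)`. Consequently for any
#' non-empty train `max(c) = c0 + delta_c` exactly, and a single isolated
#' pulse peaks at `t_i + tau_c`. The 30 ms default decay reflects the time
#' course of local synaptic calcium transients.
#'
#' @param train A `pulse_train`.
#' @param tau_c Kernel decay constant in seconds (default 0.03).
#' @param delta_c Peak amplitude added on top of `c0` (`>= 0`).
#' @param c0 Baseline drive.
#' @param dt Grid step in seconds (default 0.001).
#' @param duration Signal duration; defaults to the train's duration.
#' @return A `switch_signal` tibble with columns `t`, `c`.
#' @examples
#' tr <- poisson_pulse_train(8, 5, seed = 1)
#' sig <- pulses_to_calcium(tr)
#' max(sig$c)  # c0 + delta_c = 0.54
#' @export
pulses_to_calcium <- function(train, tau_c = 0.03, delta_c = 0.5, c0 = 0.04,
                              dt = 0.001, duration = attr(train, "duration")) {
  stopifnot(inherits(train, "pulse_train"), tau_c > 0, delta_c >= 0, dt > 0)
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  if (nrow(train) == 0) {
    return(new_switch_signal(tgrid, rep(c0, n_grid), dt, c0, delta_c, "alpha",
                             list(tau_c = tau_c, train_seed = attr(train, "seed"))))
  }
  imp <- impulse_grid(train$time, n_grid, dt)
  lk <- ceiling(15 * tau_c / dt)
  kt <- (0:lk) * dt
  kern <- kt * exp(-kt / tau_c)
  g <- stats::convolve(imp, rev(kern), type = "open")[seq_len(n_grid)]
  g[g < 0] <- 0  # FFT round-off
  cvals <- c0 + delta_c * g / max(g)
  new_switch_signal(tgrid, cvals, dt, c0, delta_c, "alpha",
                    list(tau_c = tau_c, train_seed = attr(train, "seed"),
                         pulse_times = train$time))
}

#' Sinusoidal calcium drive
#'
#' `c(t) = c0 + alpha * sin(2 pi phi t)`. A warning is issued when
#' `alpha > c0`, since the drive then dips below zero, violating the
#' physiological constraint `c(t) >= 0` (the integrators floor the total
#' drive at zero regardless).
#'
#' @param c0 Baseline drive.
#' @param alpha Oscillation amplitude.
#' @param phi Frequency in Hz.
#' @param duration Signal duration in seconds.
#' @param dt Grid step in seconds.
#' @return A `switch_signal` tibble.
#' @examples
#' sig <- sinusoidal_input(0.04, 0.02, 2, duration = 2)
#' range(sig$c)  # 0.02 .. 0.06
#' @export
sinusoidal_input <- function(c0 = 0.04, alpha = 0.02, phi = 2, duration, dt = 0.001) {
  stopifnot(c0 >= 0, alpha >= 0, phi >= 0, duration > 0, dt > 0)
  if (alpha > c0) warn("`alpha` > `c0`: the drive dips below zero and will be floored")
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  cvals <- c0 + alpha * sin(2 * pi * phi * tgrid)
  new_switch_signal(tgrid, cvals, dt, c0, alpha, "sinusoid",
                    list(phi = phi, alpha = alpha))
}

#' Calcium signal as superposed first-order exponential decays
#'
#' Each pulse contributes `delta_c * exp(-(t - t_i)/tau)` for `t >= t_i`,
#' summed linearly with no normalization (unlike [pulses_to_calcium()]):
#' a pulse raises the drive by `delta_c` instantaneously and the elevation
#' decays with e-folding time `tau`. The 200 ms default matches measured
#' dendritic calcium decay under repetitive stimulation.
#'
#' @param train A `pulse_train`.
#' @param tau Decay time constant in seconds.
#' @inheritParams pulses_to_calcium
#' @return A `switch_signal` tibble.
#' @export
exp_decay_calcium <- function(train, tau = 0.2, delta_c = 0.5, c0 = 0,
                              dt = 0.001, duration = attr(train, "duration")) {
  stopifnot(inherits(train, "pulse_train"), tau > 0, delta_c >= 0, dt > 0)
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  imp <- impulse_grid(train$time, n_grid, dt) * delta_c
  a <- exp(-dt / tau)
  cl <- as.numeric(stats::filter(imp, a, method = "recursive"))
  new_switch_signal(tgrid, c0 + cl, dt, c0, delta_c, "exp_decay",
                    list(tau = tau, train_seed = attr(train, "seed"),
                         pulse_times = train$time))
}

#' Ornstein-Uhlenbeck noise path
#'
#' Mean-reverting noise `d eta/ds = -eta + sigma xi(s)` written in units of
#' its own correlation time (`s = t / tau_eta`) and integrated by the
#' stochastic Euler (Euler-Maruyama) scheme on the simulation grid:
#' `eta[k+1] = eta[k] - (eta[k]/tau_eta) dt + sigma sqrt(dt/tau_eta) xi[k]`,
#' where `xi` are standard normal deviates bounded at `± bound` standard
#' deviations. Under this normalization `sigma` directly sets the process
#' amplitude in drive units: the stationary variance is `sigma^2 / 2`
#' independent of the step size, while the autocorrelation decays with time
#' constant `tau_eta`. The 10 ms default correlation time is an upper bound
#' for noisy microdomain calcium fluctuations.
#'
#' @param sigma Noise amplitude scale (`>= 0`).
#' @param tau_eta Correlation time in seconds (`> 0`; must exceed `dt`,
#'   otherwise the explicit Euler update is unstable and an error is thrown).
#' @param duration Path duration in seconds.
#' @param dt Grid step in seconds.
#' @param bound Truncation of the driving Gaussian, in standard deviations.
#' @param seed Optional integer seed (reproducible; global RNG untouched).
#' @param eta0 Initial value.
#' @return A tibble of class `ou_path` with columns `t`, `eta`.
#' @examples
#' ou <- ou_noise_path(0.1, duration = 1, seed = 1)
#' @export
ou_noise_path <- function(sigma, tau_eta = 0.01, duration, dt = 0.001,
                          bound = 5, seed = NULL, eta0 = 0) {
  stopifnot(sigma >= 0, tau_eta > 0, duration > 0, dt > 0, bound > 0)
  if (dt >= tau_eta) abort("`dt` must be smaller than `tau_eta` (unstable discretization)")
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  gen <- function() {
    xi <- pmin(pmax(rnorm(n_grid - 1), -bound), bound)
    b <- sigma * sqrt(dt / tau_eta) * xi
    a <- 1 - dt / tau_eta
    c(eta0, as.numeric(stats::filter(b, a, method = "recursive", init = eta0)))
  }
  eta <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble(t = tgrid, eta = eta)
  attr(out, "sigma") <- sigma
  attr(out, "tau_eta") <- tau_eta
  attr(out, "dt") <- dt
  attr(out, "bound") <- bound
  attr(out, "seed") <- seed
  class(out) <- c("ou_path", class(out))
  out
}
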