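# deterministic sub-seeds derived from a master seed (all < 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

#' Secant slope of the Hill activation term
#'
#' The quantity `p(u, x, n) = (u^n - x^n) / ((u - x)(1 + u^n)(1 + x^n))`
#' controls whether two solutions of the switch equation sharing the same
#' drive converge: the gap contracts wherever `r > p`. On the diagonal
#' `u = x` the removable singularity is filled with the limit
#' `n x^(n-1) / (1 + x^n)^2` (the derivative of the Hill term). For `n = 2`
#' the expression simplifies to `(u + x) / ((1 + u^2)(1 + x^2))`.
#'
#' @param u,x Positive state values (recycled against each other).
#' @param n Hill exponent, `> 0`.
#' @param tol Width of the diagonal band where the limit form is used.
#' @return Numeric vector; symmetric in `(u, x)` and continuous across
#'   `u = x`.
#' @examples
#' p_uniqueness(1, 1, 2)  # 1/2
#' @export
p_uniqueness <- function(u, x, n, tol = 1e-9) {
  if (any(u <= 0) || any(x <= 0)) abort("`u` and `x` must be > 0")
  stopifnot(n > 0)
  k <- pmax(length(u), length(x))
  u <- rep_len(u, k)
  x <- rep_len(x, k)
  out <- numeric(k)
  on_diag <- abs(u - x) < tol
  if (any(on_diag)) {
    xd <- x[on_diag]
    out[on_diag] <- n * xd^(n - 1) / (1 + xd^n)^2
  }
  if (any(!on_diag)) {
    uo <- u[!on_diag]; xo <- x[!on_diag]
    out[!on_diag] <- (uo^n - xo^n) / ((uo - xo) * (1 + uo^n) * (1 + xo^n))
  }
  out
}

#' Global maximum of the convergence expression
#'
#' Maximizes `p(u, x, n)` over positive `u, x`. The maximum lies on the
#' diagonal `u = x`, so the search reduces to maximizing
#' `q(x) = n x^(n-1) / (1 + x^n)^2` over `x > 0`. For `n > 1` the maximum is
#' interior and found by 1-D optimization; for `n = 1` the supremum is 1,
#' approached as `x -> 0+`, and for `n < 1` the expression is unbounded near
#' the origin — both are reported with `boundary = TRUE`. At `n = 2` the
#' maximum is `3 sqrt(3) / 8 ~ 0.6495`, attained at `x = 1/sqrt(3)`: a
#' negative-regulation rate exceeding this value guarantees global
#' convergence to a unique input-driven solution.
#'
#' @param n Hill exponent, `> 0`.
#' @return A list with `n`, `x_at_max`, `value`, and `boundary` (TRUE when
#'   the supremum is attained only in the limit `x -> 0+`).
#' @examples
#' max_p(2)$value     # 3*sqrt(3)/8
#' @export
max_p <- function(n) {
  stopifnot(length(n) == 1, n > 0)
  if (n < 1) {
    return(list(n = n, x_at_max = 0, value = Inf, boundary = TRUE))
  }
  if (n == 1) {
    return(list(n = n, x_at_max = 0, value = 1, boundary = TRUE))
  }
  q <- function(x) n * x^(n - 1) / (1 + x^n)^2
  opt <- optimize(q, c(1e-9, 100), maximum = TRUE, tol = 1e-12)
  list(n = n, x_at_max = opt$maximum, value = opt$objective, boundary = FALSE)
}

#' Hill exponent minimizing the convergence threshold
#'
#' Minimizes `max_p(n)` over `n` in `[n_lo, n_hi]`: the exponent requiring
#' the least negative regulation to guarantee a unique input-driven
#' response. A coarse grid scan brackets the minimum and golden-section
#' refinement (tolerance 1e-4) polishes it; the result is reported rounded
#' to two decimals alongside the raw minimizer. The expression is unbounded
#' for `n < 1`, so the effective search starts above 1 when `n_lo` is
#' smaller; highly uncooperative exponents are excluded by construction.
#'
#' @param n_lo,n_hi Search interval, `0.012 < n_lo < n_hi`.
#' @return A list with `n_star` (rounded to 2 decimals), `n_star_raw`,
#'   `value` (`max_p` at the minimizer), and `boundary` (TRUE when the
#'   minimum sits on an interval endpoint).
#' @examples
#' argmin_max_p(1.2, 4)$n_star
#' @export
argmin_max_p <- function(n_lo = 0.1, n_hi = 4) {
  stopifnot(n_lo > 0.012, n_hi > n_lo)
  lo <- max(n_lo, 1 + 1e-6)
  if (lo >= n_hi) {
    # entire interval below/at n = 1: supremum decreasing in n, so boundary
    v <- max_p(n_hi)
    return(list(n_star = round(n_hi, 2), n_star_raw = n_hi, value = v$value,
                boundary = TRUE))
  }
  grid <- seq(lo, n_hi, length.out = 200)
  vals <- vapply(grid, function(n) max_p(n)$value, numeric(1))
  i <- which.min(vals)
  if (i == 1 || i == length(grid)) {
    n_raw <- grid[i]
    return(list(n_star = round(n_raw, 2), n_star_raw = n_raw, value = vals[i],
                boundary = TRUE))
  }
  opt <- optimize(function(n) max_p(n)$value, c(grid[i - 1], grid[i + 1]),
                  tol = 1e-4)
  list(n_star = round(opt$minimum, 2), n_star_raw = opt$minimum,
       value = opt$objective, boundary = FALSE)
}

#' Exponential convergence bound between two trajectories
#'
#' For two solutions `u(t)`, `x(t)` of the same switch equation under the
#' same drive, the gap obeys
#' `|u(t) - x(t)| <= |u(0) - x(0)| exp(-(r - max_p(n)) t / T)`
#' (a Gronwall bound). This function evaluates the bound along the shared
#' grid and returns its margin over the observed gap; the margin is
#' non-negative everywhere (up to integrator tolerance) whenever
#' `r > max_p(n)`.
#'
#' @param u_traj,x_traj `switch_trajectory` objects on identical grids,
#'   integrated under the same parameters and input.
#' @param params The shared [switch_params()].
#' @return A tibble with columns `t`, `gap` (`|u - x|`), `bound`, `margin`
#'   (`bound - gap`); the contraction rate is stored in `attr(, "rate")`.
#' @export
gronwall_check <- function(u_traj, x_traj, params) {
  if (nrow(u_traj) != nrow(x_traj) || max(abs(u_traj$t - x_traj$t)) > 1e-12)
    abort("trajectories must share the same time grid")
  rate <- (params$r - max_p(params$n)$value) / params$T
  z0 <- abs(u_traj$x[1] - x_traj$x[1])
  gap <- abs(u_traj$x - x_traj$x)
  bound <- z0 * exp(-rate * u_traj$t)
  out <- tibble(t = u_traj$t, gap = gap, bound = bound, margin = bound - gap)
  attr(out, "rate") <- rate
  out
}

#' Per-interval switch increments between pulses
#'
#' For each inter-pulse interval `(t_i, t_{i+1}]` of a pulse train, the
#' increment is the maximum of `x` over the interval minus `x` sampled at
#' the pulse time `t_i` — the rise of the switch response evoked by that
#' pulse before the next one arrives.
#'
#' @param traj A `switch_trajectory` covering all pulse times.
#' @param train A `pulse_train` with at least 2 pulses (fewer gives an
#'   empty result).
#' @return A tibble with columns `interval`, `t_start`, `t_end`, `delta`.
#' @export
interval_deltas <- function(traj, train) {
  times <- train$time
  if (length(times) < 2) {
    return(tibble(interval = integer(0), t_start = numeric(0),
                  t_end = numeric(0), delta = numeric(0)))
  }
  if (max(times) > max(traj$t) + 1e-9) abort("trajectory does not cover all pulse times")
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  idx <- pmin(pmax(round(times / dt) + 1, 1), nrow(traj))
  x <- traj$x
  m <- length(times) - 1
  delta <- numeric(m)
  for (i in seq_len(m)) {
    seg <- x[(idx[i] + 1):idx[i + 1]]
    delta[i] <- max(seg) - x[idx[i]]
  }
  tibble(interval = seq_len(m), t_start = times[-length(times)],
         t_end = times[-1], delta = delta)
}

#' Paired-arm discrepancy of pulse-evoked increments
#'
#' Quantifies how similar the pulse-by-pulse responses of two switches are
#' when they share identical random input but sit around different states.
#' Per trial a Poisson pulse train is drawn once and drives two integrations
#' differing only in baseline: a reference arm (`c0_ref`, monostable low)
#' and an alternative arm (`c0_alt`, which input can trap in the high state
#' through hysteresis). For each shared inter-pulse interval the increments
#' `delta_x`, `delta_u` of the two arms are compared and the grand mean of
#' `|delta_u - delta_x|` over all intervals and trials is reported per `r`.
#'
#' @param r_values Negative-regulation rates to sweep.
#' @param n,T Model exponent and timescale.
#' @param rate,duration Poisson train rate (Hz) and trial length (s).
#' @param trials Trials per `r` (pulse trains are shared across `r`).
#' @param c0_ref,c0_alt Baselines of the two arms.
#' @param delta_c,tau_c,dt Calcium-signal settings (see [pulses_to_calcium()]).
#' @param seed Master seed; trial trains derive from it deterministically.
#' @return A tibble of class `discrepancy_result` with columns `r`,
#'   `discrepancy`, `n_intervals`, `trials`.
#' @export
discrepancy_experiment <- function(r_values, n = 2, T = 0.01, rate = 8,
                                   duration = 100, trials = 10,
                                   c0_ref = 0.02, c0_alt = 0.04,
                                   delta_c = 0.5, tau_c = 0.03, dt = 0.001,
                                   seed = NULL) {
  seeds <- derive_seeds(seed, trials)
  trains <- lapply(seeds, function(s) poisson_pulse_train(rate, duration, seed = s))
  sig_ref <- lapply(trains, pulses_to_calcium, tau_c = tau_c, delta_c = delta_c,
                    c0 = c0_ref, dt = dt)
  sig_alt <- lapply(trains, pulses_to_calcium, tau_c = tau_c, delta_c = delta_c,
                    c0 = c0_alt, dt = dt)
  rows <- lapply(r_values, function(r) {
    p_ref <- switch_params(r = r, c0 = c0_ref, n = n, T = T)
    p_alt <- switch_params(r = r, c0 = c0_alt, n = n, T = T)
    diffs <- numeric(0)
    for (k in seq_len(trials)) {
      dx <- interval_deltas(simulate_switch(p_ref, sig_ref[[k]]), trains[[k]])$delta
      du <- interval_deltas(simulate_switch(p_alt, sig_alt[[k]]), trains[[k]])$delta
      diffs <- c(diffs, abs(du - dx))
    }
    tibble(r = r, discrepancy = mean(diffs), n_intervals = length(diffs),
           trials = trials)
  })
  out <- bind_rows(rows)
  class(out) <- c("discrepancy_result", class(out))
  out
}

# Hann-windowed periodogram; power returned per frequency bin
periodogram_power <- function(v, dt) {
  n <- length(v)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  vw <- (v - mean(v)) * w
  sp <- Mod(fft(vw))^2
  nf <- floor(n / 2) + 1
  list(freq = (seq_len(nf) - 1) / (n * dt), power = sp[seq_len(nf)])
}

power_at <- function(v, dt, f) {
  pg <- periodogram_power(v, dt)
  pg$power[which.min(abs(pg$freq - f))]
}

#' Spectral gain of the switch at the drive frequency
#'
#' The frequency-transfer measure for stochastic resonance: the Hann-window
#' periodogram power of the switch trajectory at the frequency bin nearest
#' `phi`, divided by the power of the noiseless input signal at the same
#' bin. An identical trajectory and signal give gain 1.
#'
#' @param traj A `switch_trajectory`.
#' @param signal The (noiseless) `switch_signal` that drove it.
#' @param phi Probe frequency in Hz; must lie below the Nyquist frequency.
#' @return Scalar gain `P_x(phi) / P_c(phi)`.
#' @export
spectral_gain <- function(traj, signal, phi) {
  dt <- signal_dt(signal)
  if (phi >= 1 / (2 * dt)) abort("`phi` is at or above the Nyquist frequency")
  power_at(traj$x, dt, phi) / power_at(signal$c, dt, phi)
}

#' Stochastic-resonance sweep over noise amplitude
#'
#' Drives the switch with a weak sinusoid `c0 + alpha sin(2 pi phi t)` plus
#' additive OU noise, and measures the spectral gain at `phi` as a function
#' of the noise amplitude `sigma`. Stochastic resonance shows as a
#' non-monotone gain curve with an interior maximum at the optimal noise
#' level `sigma_p`. Gains are averaged over `trials` noise realizations per
#' `sigma`, with common random numbers across the `sigma` grid (trial `j`
#' reuses one noise seed at every `sigma`, so the noise path scales linearly
#' with `sigma` within a trial): gain fluctuations are then strongly
#' correlated between neighbouring grid points, which stabilizes the argmax
#' without biasing the per-`sigma` means. A bootstrap over trials gives an
#' interval for `sigma_p`.
#'
#' @param params A [switch_params()]; its `c0` is used as the baseline.
#' @param sigma_grid Noise amplitudes to probe (default 30 log-spaced values
#'   in `[0.005, 1]`).
#' @param trials Noise realizations per `sigma`.
#' @param duration Trial length in seconds.
#' @param alpha,phi Sinusoid amplitude and frequency (Hz).
#' @param tau_eta,bound OU noise settings.
#' @param dt Grid step in seconds.
#' @param seed Master seed; per-(sigma, trial) noise seeds derive from it.
#' @param boot Bootstrap resamples for the `sigma_p` interval (0 disables).
#' @return A tibble of class `sr_result` with columns `sigma`, `gain`,
#'   `gain_se`; attributes `sigma_p` (argmax), `sigma_p_ci` (bootstrap
#'   percentile interval), `trial_gains` (matrix), and the sweep settings.
#' @examples
#' \donttest{
#' p <- switch_params(r = 0.65, c0 = 0.04, n = 2)
#' sr <- sr_sweep(p, sigma_grid = c(0.05, 0.3, 1), trials = 2,
#'                duration = 20, seed = 1)
#' glance(sr)
#' }
#' @export
sr_sweep <- function(params, sigma_grid = exp(seq(log(0.005), log(1),
                                                  length.out = 30)),
                     trials = 10, duration = 200, alpha = 0.02, phi = 2,
                     tau_eta = 0.01, bound = 5, dt = 0.001, seed = NULL,
                     boot = 200) {
  stopifnot(inherits(params, "switch_params"))
  signal <- sinusoidal_input(params$c0, alpha, phi, duration, dt)
  pc <- power_at(signal$c, dt, phi)
  seeds <- derive_seeds(seed, trials)
  x0 <- low_state(params)
  gains <- matrix(NA_real_, nrow = length(sigma_grid), ncol = trials)
  for (i in seq_along(sigma_grid)) {
    for (j in seq_len(trials)) {
      tr <- simulate_switch_noisy(params, signal, sigma_grid[i], tau_eta,
                                  bound, seed = seeds[[j]], x0 = x0)
      gains[i, j] <- power_at(tr$x, dt, phi) / pc
    }
  }
  gain <- rowMeans(gains)
  out <- tibble(sigma = sigma_grid, gain = gain,
                gain_se = apply(gains, 1, sd) / sqrt(trials))
  sigma_p <- sigma_grid[which.max(gain)]
  ci <- c(NA_real_, NA_real_)
  if (boot > 0 && trials > 1) {
    bs <- withr::with_seed(1L, replicate(boot, {
      pick <- sample.int(trials, trials, replace = TRUE)
      sigma_grid[which.max(rowMeans(gains[, pick, drop = FALSE]))]
    }))
    ci <- unname(quantile(bs, c(0.025, 0.975)))
  }
  attr(out, "sigma_p") <- sigma_p
  attr(out, "sigma_p_ci") <- ci
  attr(out, "trial_gains") <- gains
  attr(out, "params") <- params
  attr(out, "settings") <- list(alpha = alpha, phi = phi, tau_eta = tau_eta,
                                trials = trials, duration = duration, dt = dt,
                                seed = seed)
  class(out) <- c("sr_result", class(out))
  out
}

#' Map of optimal noise amplitude over a parameter grid
#'
#' Runs [sr_sweep()] at every cell of a two-parameter grid — either
#' `(n, r)` or `(c0, r)` — and records the optimal noise level `sigma_p`
#' together with a flag for whether stochastic resonance is present at all
#' (an interior gain maximum that beats the low-noise gain; cells with a
#' monotone or boundary-peaked gain curve are flagged absent).
#'
#' @param r_values Grid of negative-regulation rates.
#' @param n_values Grid of Hill exponents (used when `c0_values` is NULL).
#' @param c0_values Optional grid of baselines (then `n` is fixed at `n_fix`).
#' @param n_fix,c0_fix Fixed values for the axis not being swept.
#' @param ... Passed to [sr_sweep()] (grids, trials, duration, seed, ...).
#' @return A tibble with columns `n` or `c0`, `r`, `sigma_p`, `peak_gain`,
#'   `sr_present`.
#' @export
sr_map <- function(r_values, n_values = NULL, c0_values = NULL,
                   n_fix = 2, c0_fix = 0.04, ...) {
  if (is.null(n_values) && is.null(c0_values))
    abort("supply `n_values` or `c0_values`")
  axis <- if (!is.null(n_values)) "n" else "c0"
  vals <- if (axis == "n") n_values else c0_values
  rows <- list()
  for (v in vals) {
    for (r in r_values) {
      params <- if (axis == "n") {
        switch_params(r = r, c0 = c0_fix, n = v)
      } else {
        switch_params(r = r, c0 = v, n = n_fix)
      }
      sr <- sr_sweep(params, ...)
      i_max <- which.max(sr$gain)
      interior <- i_max > 1 && i_max < nrow(sr)
      present <- interior && sr$gain[i_max] > 1.5 * sr$gain[1]
      row <- tibble(r = r, sigma_p = if (present) attr(sr, "sigma_p") else NA_real_,
                    peak_gain = max(sr$gain), sr_present = present)
      row[[axis]] <- v
      rows[[length(rows) + 1]] <- row
    }
  }
  bind_rows(rows)[, c(axis, "r", "sigma_p", "peak_gain", "sr_present")]
}

#' Activation histogram with Freedman-Diaconis bins
#'
#' Histogram of post-burn-in switch activation with bin widths set by the
#' Freedman-Diaconis rule (`2 IQR n^(-1/3)`). Modality is the number of
#' prominent modes: local maxima of the moving-average-smoothed counts,
#' discarding peaks below `min_height` of the tallest and merging adjacent
#' peaks whose connecting valley stays above `prominence` times the smaller
#' peak — a reproducible stand-in for visual uni-/bimodality that is robust
#' to bin-level noise in long records.
#'
#' @param traj A `switch_trajectory`.
#' @param burn_in Seconds of initial transient to discard.
#' @param smooth_bins Width (bins) of the moving-average smoother.
#' @param min_height Minimum peak height as a fraction of the tallest peak.
#' @param prominence Valley-to-peak ratio above which neighbouring peaks are
#'   merged into one mode.
#' @return A list of class `activation_histogram` with `breaks`, `counts`,
#'   `mids`, `modality`, `n`.
#' @export
activation_histogram <- function(traj, burn_in = 10, smooth_bins = 5,
                                 min_height = 0.05, prominence = 0.8) {
  x <- traj$x[traj$t >= burn_in]
  n <- length(x)
  if (n < 2) abort("too few post-burn-in samples")
  iqr <- stats::IQR(x)
  if (iqr == 0 || diff(range(x)) == 0) {
    h <- list(breaks = range(x) + c(-0.5, 0.5) * max(1e-9, abs(x[1]) * 1e-6),
              counts = n, mids = x[1])
    out <- list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                modality = 1L, n = n)
    class(out) <- "activation_histogram"
    return(out)
  }
  width <- 2 * iqr / n^(1 / 3)
  breaks <- seq(min(x), max(x) + width, by = width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  sm <- stats::filter(h$counts, rep(1 / smooth_bins, smooth_bins), sides = 2)
  sm[is.na(sm)] <- h$counts[is.na(sm)]
  sm <- as.numeric(sm)
  modality <- count_modes(sm, min_height, prominence)
  out <- list(breaks = h$breaks, counts = h$counts, mids = h$mids,
              modality = as.integer(modality), n = n)
  class(out) <- "activation_histogram"
  out
}

count_modes <- function(sm, min_height, prominence) {
  k <- length(sm)
  pad <- c(-Inf, sm, -Inf)
  pk <- which(pad[2:(k + 1)] >= pad[1:k] & pad[2:(k + 1)] > pad[3:(k + 2)])
  pk <- pk[sm[pk] >= min_height * max(sm)]
  repeat {
    if (length(pk) < 2) break
    drop <- NULL
    for (i in seq_len(length(pk) - 1)) {
      valley <- min(sm[pk[i]:pk[i + 1]])
      if (valley > prominence * min(sm[pk[i]], sm[pk[i + 1]])) {
        drop <- pk[i + (sm[pk[i]] > sm[pk[i + 1]])]
        break
      }
    }
    if (is.null(drop)) break
    pk <- setdiff(pk, drop)
  }
  length(pk)
}

#' @export
print.activation_histogram <- function(x, ...) {
  cat("<activation_histogram> ", length(x$counts), "bins,", x$n,
      "samples, modality", x$modality, "\n")
  invisible(x)
}

#' Burst-detection protocol with a history-dependent threshold
#'
#' Drives a bistable-capable switch with a sparse pulse sequence while the
#' residual calcium baseline follows a step schedule, and labels every time
#' step low/high relative to the separatrix — the unstable fixed point at
#' the instantaneous baseline `c0(t)`. Sufficiently closely spaced pulses
#' (a burst) carry the state across the separatrix; hysteresis through an
#' elevated baseline then holds the high state. When the instantaneous
#' baseline is monostable the most recent bistable separatrix is retained.
#'
#' @param pulse_times Pulse times in seconds.
#' @param c0_schedule A data frame with columns `time`, `c0`: the baseline
#'   takes value `c0` from `time` onwards (first row should start at 0).
#' @param r,n,T Model parameters (`r` below its critical value so the
#'   augmented baseline supports bistability).
#' @param delta_c Peak amplitude of the normalized pulse response. The
#'   default 0.12 is calibrated (at the default `r = 0.54`, `n = 2`,
#'   `T = 0.01`) so the peak drive exceeds the upper saddle-node yet a
#'   single 30 ms transient is too brief to transit the activation
#'   bottleneck: one isolated pulse cannot carry the state across the
#'   separatrix while a 10 Hz pulse pair can.
#' @param tau_c,dt As in [pulses_to_calcium()].
#' @param duration Total protocol duration in seconds.
#' @return A `switch_trajectory` tibble with extra columns `c`, `c0`,
#'   `separatrix`, `state` (`"low"`/`"high"`).
#' @export
burst_detection_protocol <- function(pulse_times, c0_schedule, r = 0.54,
                                     n = 2, T = 0.01, delta_c = 0.12,
                                     tau_c = 0.03, dt = 0.001,
                                     duration = max(pulse_times) + 1) {
  stopifnot(is.data.frame(c0_schedule), all(c("time", "c0") %in% names(c0_schedule)))
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  sched <- c0_schedule[order(c0_schedule$time), ]
  c0_t <- sched$c0[findInterval(tgrid, sched$time, rightmost.closed = FALSE)]
  c0_t[is.na(c0_t)] <- sched$c0[1]
  # normalized pulse component, independent of the baseline schedule
  train <- tibble(time = sort(pulse_times))
  attr(train, "duration") <- duration
  class(train) <- c("pulse_train", class(train))
  base <- pulses_to_calcium(train, tau_c, delta_c, c0 = 0, dt = dt,
                            duration = duration)
  cvals <- c0_t + base$c
  signal <- new_switch_signal(tgrid, cvals, dt, c0 = NA_real_, delta_c, "alpha",
                              list(tau_c = tau_c))
  params <- switch_params(r = r, c0 = sched$c0[1], n = n, T = T)
  x0 <- low_state(params, c = c0_t[1])
  traj <- simulate_switch(params, signal, x0 = x0)
  # separatrix per distinct baseline value; carry the last bistable one
  sep_of <- vapply(unique(c0_t), function(cc) {
    eq <- fixed_points(max(cc, 1e-12), r, n)
    if (sum(eq$stability == "unstable" & !eq$saddle_node) >= 1 && nrow(eq) == 3)
      eq$x[2] else NA_real_
  }, numeric(1))
  names(sep_of) <- as.character(unique(c0_t))
  sep_t <- unname(sep_of[as.character(c0_t)])
  # forward-fill the most recent bistable separatrix
  filled <- sep_t
  last <- NA_real_
  for (i in seq_along(filled)) {
    if (!is.na(filled[i])) last <- filled[i] else filled[i] <- last
  }
  state <- unname(ifelse(is.na(filled), "low",
                         ifelse(traj$x > filled, "high", "low")))
  out <- traj
  out$c <- cvals
  out$c0 <- c0_t
  out$separatrix <- unname(filled)
  out$state <- state
  out
}

#' Offset minimizing the Euclidean distance between two traces
#'
#' The scalar `o` minimizing `||a - (b + o)||` has the closed form
#' `o = mean(a - b)`; used to overlay fluctuation traces that ride on
#' different stable states.
#'
#' @param a,b Equal-length numeric vectors (or `switch_trajectory` objects,
#'   whose `x` columns are used).
#' @return Scalar offset.
#' @export
align_offset <- function(a, b) {
  if (inherits(a, "switch_trajectory")) a <- a$x
  if (inherits(b, "switch_trajectory")) b <- b$x
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  mean(a - b)
}
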