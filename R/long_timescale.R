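#' Autonomous activation from a trajectory
#'
#' Long-timescale readout of the switch: the level of autonomously
#' activated (stimulus-outlasting) switch is modelled as proportional to
#' the time average of activity over the stimulus window,
#' `X = omega * (1/Dt) * integral of x dt` (trapezoidal quadrature), with
#' `omega` a fixed basal rate of transition to the autonomous state. The
#' default `omega = 1` makes `X` the plain normalized average; protocol
#' outputs are typically reported relative to their maximum cell, so the
#' unknown proportionality constant drops out.
#'
#' @param traj A `switch_trajectory`.
#' @param omega Basal transition rate (dimensionless).
#' @param window Length-2 numeric `(start, end)` of the averaging window in
#'   seconds; must lie within the trajectory and be non-empty.
#' @return A one-row tibble with columns `X`, `omega`, `t_start`, `t_end`.
#' @export
autonomous_activation <- function(traj, omega = 1, window = range(traj$t)) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) abort("empty averaging window")
  if (window[1] < min(traj$t) - 1e-9 || window[2] > max(traj$t) + 1e-9)
    abort("window must lie within the trajectory")
  keep <- traj$t >= window[1] & traj$t <= window[2]
  tt <- traj$t[keep]
  xx <- traj$x[keep]
  if (length(tt) < 2) abort("window contains fewer than 2 samples")
  area <- sum(diff(tt) * (xx[-1] + xx[-length(xx)]) / 2)
  tibble(X = omega * area / (tt[length(tt)] - tt[1]), omega = omega,
         t_start = window[1], t_end = window[2])
}

# square-pulse calcium drive for pulse-duration/frequency protocols
square_pulse_signal <- function(rate, pulse_dur, n_pulses, delta_c, c0, dt) {
  duration <- n_pulses / rate
  n_grid <- round(duration / dt) + 1
  tgrid <- (seq_len(n_grid) - 1) * dt
  phase <- tgrid %% (1 / rate)
  cvals <- c0 + delta_c * (phase < pulse_dur & tgrid < (n_pulses - 1) / rate + pulse_dur)
  new_switch_signal(tgrid, cvals, dt, c0, delta_c, "square",
                    list(rate = rate, pulse_dur = pulse_dur))
}

#' Frequency/pulse-duration decoding grid
#'
#' Reproduces the classic frequency-decoding protocol: periodic trains of
#' square calcium pulses at each combination of pulse frequency and pulse
#' duration drive the switch, and the autonomous activation `X` (time
#' average over the stimulus) is recorded per cell. `X` increases along
#' both axes, and distinct (frequency, duration) pairs can map to the same
#' `X` — the input-ambiguity of long-timescale decoding. The default
#' parameters (`n = 1.6`, `r = 0.61`, `T = 0.4`) are the values under which
#' the experimental curves are captured qualitatively.
#'
#' @param frequencies Pulse frequencies in Hz.
#' @param durations_ms Pulse durations in milliseconds (must satisfy
#'   `frequency * duration < 1` against every frequency).
#' @param params A [switch_params()]; default `switch_params(0.61, c0 = 0,
#'   n = 1.6, T = 0.4)`.
#' @param omega Basal autonomous-transition rate.
#' @param n_pulses Pulses per train.
#' @param delta_c Square-pulse amplitude.
#' @param dt Grid step in seconds.
#' @return A tibble of class `protocol_result` with columns `frequency`,
#'   `duration_ms`, `X`, `X_rel` (relative to the maximum cell).
#' @export
dekoninck_protocol <- function(frequencies = c(0.5, 1, 2, 4),
                               durations_ms = c(50, 100, 200),
                               params = switch_params(0.61, c0 = 0, n = 1.6,
                                                      T = 0.4),
                               omega = 1, n_pulses = 30, delta_c = 0.5,
                               dt = 0.001) {
  stopifnot(all(frequencies > 0), all(durations_ms > 0))
  grid <- expand.grid(frequency = frequencies, duration_ms = durations_ms)
  bad <- grid$frequency * grid$duration_ms / 1000 >= 1
  if (any(bad)) abort("overlapping pulses: frequency * duration must be < 1")
  x0 <- low_state(params, c = params$c0)
  rows <- purrr::pmap(grid, function(frequency, duration_ms) {
    sig <- square_pulse_signal(frequency, duration_ms / 1000, n_pulses,
                               delta_c, params$c0, dt)
    traj <- simulate_switch(params, sig, x0 = x0)
    X <- autonomous_activation(traj, omega)$X
    tibble(frequency = frequency, duration_ms = duration_ms, X = X)
  })
  out <- bind_rows(rows)
  out$X_rel <- out$X / max(out$X)
  class(out) <- c("protocol_result", class(out))
  out
}

#' Wild-type vs autophosphorylation-dead switch under 1 Hz stimulation
#'
#' A 1 Hz train of exponential-decay calcium transients (decay 200 ms)
#' drives two switches sharing the identical input: the wild type with the
#' full Hill activation, and a T286A-like mutant with the Hill term removed
#' (`hill = FALSE`). The negative-regulation rate ramps linearly from
#' `r_start` to `r_end` over the stimulation period (set `ramp = FALSE` for
#' a fixed `r = r_start`), which produces the slow plateau decay seen in
#' imaging data; both trajectories continue past the stimulus to capture
#' the post-stimulation decay toward the baseline fixed point.
#'
#' @param n,T Hill exponent and timescale (defaults 1.6 and 0.1 s).
#' @param r_start,r_end Ramp endpoints for the negative-regulation rate.
#' @param ramp Logical; `FALSE` keeps `r` fixed at `r_start`.
#' @param rate,n_pulses Stimulation rate (Hz) and pulse count.
#' @param tau Calcium decay constant in seconds.
#' @param delta_c,c0 Calcium transient amplitude and baseline.
#' @param post Seconds of post-stimulus integration.
#' @param dt Grid step in seconds.
#' @return A tibble of class `chang_result` with columns `t`, `x`,
#'   `variant` (`"WT"` / `"T286A"`); the stimulation end time is stored in
#'   `attr(, "stim_end")`.
#' @export
chang_protocol <- function(n = 1.6, T = 0.1, r_start = 0.58, r_end = 0.67,
                           ramp = TRUE, rate = 1, n_pulses = 30, tau = 0.2,
                           delta_c = 0.5, c0 = 0, post = 30, dt = 0.001) {
  stim_end <- n_pulses / rate
  train <- regular_pulse_train(rate, n_pulses, duration = stim_end + post)
  signal <- exp_decay_calcium(train, tau = tau, delta_c = delta_c, c0 = c0,
                              dt = dt)
  r_hi <- if (ramp) r_end else r_start
  wt <- switch_params(r = r_start, c0 = c0, n = n, T = T, hill = TRUE)
  mut <- switch_params(r = r_start, c0 = c0, n = n, T = T, hill = FALSE)
  sim <- function(p) {
    if (ramp) {
      simulate_switch_ramped(p, signal, r_start, r_end, stim_end = stim_end,
                             x0 = 0)
    } else {
      simulate_switch(p, signal, x0 = 0)
    }
  }
  twt <- sim(wt)
  tmu <- sim(mut)
  out <- bind_rows(
    tibble(t = twt$t, x = twt$x, variant = "WT"),
    tibble(t = tmu$t, x = tmu$x, variant = "T286A")
  )
  attr(out, "stim_end") <- stim_end
  attr(out, "ramp") <- ramp
  attr(out, "r_range") <- c(r_start, r_hi)
  class(out) <- c("chang_result", class(out))
  out
}
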