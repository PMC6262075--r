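#' Tidy a stochastic-resonance sweep
#'
#' @param x An `sr_result` from [sr_sweep()].
#' @param ... Unused.
#' @return A plain tibble with columns `sigma`, `gain`, `gain_se`.
#' @export
tidy.sr_result <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a stochastic-resonance sweep
#'
#' @inheritParams tidy.sr_result
#' @return A tibble with `sigma_p`, `peak_gain`, bootstrap interval bounds,
#'   grid size and trial count.
#' @export
glance.sr_result <- function(x, ...) {
  ci <- attr(x, "sigma_p_ci")
  st <- attr(x, "settings")
  tibble(sigma_p = attr(x, "sigma_p"), peak_gain = max(x$gain),
         sigma_p_lo = ci[1], sigma_p_hi = ci[2],
         n_sigma = nrow(x), trials = st$trials, duration = st$duration)
}

#' Tidy an equilibrium set
#'
#' @param x An `equilibrium_set` from [fixed_points()].
#' @param ... Unused.
#' @return A plain tibble with columns `x`, `stability`, `dfdx`,
#'   `saddle_node` plus the parameter triple as columns `c`, `r`, `n`.
#' @export
tidy.equilibrium_set <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  out$c <- attr(x, "c")
  out$r <- attr(x, "r")
  out$n <- attr(x, "n")
  out
}

#' One-row summary of an equilibrium set
#'
#' @inheritParams tidy.equilibrium_set
#' @return A tibble with the fixed-point count, regime label and parameters.
#' @export
glance.equilibrium_set <- function(x, ...) {
  tibble(n_fixed = nrow(x),
         n_stable = sum(x$stability == "stable"),
         regime = classify_regime(max(attr(x, "c"), 1e-12), attr(x, "r"),
                                  attr(x, "n")),
         c = attr(x, "c"), r = attr(x, "r"), n = attr(x, "n"))
}

#' Tidy a discrepancy sweep
#'
#' @param x A `discrepancy_result` from [discrepancy_experiment()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.discrepancy_result <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a discrepancy sweep
#'
#' @inheritParams tidy.discrepancy_result
#' @return A tibble with the maximizing `r` and the peak discrepancy.
#' @export
glance.discrepancy_result <- function(x, ...) {
  i <- which.max(x$discrepancy)
  tibble(r_max = x$r[i], max_discrepancy = x$discrepancy[i],
         n_r = nrow(x), trials = x$trials[1])
}
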