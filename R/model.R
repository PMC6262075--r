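#' Drift of the switch equation
#'
#' Evaluates `f(x, c) = c - r x + x^n/(1+x^n)` (or `c - r x` when the Hill
#' term is disabled). The ODE solved by the integrators is `dx/dt = f / T`.
#' Vectorized over `x` and `c` (recycled against each other).
#'
#' @param x Switch activation, non-negative. Negative values are a domain
#'   error: the integrators clamp the state at zero themselves, so a negative
#'   `x` reaching this function indicates a bug upstream.
#' @param c Calcium drive, non-negative.
#' @param params A [switch_params()] object.
#' @return Numeric vector of drift values.
#' @examples
#' p <- switch_params(r = 0.52, c0 = 0.04)
#' switch_drift(0, 0.04, p)  # equals c
#' @export
switch_drift <- function(x, c, params) {
  stopifnot(inherits(params, "switch_params"))
  if (any(x < 0)) abort("`x` must be >= 0")
  f <- c - params$r * x
  if (params$hill) {
    xn <- x^params$n
    f <- f + xn / (1 + xn)
  }
  f
}

#' Derivative of the drift with respect to the state
#'
#' `f'(x) = -r + n x^(n-1) / (1+x^n)^2` (or `-r` without the Hill term);
#' its sign at a fixed point decides stability.
#'
#' @inheritParams switch_drift
#' @return Numeric vector of `df/dx` values.
#' @export
switch_drift_deriv <- function(x, params) {
  stopifnot(inherits(params, "switch_params"))
  if (any(x < 0)) abort("`x` must be >= 0")
  d <- rep(-params$r, length(x))
  if (params$hill) {
    n <- params$n
    d <- d + n * x^(n - 1) / (1 + x^n)^2
  }
  d
}

#' Potential function of the switch
#'
#' `U(x) = -\int_0^x f(s, c) ds` under the convention `U(0) = 0`. Stable
#' equilibria are local minima of `U`, the unstable equilibrium a local
#' maximum. For `n = 2` the closed form
#' `U(x) = -c x + r x^2/2 - x + atan(x)` is used; for other exponents the
#' integral is evaluated by adaptive quadrature (relative tolerance 1e-9).
#'
#' @inheritParams switch_drift
#' @param c Constant calcium drive; defaults to `params$c0`.
#' @return Numeric vector `U(x)`.
#' @examples
#' p <- switch_params(r = 0.52)
#' switch_potential(c(0, 0.5, 1), p, c = 0.04)
#' @export
switch_potential <- function(x, params, c = params$c0) {
  stopifnot(inherits(params, "switch_params"), length(c) == 1)
  if (any(x < 0)) abort("`x` must be >= 0")
  r <- params$r
  if (!params$hill) {
    return(-c * x + r * x^2 / 2)
  }
  if (params$n == 2) {
    return(-c * x + r * x^2 / 2 - x + atan(x))
  }
  n <- params$n
  base <- -c * x + r * x^2 / 2
  hill_int <- vapply(x, function(xi) {
    if (xi == 0) return(0)
    integrate(function(s) s^n / (1 + s^n), 0, xi,
              rel.tol = 1e-9, abs.tol = 1e-12)$value
  }, numeric(1))
  base - hill_int
}
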