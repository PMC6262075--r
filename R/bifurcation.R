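#' Fixed points and stability of the switch at constant drive
#'
#' Solves `f(x) = c - r x + x^n/(1+x^n) = 0` for `x >= 0` and labels each
#' root by the sign of `f'(x*)` (negative slope is stable). For `n = 2` the
#' roots of the equivalent cubic `-r x^3 + (c+1) x^2 - r x + c = 0` are found
#' in closed form and Newton-polished; for general `n` sign changes of `f`
#' are bracketed on `[0, (c+1)/r + 1]` (beyond which `f < 0`) and refined by
#' bisection. In the bistable regime there are three fixed points with
#' stabilities alternating stable/unstable/stable.
#'
#' @param c Constant calcium drive, `>= 0`.
#' @param r Negative-regulation rate, `>= 0`. `c = r = 0` is degenerate and
#'   rejected.
#' @param n Hill exponent, `> 0`.
#' @param hill Logical; `FALSE` drops the Hill term (single root `c / r`).
#' @return A tibble of class `equilibrium_set` with columns `x`, `stability`
#'   (`"stable"`/`"unstable"`), `dfdx`, and `saddle_node` (flag for roots
#'   lying numerically on a saddle-node, where `f'(x*) = 0`). The `(c, r, n)`
#'   triple is stored in attributes.
#' @examples
#' fixed_points(c = 0.04, r = 0.52)   # bistable: three fixed points
#' @export
fixed_points <- function(c, r, n = 2, hill = TRUE) {
  stopifnot(length(c) == 1, length(r) == 1, c >= 0, r >= 0, n > 0)
  if (c == 0 && r == 0) abort("degenerate input: c = r = 0 has no isolated fixed points")
  p <- switch_params(r = r, c0 = c, n = n, hill = hill)
  roots <- if (!hill) {
    if (r == 0) numeric(0) else c / r
  } else if (n == 2) {
    fp_roots_cubic(c, r)
  } else {
    fp_roots_bracketed(c, r, n)
  }
  roots <- sort(unique(pmax(roots, 0)))
  dfdx <- switch_drift_deriv(roots, p)
  tol <- 1e-10
  stability <- ifelse(dfdx < -tol, "stable", "unstable")
  out <- tibble(x = roots, stability = stability, dfdx = dfdx,
                saddle_node = abs(dfdx) <= tol)
  attr(out, "c") <- c
  attr(out, "r") <- r
  attr(out, "n") <- n
  attr(out, "hill") <- hill
  class(out) <- c("equilibrium_set", class(out))
  out
}

# closed-form cubic roots for n = 2, Newton-polished to |f| < 1e-12
fp_roots_cubic <- function(c, r) {
  if (r == 0) {
    # c + x^2/(1+x^2) = 0 has no root for c > 0 -> drift always positive
    return(numeric(0))
  }
  z <- polyroot(c(c, -r, c + 1, -r))
  x <- Re(z[abs(Im(z)) < 1e-7])
  x <- x[x > -1e-9]
  x <- pmax(x, 0)
  f <- function(xx) c - r * xx + xx^2 / (1 + xx^2)
  fp <- function(xx) -r + 2 * xx / (1 + xx^2)^2
  for (i in seq_len(3)) {
    d <- fp(x)
    ok <- abs(d) > 1e-8
    x[ok] <- x[ok] - f(x[ok]) / d[ok]
    x <- pmax(x, 0)
  }
  x[abs(f(x)) < 1e-9]
}

fp_roots_bracketed <- function(c, r, n) {
  f <- function(x) c - r * x + x^n / (1 + x^n)
  if (r == 0) return(numeric(0))
  x_max <- (c + 1) / r + 1
  grid <- seq(0, x_max, length.out = 4000)
  fv <- f(grid)
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    roots <- c(roots, uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root)
  }
  roots
}

#' Parametric saddle-node (critical) curves
#'
#' Along the saddle-node boundary both `f` and `f'` vanish; parametrizing by
#' the fixed-point location `x` gives
#' `r_c(x) = n x^(n-1) / (1+x^n)^2` and `c_c(x) = r_c(x) x - x^n/(1+x^n)`.
#' For `n = 2` these reduce to `r_c = 2x/(1+x^2)^2` and
#' `c_c = x^2 (1-x^2)/(1+x^2)^2`. The two branches meet tangentially at the
#' codimension-two point (`(1/8, 3*sqrt(3)/8)` for `n = 2`), beyond which
#' only one fixed point exists and bistability is lost.
#'
#' @param n Hill exponent, `> 0`.
#' @param x_grid Strictly positive, increasing parametrization grid.
#' @return A tibble of class `bifurcation_curves` with columns `x`, `r_c`,
#'   `c_c`; the codimension-two point is stored in
#'   `attr(, "codim2")` as `c(c = ..., r = ..., x = ...)`.
#' @examples
#' critical_curves()               # n = 2; r_c(1) == 1/2
#' attr(critical_curves(), "codim2")
#' @export
critical_curves <- function(n = 2, x_grid = seq(0.02, 4, length.out = 400)) {
  stopifnot(n > 0, all(x_grid > 0), !is.unsorted(x_grid))
  xn <- x_grid^n
  r_c <- n * x_grid^(n - 1) / (1 + xn)^2
  c_c <- r_c * x_grid - xn / (1 + xn)
  out <- tibble(x = x_grid, r_c = r_c, c_c = c_c)
  # codimension-two point: maximum of c_c(x) over x > 0
  cc_of_x <- function(x) {
    xn <- x^n
    rc <- n * x^(n - 1) / (1 + xn)^2
    rc * x - xn / (1 + xn)
  }
  opt <- optimize(cc_of_x, c(1e-6, 5), maximum = TRUE, tol = 1e-12)
  x2 <- opt$maximum
  attr(out, "codim2") <- c(c = opt$objective,
                           r = n * x2^(n - 1) / (1 + x2^n)^2, x = x2)
  attr(out, "n") <- n
  class(out) <- c("bifurcation_curves", class(out))
  out
}

#' Classify the dynamical regime at a parameter point
#'
#' Counts fixed points at `(c, r, n)`: three means bistable; with a single
#' fixed point the label says which branch survives, decided by comparing
#' the root with the fixed-point location at the codimension-two point
#' (the waist where low and high branches merge). The measure-zero boundary
#' case of two fixed points (exactly on a saddle-node) is reported as
#' `"bistable"` since both basins still exist on one side.
#'
#' @inheritParams fixed_points
#' @return One of `"monostable_low"`, `"bistable"`, `"monostable_high"`.
#' @examples
#' classify_regime(0.04, 0.52)  # "bistable"
#' classify_regime(0.2, 0.52)   # "monostable_high"
#' @export
classify_regime <- function(c, r, n = 2) {
  stopifnot(r > 0)
  eq <- fixed_points(c, r, n)
  if (nrow(eq) >= 2) return("bistable")
  x_waist <- attr(critical_curves(n, x_grid = c(1)), "codim2")[["x"]]
  if (eq$x[1] > x_waist) "monostable_high" else "monostable_low"
}

#' Quasi-static hysteresis sweep along a drive path
#'
#' Follows the occupied stable branch as the constant drive `c` moves along
#' `c_path` adiabatically (drive much slower than the switch relaxation): at
#' each value of `c` the occupied state is the stable fixed point nearest
#' the previously occupied one; when that branch disappears through a
#' saddle-node the state jumps to the remaining stable point. In a bistable
#' `r`-slice the upward and downward jumps occur at different `c`
#' (hysteresis); above the critical `r` the path is retraced exactly.
#'
#' @param r,n Model parameters (see [fixed_points()]).
#' @param c_path Numeric vector of drive values (piecewise monotone).
#' @param x_init Optional starting state; defaults to the stable fixed point
#'   nearest 0 at `c_path[1]`.
#' @return A tibble of class `hysteresis_sweep` with columns `step`, `c`,
#'   `x` (occupied stable state).
#' @seealso [hysteresis_jumps()]
#' @export
hysteresis_sweep <- function(r, n = 2, c_path, x_init = NULL) {
  stopifnot(r > 0, length(c_path) >= 1)
  x_prev <- x_init
  xs <- numeric(length(c_path))
  for (i in seq_along(c_path)) {
    eq <- fixed_points(c_path[i], r, n)
    stab <- eq$x[eq$stability == "stable"]
    if (length(stab) == 0) stab <- eq$x   # saddle-node boundary case
    if (is.null(x_prev)) x_prev <- min(stab)
    xs[i] <- stab[which.min(abs(stab - x_prev))]
    x_prev <- xs[i]
  }
  out <- tibble(step = seq_along(c_path), c = c_path, x = xs)
  attr(out, "r") <- r
  attr(out, "n") <- n
  class(out) <- c("hysteresis_sweep", class(out))
  out
}

#' Locate branch jumps in a hysteresis sweep
#'
#' @param sweep Output of [hysteresis_sweep()].
#' @param threshold Minimum jump in `x` between consecutive steps counted as
#'   a branch switch.
#' @return Tibble with columns `direction` (`"up"`/`"down"`) and `c` (drive
#'   value at which the jump was taken).
#' @export
hysteresis_jumps <- function(sweep, threshold = 0.2) {
  dx <- diff(sweep$x)
  idx <- which(abs(dx) > threshold)
  tibble(direction = ifelse(dx[idx] > 0, "up", "down"),
         c = sweep$c[idx + 1])
}
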