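#' Nondimensional switch parameters
#'
#' Bundles the parameters of the reduced switch equation
#' \deqn{T \frac{dx}{dt} = c(t) - r x + \frac{x^n}{1 + x^n}}
#' where `x` is the (dimensionless) concentration of activated switch,
#' `c(t) = c0 + c_l(t)` is the calcium drive, `r` the strength of negative
#' regulation by phosphatases, `n` the Hill exponent of cooperative
#' autophosphorylation, and `T` (seconds) the timescale factor, the ratio of
#' the dissociation and association constants of the underlying kinetics.
#'
#' Setting `hill = FALSE` removes the autophosphorylation term altogether,
#' modelling a T286A-like mutant that cannot self-activate; the dynamics then
#' reduce to the linear relaxation `T dx/dt = c(t) - r x`.
#'
#' @param r Negative-regulation (phosphatase) rate, dimensionless, `>= 0`.
#' @param c0 Residual calcium drive (baseline of `c(t)`), dimensionless, `>= 0`.
#' @param n Hill exponent, `> 0`. `n = 2` admits closed-form analysis.
#' @param T Timescale factor in seconds, `> 0`. Default 0.01 s, the value
#'   appropriate for CaMKII whose dissociation constant is at least 100-fold
#'   smaller than its association constant.
#' @param hill Logical; `FALSE` disables the Hill activation term (mutant).
#'
#' @return An object of class `switch_params`.
#' @examples
#' p <- switch_params(r = 0.52, c0 = 0.04)
#' p
#' @export
switch_params <- function(r, c0 = 0.04, n = 2, T = 0.01, hill = TRUE) {
  stopifnot(is.numeric(r), length(r) == 1, is.numeric(c0), length(c0) == 1,
            is.numeric(n), length(n) == 1, is.numeric(T), length(T) == 1,
            is.logical(hill), length(hill) == 1)
  if (r < 0) abort("`r` must be >= 0")
  if (c0 < 0) abort("`c0` must be >= 0")
  if (n <= 0) abort("`n` must be > 0")
  if (T <= 0) abort("`T` must be > 0")
  structure(list(r = r, c0 = c0, n = n, T = T, hill = hill),
            class = "switch_params")
}

#' @export
print.switch_params <- function(x, ...) {
  cat("<switch_params>  r =", x$r, " c0 =", x$c0, " n =", x$n,
      " T =", x$T, "s ", if (!x$hill) " [Hill term disabled]" else "", "\n")
  invisible(x)
}

#' Dimensional kinetic parameters
#'
#' The four-constant kinetic description
#' \deqn{dy/dt = k_0 s - k_1 y + k_2 y^n / (k_3^n + y^n)}
#' of activated kinase concentration `y` driven by bound calcium `s`:
#' `k0` the input gain, `k1` the phosphatase rate, and `k2`, `k3` the
#' association and dissociation constants of autophosphorylation.
#'
#' @param k0,k1,k2,k3 Non-negative kinetic constants; `k2`, `k3` must be
#'   strictly positive to admit nondimensionalization.
#' @param n Hill exponent, `> 0`.
#' @return An object of class `dimensional_params`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(k0, k1, k2, k3, n = 2) {
  vals <- c(k0 = k0, k1 = k1, k2 = k2, k3 = k3)
  if (any(vals < 0)) abort("kinetic constants must be >= 0")
  if (n <= 0) abort("`n` must be > 0")
  structure(list(k0 = k0, k1 = k1, k2 = k2, k3 = k3, n = n),
            class = "dimensional_params")
}

#' Reduce the dimensional kinetics to the three-parameter switch form
#'
#' Applies the substitution `y = x * k3`, which turns the four-constant
#' kinetic equation into `T dx/dt = c - r x + x^n/(1+x^n)` with
#' `r = k1 k3 / k2`, `T = k3 / k2`, and the input map `c(t) = (k0/k2) s(t)`.
#' The returned maps convert between the two descriptions: `c_of_s()` maps a
#' dimensional input to the reduced drive and `x_of_y()` / `y_of_x()` convert
#' the state variables.
#'
#' @param dp A [dimensional_params()] object.
#' @param c0 Baseline drive to record on the reduced parameter set (default 0).
#' @return A list with elements `params` (a [switch_params()] with the mapped
#'   `r`, `n`, `T`), and functions `c_of_s`, `x_of_y`, `y_of_x`.
#' @examples
#' nd <- nondimensionalize(dimensional_params(1, 1, 1, 1))
#' nd$params
#' @export
nondimensionalize <- function(dp, c0 = 0) {
  stopifnot(inherits(dp, "dimensional_params"))
  if (dp$k2 <= 0 || dp$k3 <= 0) abort("`k2` and `k3` must be > 0 to nondimensionalize")
  list(
    params = switch_params(r = dp$k1 * dp$k3 / dp$k2, c0 = c0, n = dp$n,
                           T = dp$k3 / dp$k2),
    c_of_s = function(s) (dp$k0 / dp$k2) * s,
    x_of_y = function(y) y / dp$k3,
    y_of_x = function(x) x * dp$k3
  )
}

#' Read/write switch parameters
#'
#' Parameters serialize to a flat JSON or YAML mapping
#' `{r, c0, n, T, hill}`; the format follows the file extension
#' (`.json`, `.yaml`/`.yml`). Times are in seconds.
#'
#' @param p A [switch_params()] object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_switch_params()` returns a [switch_params()];
#'   `write_switch_params()` returns `path` invisibly.
#' @export
write_switch_params <- function(p, path) {
  stopifnot(inherits(p, "switch_params"))
  flat <- list(r = p$r, c0 = p$c0, n = p$n, T = p$T, hill = p$hill)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path)
  } else {
    abort("unsupported extension; use .json, .yaml or .yml")
  }
  invisible(path)
}

#' @rdname write_switch_params
#' @export
read_switch_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  flat <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("unsupported extension; use .json, .yaml or .yml")
  }
  switch_params(r = flat$r, c0 = flat$c0, n = flat$n, T = flat$T,
                hill = isTRUE(flat$hill))
}
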