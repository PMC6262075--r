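#' Plot a switch trajectory
#'
#' @param object A `switch_trajectory`.
#' @param ... Unused.
#' @return A ggplot object of `x` against time.
#' @export
autoplot.switch_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "switch activation x") +
    ggplot2::theme_minimal()
}

#' Plot a stochastic-resonance sweep
#'
#' Spectral gain against noise amplitude on a log axis, with the optimal
#' noise level marked.
#'
#' @param object An `sr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sr_result <- function(object, ...) {
  sp <- attr(object, "sigma_p")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$gain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = sp, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma), y = "spectral gain",
                  subtitle = paste0("optimal noise  sigma_p = ",
                                    signif(sp, 3))) +
    ggplot2::theme_minimal()
}

#' Plot parametric saddle-node curves
#'
#' The bistable tongue in the `(c, r)` plane: the saddle-node boundary
#' traced parametrically by the fixed-point location, with the
#' codimension-two point where the branches meet tangentially.
#'
#' @param object A `bifurcation_curves` object from [critical_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifurcation_curves <- function(object, ...) {
  cod <- attr(object, "codim2")
  keep <- object$c_c >= 0
  ggplot2::ggplot(object[keep, ],
                  ggplot2::aes(x = .data$c_c, y = .data$r_c)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = cod[["c"]], y = cod[["r"]],
                      colour = "red", size = 2) +
    ggplot2::labs(x = "critical drive c_c", y = "critical regulation r_c") +
    ggplot2::theme_minimal()
}

#' Plot wild-type vs mutant stimulation time courses
#'
#' @param object A `chang_result` from [chang_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chang_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x,
                                       colour = .data$variant)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = attr(object, "stim_end"), linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "switch activation x", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Potential landscape at a constant drive
#'
#' Plots `U(x)` with the stable equilibria (minima) and the unstable
#' equilibrium (maximum) marked.
#'
#' @param params A [switch_params()].
#' @param c Constant drive (default `params$c0`).
#' @param x_max Right edge of the plotted range.
#' @return A ggplot object.
#' @export
plot_potential <- function(params, c = params$c0, x_max = 2.5) {
  xg <- seq(0, x_max, length.out = 400)
  df <- tibble(x = xg, U = switch_potential(xg, params, c))
  eq <- fixed_points(c, params$r, params$n, hill = params$hill)
  eqd <- tibble(x = eq$x, U = switch_potential(eq$x, params, c),
                stability = eq$stability)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = eqd,
                        ggplot2::aes(colour = .data$stability), size = 2) +
    ggplot2::scale_colour_manual(values = c(stable = "black",
                                            unstable = "red")) +
    ggplot2::labs(x = "switch activation x", y = "potential U(x)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
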