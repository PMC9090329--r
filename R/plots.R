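#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a parameter sweep
#'
#' Plots the mean second-half risky proportion over the `alpha` x `beta`
#' plane, facetted by the social parameters when they vary, with the
#' asocial indifference boundary `beta = (2 - alpha)/alpha` overlaid.
#'
#' @param object A sweep tibble from [sweep_parameter_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$alpha, .data$beta,
                                    fill = .data$prop_risky)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = "P(risky), 2nd half") +
    ggplot2::geom_function(
      fun = function(a) (2 - a) / a, colour = "black", linetype = "dashed",
      inherit.aes = FALSE
    ) +
    ggplot2::coord_cartesian(ylim = range(object$beta)) +
    ggplot2::labs(x = expression(alpha), y = expression(beta))
  if (length(unique(object$sigma)) > 1 || length(unique(object$theta)) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$theta), cols = ggplot2::vars(.data$sigma),
      labeller = ggplot2::label_both
    )
  }
  p
}

#' Bifurcation diagram of the population dynamics
#'
#' Equilibrium risky density against the social weight, stable equilibria
#' as filled points, with the neutral line `NR = N/2`.
#'
#' @param object A `bifurcation_scan` from [stable_equilibria_scan()].
#' @param N Population size for the neutral line (default from the data).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifurcation_scan <- function(object, N = NULL, ...) {
  N <- N %||% 2 * stats::median(object$NR_star, na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(.data$sigma, .data$NR_star,
                                       shape = .data$stable)) +
    ggplot2::geom_hline(yintercept = N / 2, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "stable") +
    ggplot2::labs(x = expression(sigma), y = expression(N[R]^"*"))
}

#' Posterior predictive risky-choice trajectories
#'
#' @param object A `posthoc_prediction` from [posthoc_simulate()].
#' @param ... Unused.
#' @return A ggplot with the mean trajectory and credible band.
#' @export
autoplot.posthoc_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$trial, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial", y = "proportion choosing risky")
}

#' Heterogeneous-group performance plot
#'
#' Per-member mean performance by composition, with composition means.
#'
#' @param object A `heterogeneous_result` from [run_heterogeneous()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heterogeneous_result <- function(object, ...) {
  ggplot2::ggplot(object$members,
                  ggplot2::aes(.data$composition, .data$mean_prop_risky)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = object$groups, shape = 18, size = 4,
                        colour = "#b2182b") +
    ggplot2::labs(x = "composition", y = "mean P(risky), 2nd half")
}
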