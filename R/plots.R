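#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cooperative unfolding fit
#'
#' Data points with the fitted cooperative isotherm; when an LEM
#' comparator is attached its logistic curve is overlaid for comparison.
#'
#' @param object a `coop_fit`.
#' @param n_curve number of points on the plotted model curve.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.coop_fit <- function(object, n_curve = 200, ...) {
  grid <- seq(min(object$data$concentration_M),
              max(object$data$concentration_M), length.out = n_curve)
  curves <- tibble::tibble(
    concentration_M = grid,
    theta = fraction_unfolded(object$params, grid, method = object$method),
    model = "multistate cooperative"
  )
  if (!is.null(object$lem)) {
    curves <- dplyr::bind_rows(curves, tibble::tibble(
      concentration_M = grid,
      theta = lem_fraction_unfolded(object$lem$params, grid,
                                    object$params$temperature_K),
      model = "LEM"
    ))
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_M, .data$theta)) +
    ggplot2::geom_line(data = curves, ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$c0, linetype = "dotted") +
    ggplot2::labs(x = "denaturant concentration (M)",
                  y = expression(Theta[U]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an LEM fit
#'
#' @param object an `lem_fit`.
#' @param n_curve number of points on the plotted curve.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lem_fit <- function(object, n_curve = 200, ...) {
  grid <- seq(min(object$data$concentration_M),
              max(object$data$concentration_M), length.out = n_curve)
  curve <- tibble::tibble(
    concentration_M = grid,
    theta = lem_fraction_unfolded(object$params, grid, object$temperature_K)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration_M, .data$theta)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "denaturant concentration (M)",
                  y = expression(Theta[U])) +
    ggplot2::theme_minimal()
}

#' Plot a free-energy profile
#'
#' @param object an `fe_profile` tibble from [free_energy_profile()].
#' @param ... unused.
#' @return A ggplot of `delta_F` against concentration.
#' @export
autoplot.fe_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(.data$concentration_M,
                               .data$delta_F_kcal_mol)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "denaturant concentration (M)",
                  y = expression(Delta * F ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' Plot a van't Hoff thermal fit
#'
#' Free energies against temperature with the fitted regression line
#' whose negative slope is the unfolding entropy.
#'
#' @param object a `thermal_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.thermal_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$temperature_K,
                               .data$delta_F_kcal_mol)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$delta_H_mean, slope = -object$delta_S,
      colour = "firebrick") +
    ggplot2::labs(x = "temperature (K)",
                  y = expression(Delta * F ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}
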