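#' Simulate a chemical unfolding isotherm
#'
#' Generates an experimental-style isotherm: the model curve
#' `Theta_U(c_D)` on an even concentration grid plus additive Gaussian
#' noise in theta space, lightly clipped to `[-0.05, 1.05]` (normalised
#' spectroscopic data routinely strays slightly outside `[0, 1]`).
#' Reproducible under a fixed `seed`.
#'
#' @inheritParams fraction_unfolded
#' @param c_min,c_max concentration range, M, `c_max > c_min`.
#' @param n_points number of points, at least 5.
#' @param noise_sd Gaussian noise standard deviation in theta units.
#' @param seed optional integer seed (local to this call).
#' @return A tibble (`concentration_M`, `theta`) carrying `nu`,
#'   `temperature_K` and `true_params` attributes.
#' @export
#' @examples
#' p <- unfolding_params(0.25, 1e-3, 129, 298.15)
#' simulate_isotherm(p, 1, 7, n_points = 13, noise_sd = 0.01, seed = 1)
simulate_isotherm <- function(params, c_min, c_max, n_points = 25L,
                              noise_sd = 0, seed = NULL,
                              method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "unfolding_params"))
  check_number(c_min, "c_min", lower = 0)
  check_number(c_max, "c_max")
  if (c_max <= c_min) abort("`c_max` must exceed `c_min`.")
  check_number(n_points, "n_points", lower = 5)
  check_number(noise_sd, "noise_sd", lower = 0)
  cc <- seq(c_min, c_max, length.out = n_points)
  th <- fraction_unfolded(params, cc, method = method)
  th <- th + local_rnorm(n_points, noise_sd, seed)
  out <- tibble::tibble(concentration_M = cc,
                        theta = pmin(pmax(th, -0.05), 1.05))
  attr(out, "nu") <- params$nu
  attr(out, "temperature_K") <- params$temperature_K
  attr(out, "true_params") <- params
  attr(out, "response_type") <- "theta"
  out
}

#' Simulate a temperature series of unfolding free energies
#'
#' Linear van't Hoff construction `dF(T) = dH - T * dS` plus optional
#' Gaussian noise, emulating free energies extracted from unfolding
#' isotherms measured at several temperatures.
#'
#' @param delta_H unfolding enthalpy, kcal/mol.
#' @param delta_S unfolding entropy, kcal mol-1 K-1.
#' @param temperatures strictly increasing temperatures, K (at least 2).
#' @param noise_sd Gaussian noise on `dF`, kcal/mol.
#' @param seed optional integer seed.
#' @return A tibble (`temperature_K`, `delta_F_kcal_mol`).
#' @export
simulate_thermal_series <- function(delta_H, delta_S, temperatures,
                                    noise_sd = 0, seed = NULL) {
  check_number(delta_H, "delta_H")
  check_number(delta_S, "delta_S")
  if (length(temperatures) < 2L ||
      is.unsorted(temperatures, strictly = TRUE)) {
    abort("`temperatures` must be at least two strictly increasing values.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  dF <- delta_H - temperatures * delta_S +
    local_rnorm(length(temperatures), noise_sd, seed)
  tibble::tibble(temperature_K = temperatures, delta_F_kcal_mol = dF)
}

#' Simulate a calorimetric denaturant titration
#'
#' Heat per mole protein `Q(c_D) = dH0 * Theta_U(c_D)` plus Gaussian
#' noise, emulating point-by-point isothermal calorimetry of a protein
#' titrated with denaturant.
#'
#' @inheritParams predict_titration_heat
#' @param c_points concentrations at which heats are measured, M,
#'   ascending.
#' @param noise_sd Gaussian noise on the heats, kcal/mol.
#' @param seed optional integer seed.
#' @return A tibble (`concentration_M`, `heat_kcal_mol`) carrying a
#'   `true_delta_H0` attribute.
#' @export
simulate_titration <- function(params, delta_H0, c_points, noise_sd = 0,
                               seed = NULL,
                               method = c("exact", "approx")) {
  method <- match.arg(method)
  check_concentration(c_points, "c_points")
  if (is.unsorted(c_points, strictly = TRUE)) {
    abort("`c_points` must be strictly increasing.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  q <- predict_titration_heat(params, delta_H0, c_points, method = method) +
    local_rnorm(length(c_points), noise_sd, seed)
  out <- tibble::tibble(concentration_M = c_points, heat_kcal_mol = q)
  attr(out, "true_delta_H0") <- delta_H0
  attr(out, "temperature_K") <- params$temperature_K
  out
}

# seed-local Gaussian noise: leaves the caller's RNG stream untouched
local_rnorm <- function(n, sd, seed) {
  if (sd == 0) return(rep(0, n))
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
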