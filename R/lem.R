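#' LEM free energy of unfolding
#'
#' The linear extrapolation method assumes the free energy of the
#' two-state N <-> U equilibrium is linear in denaturant concentration:
#' `dG(c) = dG0 - m * c`. It is positive in water, zero at the midpoint
#' `c0 = dG0 / m`, and negative beyond.
#'
#' @param params an [lem_params()] object.
#' @param c_D denaturant concentration(s), M.
#' @return `dG` in kcal/mol, one per element of `c_D`.
#' @export
#' @examples
#' lem <- lem_params(delta_G0 = 8.598, c0 = 4.0)
#' lem_free_energy(lem, c(0, 4, 6))
lem_free_energy <- function(params, c_D) {
  stopifnot(inherits(params, "lem_params"))
  check_concentration(c_D)
  params$delta_G0 - params$m_value * c_D
}

#' LEM unfolding isotherm
#'
#' Fraction unfolded under the two-state model,
#' `Theta = K / (1 + K)` with `K = exp(-dG(c) / RT)`. A logistic curve in
#' concentration, symmetric about the midpoint where it equals 1/2.
#'
#' @inheritParams lem_free_energy
#' @param temperature_K absolute temperature, K.
#' @return Fraction(s) unfolded in `[0, 1]`.
#' @export
lem_fraction_unfolded <- function(params, c_D, temperature_K) {
  check_number(temperature_K, "temperature_K", lower = 0,
               closed_lower = FALSE)
  dG <- lem_free_energy(params, c_D)
  K <- exp(-dG / (R_KCAL * temperature_K))
  K / (1 + K)
}

#' LEM slope from the midpoint identity
#'
#' Because the LEM free energy vanishes at the midpoint, the slope is
#' fixed by `m = dG0 / c0` and is not an independent fit parameter.
#'
#' @param delta_G0 free energy of the native protein in water, kcal/mol.
#' @param c0 midpoint concentration, M; must be positive.
#' @return Slope `m`, kcal L mol^-2.
#' @export
#' @examples
#' m_from_midpoint(8.598, 4.0) # 2.1495
m_from_midpoint <- function(delta_G0, c0) {
  check_number(delta_G0, "delta_G0")
  check_number(c0, "c0", lower = 0, closed_lower = FALSE)
  delta_G0 / c0
}
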