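#' Molecular parameters of the cooperative unfolding model
#'
#' Bundles the four molecular parameters of the multistate cooperative
#' model: the denaturant binding constant `K_D` (M^-1), the Zimm-Bragg
#' cooperativity (nucleation) parameter `sigma`, the number of amino acid
#' residues `nu` participating in the unfolding reaction, and the absolute
#' temperature. In this model the binding constant is the reciprocal of the
#' midpoint concentration of unfolding, `K_D = 1/c0`, and `sigma` sets the
#' steepness of the transition (small sigma, sharp transition).
#'
#' @param K_D denaturant binding constant, M^-1; must be positive.
#' @param sigma cooperativity parameter in (0, 1]; `sigma = 1` is the
#'   noncooperative (Langmuir) limit.
#' @param nu number of residues in the cooperative unit, a positive integer.
#' @param temperature_K absolute temperature, K.
#' @return An object of class `unfolding_params` (a named list).
#' @export
#' @examples
#' lys <- unfolding_params(K_D = 0.25, sigma = 1e-3, nu = 129,
#'                         temperature_K = 298.15)
#' lys
unfolding_params <- function(K_D, sigma = 1e-3, nu = 129,
                             temperature_K = 298.15) {
  check_number(K_D, "K_D", lower = 0, closed_lower = FALSE)
  check_number(sigma, "sigma", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(nu, "nu", lower = 1)
  if (abs(nu - round(nu)) > 1e-8) {
    abort("`nu` must be a whole number of residues.")
  }
  check_number(temperature_K, "temperature_K", lower = 0,
               closed_lower = FALSE)
  structure(
    list(K_D = K_D, sigma = sigma, nu = as.integer(round(nu)),
         temperature_K = temperature_K),
    class = "unfolding_params"
  )
}

#' @export
print.unfolding_params <- function(x, ...) {
  cat("Multistate cooperative unfolding parameters\n")
  cat(sprintf("  K_D    = %g M^-1  (midpoint c0 = %g M)\n", x$K_D, 1 / x$K_D))
  cat(sprintf("  sigma  = %g\n", x$sigma))
  cat(sprintf("  nu     = %d residues\n", x$nu))
  cat(sprintf("  T      = %g K\n", x$temperature_K))
  invisible(x)
}

#' Parameters of the linear extrapolation method (LEM)
#'
#' The two-state LEM describes unfolding by `dG(c) = dG0 - m * c`, with
#' `dG0` the free energy assigned to the native protein in water and `m`
#' the slope. Because the free energy is zero at the midpoint `c0`, the
#' slope is not an independent quantity: `m = dG0 / c0`.
#'
#' Supply any two of `delta_G0`, `m_value`, `c0`; the third is filled in
#' from the midpoint identity. Supplying all three is allowed only if they
#' are consistent.
#'
#' @param delta_G0 free energy of the native protein in water, kcal/mol.
#' @param m_value slope, kcal L mol^-2; must be positive.
#' @param c0 midpoint concentration, M; must be positive.
#' @return An object of class `lem_params`.
#' @export
#' @examples
#' lem_params(delta_G0 = 8.598, c0 = 4.0) # m filled in as 2.1495
lem_params <- function(delta_G0 = NULL, m_value = NULL, c0 = NULL) {
  n_given <- sum(!vapply(list(delta_G0, m_value, c0), is.null, logical(1)))
  if (n_given < 2) {
    abort("Supply at least two of `delta_G0`, `m_value`, `c0`.")
  }
  if (is.null(delta_G0)) delta_G0 <- m_value * c0
  if (is.null(m_value)) m_value <- m_from_midpoint(delta_G0, c0)
  if (is.null(c0)) c0 <- delta_G0 / m_value
  check_number(m_value, "m_value", lower = 0, closed_lower = FALSE)
  check_number(c0, "c0", lower = 0, closed_lower = FALSE)
  if (abs(m_value * c0 - delta_G0) > 1e-9 * max(1, abs(delta_G0))) {
    abort("Inconsistent LEM parameters: `m_value * c0` must equal `delta_G0`.")
  }
  structure(list(delta_G0 = delta_G0, m_value = m_value, c0 = c0),
            class = "lem_params")
}

#' @export
print.lem_params <- function(x, ...) {
  cat("Linear extrapolation method (LEM) parameters\n")
  cat(sprintf("  dG0(H2O) = %g kcal/mol\n", x$delta_G0))
  cat(sprintf("  m        = %g kcal L mol^-2\n", x$m_value))
  cat(sprintf("  c0       = %g M\n", x$c0))
  invisible(x)
}

# shared scalar validator
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  invisible(x)
}

check_concentration <- function(c_D, name = "c_D") {
  if (!is.numeric(c_D) || any(!is.finite(c_D)) || any(c_D < 0)) {
    abort(sprintf("`%s` must be non-negative finite concentration(s) in M.",
                  name))
  }
  invisible(c_D)
}
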