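#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a cooperative unfolding fit
#'
#' @param x a `coop_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter (`c0`, `K_D`, `sigma`,
#'   `log10_sigma`), columns `term`, `estimate`, `unit`, `fixed`
#'   (whether the parameter was pinned rather than optimised).
#' @export
tidy.coop_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c0", "K_D", "sigma", "log10_sigma"),
    estimate = c(x$c0, x$K_D, x$sigma, log10(x$sigma)),
    unit = c("M", "1/M", "", ""),
    fixed = c(!x$joint, !x$joint, FALSE, FALSE)
  )
}

#' Glance at a cooperative unfolding fit
#'
#' @inheritParams tidy.coop_fit
#' @return A one-row tibble: goodness of fit (`sse`, `r_squared`,
#'   `nobs`), the transition range (`c_ini`, `c_end`, `delta_c`), the
#'   free-energy change `delta_F` across it, the diffusive free energy
#'   `g_den`, the per-residue transition energy `delta_g_nu`, and the
#'   nucleation penalty `delta_F_sigma` (all kcal/mol).
#' @export
glance.coop_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, r_squared = x$r_squared, nobs = nrow(x$data),
    c_ini = x$range$c_ini, c_end = x$range$c_end,
    delta_c = x$range$delta_c, delta_F = x$delta_F,
    g_den = x$thermo$g_den, delta_g_nu = x$thermo$delta_g_nu,
    delta_F_sigma = x$thermo$delta_F_sigma,
    converged = x$converged
  )
}

#' Augment isotherm data with cooperative-fit columns
#'
#' @inheritParams tidy.coop_fit
#' @return The fitted isotherm with `.fitted` and `.resid` columns.
#' @export
augment.coop_fit <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$data),
                .fitted = x$fitted, .resid = x$residuals)
}

#' Tidy an LEM fit
#'
#' @param x an `lem_fit` object.
#' @param ... unused.
#' @return A tibble with rows `delta_G0`, `m`, `c0`.
#' @export
tidy.lem_fit <- function(x, ...) {
  tibble::tibble(
    term = c("delta_G0", "m", "c0"),
    estimate = c(x$params$delta_G0, x$params$m_value, x$params$c0),
    unit = c("kcal/mol", "kcal L/mol^2", "M"),
    fixed = c(FALSE, x$constrained, x$constrained)
  )
}

#' @rdname tidy.lem_fit
#' @export
glance.lem_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r_squared = x$r_squared,
                 nobs = nrow(x$data), constrained = x$constrained)
}

#' Tidy a van't Hoff thermal fit
#'
#' @param x a `thermal_fit` object from [fit_thermal()].
#' @param ... unused.
#' @return A tibble with rows `delta_S` (with standard error) and
#'   `delta_H_mean`.
#' @export
tidy.thermal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("delta_S", "delta_H_mean"),
    estimate = c(x$delta_S, x$delta_H_mean),
    std.error = c(x$delta_S_stderr, x$delta_H_sd / sqrt(x$n)),
    unit = c("kcal/mol/K", "kcal/mol")
  )
}

#' @rdname tidy.thermal_fit
#' @export
glance.thermal_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, nobs = x$n,
                 delta_S = x$delta_S, delta_H_mean = x$delta_H_mean)
}

#' @rdname tidy.thermal_fit
#' @export
augment.thermal_fit <- function(x, ...) {
  dplyr::mutate(x$data,
    T_delta_S_kcal_mol = .data$temperature_K * x$delta_S,
    delta_H_kcal_mol = x$delta_H_values)
}
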