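#' Built-in literature unfolding parameter tables
#'
#' Two curated tables of multistate-cooperative fit parameters for
#' chemical protein denaturation, shipped as plain CSV under
#' `inst/extdata/` and re-read on each call:
#'
#' * `"lysozyme_temperature"` — lysozyme unfolded with guanidine HCl at
#'   10-60 degrees C, one row per published isotherm: midpoint `c_mid_M`,
#'   binding constant `K_D_per_M`, cooperativity `sigma`, transition
#'   range `c_ini_M`/`c_end_M`, the free-energy change
#'   `delta_F_kcal_mol` across it, the per-denaturant free energy
#'   `g_den_kcal_mol` (the diffusive free energy of the concentration
#'   gradient, negative by convention), and the LEM comparator values
#'   `delta_G0_kcal_mol` and `m_kcal_L_mol2`.
#' * `"survey"` — peptides and proteins of 32-1600 residues unfolded
#'   with guanidine HCl, urea, or SDS. Concentrations are in molar
#'   units throughout (the SDS midpoint, 4.35 mM, appears as 0.00435).
#'
#' Every row obeys the reciprocal midpoint relation
#' `K_D * c_mid = 1` to within printed rounding.
#'
#' @param table which table to return.
#' @return A tibble.
#' @export
#' @examples
#' unfolding_fixtures("lysozyme_temperature")
unfolding_fixtures <- function(table = c("lysozyme_temperature", "survey")) {
  table <- match.arg(table)
  file <- switch(table,
    lysozyme_temperature = "lysozyme_gdnhcl_temperature.csv",
    survey = "protein_denaturant_survey.csv"
  )
  path <- system.file("extdata", file, package = "coopunfold",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, na = "NA")
}

#' Lysozyme free-energy temperature series
#'
#' The consistent subset of the lysozyme/guanidine-HCl temperature table
#' (single literature source, 10-25 degrees C) in the form
#' [fit_thermal()] expects, for extracting the unfolding entropy and
#' enthalpy from the temperature dependence of `dF`.
#'
#' @param source_ref which source tag to select (default `"ref20"`).
#' @param max_temp_C upper temperature cut, degrees C (default 25; the
#'   higher-temperature points depart from the linear regime).
#' @return A tibble (`temperature_K`, `delta_F_kcal_mol`).
#' @export
lysozyme_thermal_series <- function(source_ref = "ref20", max_temp_C = 25) {
  tab <- unfolding_fixtures("lysozyme_temperature")
  tab <- dplyr::filter(tab, .data$source_ref == !!source_ref,
                       .data$temp_C <= max_temp_C)
  tibble::tibble(
    temperature_K = celsius_to_kelvin(tab$temp_C),
    delta_F_kcal_mol = tab$delta_F_kcal_mol
  )
}
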