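#' Read an unfolding isotherm from a delimited text file
#'
#' The expected layout is a plain text table with a header line naming a
#' `concentration_M` column plus either `theta` (fraction unfolded) or
#' `signal` (raw spectroscopic response), preceded by optional
#' `# key=value` metadata lines (`protein`, `denaturant`,
#' `temperature_K`, `pH`, `nu`). Comma, tab or whitespace delimited.
#' Rows are returned sorted by concentration; malformed cells and
#' duplicate concentrations raise errors naming the offending line.
#'
#' Concentrations must be in molar units. If every concentration is
#' below 0.05 M and the denaturant is not an SDS-like surfactant, a
#' warning suggests a millimolar-unit mistake.
#'
#' @param path file to read.
#' @return A tibble with the file's columns, carrying the metadata as
#'   attributes plus `response_type` (`"theta"` or `"signal"`) and
#'   `needs_normalization`.
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^\\s*#", lines)
  meta <- parse_metadata(lines[meta_idx])
  body_idx <- setdiff(which(nzchar(trimws(lines))), meta_idx)
  if (length(body_idx) < 2L) {
    abort(sprintf("%s: no data rows found.", path))
  }
  header_line <- body_idx[1]
  delim <- detect_delim(lines[header_line])
  cols <- split_fields(lines[header_line], delim)
  if (!"concentration_M" %in% cols) {
    abort(sprintf("%s line %d: header must contain `concentration_M`.",
                  path, header_line))
  }
  response <- intersect(c("theta", "signal"), cols)
  if (!length(response)) {
    abort(sprintf("%s line %d: header must contain `theta` or `signal`.",
                  path, header_line))
  }
  response <- response[1]

  rows <- lapply(body_idx[-1], function(i) {
    fields <- split_fields(lines[i], delim)
    if (length(fields) != length(cols)) {
      abort(sprintf("%s line %d: expected %d fields, found %d.",
                    path, i, length(cols), length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals) & !fields %in% c("NA", ""))) {
      bad <- cols[which(is.na(vals))[1]]
      abort(sprintf("%s line %d: non-numeric value in column `%s`.",
                    path, i, bad))
    }
    setNames(as.list(vals), cols)
  })
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out$concentration_M)
  if (any(dup)) {
    abort(sprintf("%s line %d: duplicate concentration %g M.",
                  path, body_idx[-1][which(dup)[1]],
                  out$concentration_M[which(dup)[1]]))
  }
  out <- dplyr::arrange(out, .data$concentration_M)

  for (field in c("protein", "denaturant")) {
    if (!is.null(meta[[field]])) attr(out, field) <- meta[[field]]
  }
  for (field in c("temperature_K", "pH", "nu")) {
    if (!is.null(meta[[field]])) attr(out, field) <- as.numeric(meta[[field]])
  }
  attr(out, "response_type") <- response
  attr(out, "needs_normalization") <- identical(response, "signal")

  den <- meta$denaturant %||% ""
  if (max(out$concentration_M) < 0.05 &&
      !grepl("sds|dodecyl|surfactant", tolower(den))) {
    warn(paste0(
      "all concentrations are below 0.05 M; files must use molar units ",
      "(millimolar data, e.g. SDS, should be pre-converted)."))
  }
  out
}

parse_metadata <- function(lines) {
  lines <- sub("^\\s*#\\s*", "", lines)
  kv <- strsplit(lines[grepl("=", lines)], "=", fixed = TRUE)
  out <- lapply(kv, function(x) trimws(paste(x[-1], collapse = "=")))
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}

detect_delim <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else "ws"
}

split_fields <- function(line, delim) {
  if (delim == "ws") {
    strsplit(trimws(line), "\\s+")[[1]]
  } else {
    trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  }
}

#' Write an unfolding isotherm to a delimited text file
#'
#' Inverse of [read_isotherm()]: metadata attributes become `# key=value`
#' header lines and the table is written as CSV at full double precision,
#' so a write/read round trip is lossless.
#'
#' @param data isotherm tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (field in c("protein", "denaturant", "temperature_K", "pH", "nu")) {
    val <- attr(data, field, exact = TRUE)
    if (!is.null(val)) {
      writeLines(sprintf("# %s=%s", field, format(val, digits = 15)), con)
    }
  }
  writeLines(paste(names(data), collapse = ","), con)
  cells <- matrix(
    vapply(data, function(col) format(col, digits = 15, trim = TRUE,
                                      scientific = FALSE),
           character(nrow(data))),
    nrow = nrow(data))
  body <- apply(cells, 1, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' Normalize a raw spectroscopic signal to fraction unfolded
#'
#' Fits linear pre- and post-transition baselines `y_N(c)` and `y_U(c)`
#' on the concentration windows supplied, then converts the signal to
#' `theta = (y - y_N) / (y_U - y_N)`. With both windows `NULL` the signal
#' is taken as already normalized and copied to `theta` unchanged.
#'
#' @param data isotherm tibble with a `signal` column.
#' @param native_window,unfolded_window length-2 concentration intervals
#'   (M) containing at least two data points each, over which the folded
#'   and unfolded baselines are fitted.
#' @return The isotherm with a `theta` column replacing `signal`.
#' @export
normalize_signal <- function(data, native_window = NULL,
                             unfolded_window = NULL) {
  data <- as_isotherm(data, require_theta = FALSE)
  if (!"signal" %in% names(data)) {
    abort("`data` has no `signal` column to normalize.")
  }
  atts <- attributes(data)
  if (is.null(native_window) && is.null(unfolded_window)) {
    out <- dplyr::rename(data, theta = "signal")
  } else {
    if (is.null(native_window) || is.null(unfolded_window)) {
      abort("supply both baseline windows, or neither.")
    }
    y_N <- baseline_fit(data, native_window, "native")
    y_U <- baseline_fit(data, unfolded_window, "unfolded")
    denom <- y_U - y_N
    if (any(abs(denom) < 1e-12)) {
      abort("baselines coincide within the data range; cannot normalize.")
    }
    out <- dplyr::mutate(data, theta = (.data$signal - y_N) / denom)
    out <- dplyr::select(out, -"signal")
  }
  for (field in setdiff(names(atts), c("names", "row.names", "class"))) {
    attr(out, field) <- atts[[field]]
  }
  attr(out, "response_type") <- "theta"
  attr(out, "needs_normalization") <- FALSE
  out
}

baseline_fit <- function(data, window, which) {
  if (length(window) != 2L || window[2] < window[1]) {
    abort(sprintf("%s baseline window must be c(lo, hi).", which))
  }
  in_win <- data$concentration_M >= window[1] &
    data$concentration_M <= window[2]
  if (sum(in_win) < 2L) {
    abort(sprintf("%s baseline window contains fewer than 2 points.", which))
  }
  fit <- lm(signal ~ concentration_M, data = data[in_win, ])
  unname(predict(fit, newdata = data["concentration_M"]))
}

#' Write fit results as a literature-style summary table
#'
#' One CSV row per fitted isotherm, in the column layout of the
#' published parameter tables: protein, denaturant, temperature,
#' pH, midpoint, binding constant, cooperativity, transition range and
#' width, per-denaturant free energy `g_den` (the diffusive free energy,
#' negative), the free-energy change across the transition, and the LEM
#' comparator parameters (NA when no LEM fit is attached).
#'
#' @param fits a `coop_fit` or a list of them.
#' @param path output CSV file.
#' @return The assembled tibble, invisibly.
#' @export
write_results <- function(fits, path) {
  if (inherits(fits, "coop_fit")) fits <- list(fits)
  if (!length(fits)) abort("need at least one fit result.")
  rows <- purrr::map(fits, function(f) {
    stopifnot(inherits(f, "coop_fit"))
    tibble::tibble(
      protein = iso_meta(f$data, "protein", NA_character_),
      denaturant = iso_meta(f$data, "denaturant", NA_character_),
      temperature_K = f$params$temperature_K,
      pH = iso_meta(f$data, "pH", NA_real_),
      c_mid_M = f$c0,
      K_D_per_M = f$K_D,
      sigma = f$sigma,
      c_ini_M = f$range$c_ini,
      c_end_M = f$range$c_end,
      delta_c_M = f$range$delta_c,
      g_den_kcal_mol = f$thermo$g_den,
      delta_F_kcal_mol = f$delta_F,
      lem_delta_G0_kcal_mol = if (is.null(f$lem)) NA_real_ else
        f$lem$params$delta_G0,
      lem_m_kcal_L_mol2 = if (is.null(f$lem)) NA_real_ else
        f$lem$params$m_value
    )
  })
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, path)
  invisible(out)
}

#' Read a temperature series of unfolding free energies
#'
#' CSV (or tab/whitespace) file with columns `temperature_K` and
#' `delta_F_kcal_mol`, as consumed by [fit_thermal()].
#'
#' @param path file to read.
#' @return A tibble sorted by temperature.
#' @export
read_thermal_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  as_thermal_series(dplyr::arrange(out, .data$temperature_K))
}
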