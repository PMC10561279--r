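# isotherm tables: tibbles with a `concentration_M` column plus either
# `theta` (fraction unfolded) or `signal` (raw spectroscopic response);
# metadata (protein, denaturant, temperature_K, pH, nu) travels as
# attributes set by read_isotherm()/simulate_isotherm()

as_isotherm <- function(data, require_theta = TRUE, min_points = 5L) {
  data <- tibble::as_tibble(data)
  if (!"concentration_M" %in% names(data)) {
    abort("isotherm data must have a `concentration_M` column.")
  }
  if (require_theta && !"theta" %in% names(data)) {
    abort(paste0(
      "isotherm data must have a `theta` column; raw `signal` data needs ",
      "normalize_signal() first."))
  }
  if (nrow(data) < min_points) {
    abort(sprintf("isotherm needs at least %d points.", min_points))
  }
  cc <- data$concentration_M
  if (any(!is.finite(cc)) || any(cc < 0)) {
    abort("`concentration_M` must be non-negative and finite.")
  }
  if (is.unsorted(cc, strictly = TRUE)) {
    abort("`concentration_M` must be strictly increasing (no duplicates).")
  }
  data
}

iso_meta <- function(data, field, default = NULL) {
  attr(data, field, exact = TRUE) %||% default
}

#' Midpoint concentration of an unfolding isotherm
#'
#' Locates the first crossing of `theta = 1/2` by linear interpolation
#' between the bracketing data points. In the cooperative model the
#' denaturant binding constant is the reciprocal of this midpoint,
#' `K_D = 1/c0`.
#'
#' @param data isotherm data frame with columns `concentration_M` and
#'   `theta` (ascending concentrations, at least five points).
#' @return Midpoint concentration `c0`, M.
#' @export
#' @examples
#' p <- unfolding_params(0.25, 2e-3, 129, 298.15)
#' iso <- simulate_isotherm(p, 1, 7, n_points = 25)
#' estimate_midpoint(iso) # 4.0
estimate_midpoint <- function(data) {
  data <- as_isotherm(data)
  th <- data$theta
  cc <- data$concentration_M
  exact <- which(th == 0.5)
  if (length(exact)) return(cc[exact[1]])
  idx <- which(th[-1] > 0.5 & th[-length(th)] < 0.5)
  if (!length(idx)) {
    abort(paste0(
      "theta values never bracket 0.5; widen the concentration range ",
      "so the transition midpoint is covered."))
  }
  i <- idx[1]
  cc[i] + (0.5 - th[i]) * (cc[i + 1] - cc[i]) / (th[i + 1] - th[i])
}

#' Fit the multistate cooperative model to an unfolding isotherm
#'
#' The binding constant is fixed by the midpoint, `K_D = 1/c0` (from
#' [estimate_midpoint()]), leaving the cooperativity `sigma` as the single
#' free parameter. `sigma` is found by minimising the sum of squared
#' residuals in theta space on a `log10(sigma)` grid over `sigma_bounds`
#' (41 points by default), followed by a three-point parabolic refinement
#' of the grid minimum. With `joint = TRUE`, `K_D` and `sigma` are instead
#' optimised together (Nelder-Mead on the log scale) and the midpoint is
#' reported as `1/K_D`.
#'
#' @param data isotherm data frame (`concentration_M`, `theta`).
#' @param nu residues in the cooperative unit; defaults to the isotherm's
#'   `nu` attribute.
#' @param temperature_K absolute temperature; defaults to the isotherm's
#'   attribute.
#' @param method isotherm evaluation route passed to
#'   [fraction_unfolded()]: `"approx"` (default, the practitioner form) or
#'   `"exact"`.
#' @param sigma_bounds search interval for `sigma`, default `c(1e-6, 1)`.
#' @param n_grid number of log-spaced grid points, default 41.
#' @param theta_lo,theta_hi thresholds defining the reported transition
#'   range, defaults 0.01 and 0.95.
#' @param joint if `TRUE`, fit `K_D` jointly with `sigma` instead of
#'   pinning it at the reciprocal midpoint.
#' @param include_lem also fit the two-state LEM comparator to the same
#'   data (constrained form) and attach it to the result.
#' @return An object of class `coop_fit`; see [tidy.coop_fit()] and
#'   [glance.coop_fit()] for tabular views.
#' @export
#' @examples
#' p <- unfolding_params(0.245, 2e-3, 129, 298.15)
#' iso <- simulate_isotherm(p, 0.5, 8, n_points = 30)
#' fit <- fit_cooperative(iso, nu = 129, temperature_K = 298.15)
#' fit
fit_cooperative <- function(data, nu = NULL, temperature_K = NULL,
                            method = c("approx", "exact"),
                            sigma_bounds = c(1e-6, 1), n_grid = 41L,
                            theta_lo = 0.01, theta_hi = 0.95,
                            joint = FALSE, include_lem = TRUE) {
  method <- match.arg(method)
  data <- as_isotherm(data)
  nu <- nu %||% iso_meta(data, "nu")
  temperature_K <- temperature_K %||% iso_meta(data, "temperature_K")
  if (is.null(nu) || is.null(temperature_K)) {
    abort("`nu` and `temperature_K` must be supplied or carried as attributes.")
  }
  stopifnot(sigma_bounds[1] > 0, sigma_bounds[2] <= 1,
            sigma_bounds[1] < sigma_bounds[2])

  c0 <- estimate_midpoint(data)
  K_D <- 1 / c0
  sse_of <- function(K_D, sigma) {
    p <- unfolding_params(K_D, sigma, nu, temperature_K)
    sum((fraction_unfolded(p, data$concentration_M, method = method) -
           data$theta)^2)
  }

  lg <- seq(log10(sigma_bounds[1]), log10(sigma_bounds[2]),
            length.out = n_grid)
  sse_grid <- vapply(lg, function(x) sse_of(K_D, 10^x), numeric(1))
  i <- which.min(sse_grid)
  lg_best <- lg[i]
  sse_best <- sse_grid[i]
  converged <- TRUE
  if (i > 1L && i < length(lg)) {
    lg_ref <- parabolic_vertex(lg[(i - 1):(i + 1)], sse_grid[(i - 1):(i + 1)])
    if (is.finite(lg_ref) &&
        lg_ref >= log10(sigma_bounds[1]) &&
        lg_ref <= log10(sigma_bounds[2])) {
      sse_ref <- sse_of(K_D, 10^lg_ref)
      if (sse_ref <= sse_best) {
        lg_best <- lg_ref
        sse_best <- sse_ref
      }
    } else {
      converged <- FALSE
      warn("parabolic refinement failed; reporting best grid point.")
    }
  }
  sigma <- 10^lg_best

  if (joint) {
    opt <- optim(
      c(log10(K_D), lg_best),
      function(par) {
        s <- 10^par[2]
        if (s > 1) return(1e6 + par[2])
        sse_of(10^par[1], s)
      },
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000)
    )
    K_D <- 10^opt$par[1]
    sigma <- min(10^opt$par[2], 1)
    sse_best <- opt$value
    c0 <- 1 / K_D
    converged <- opt$convergence == 0
  }

  params <- unfolding_params(K_D, sigma, nu, temperature_K)
  fitted <- fraction_unfolded(params, data$concentration_M, method = method)
  residuals <- data$theta - fitted
  sstot <- sum((data$theta - mean(data$theta))^2)
  r_squared <- if (sstot > 0) 1 - sse_best / sstot else NA_real_
  rng <- transition_range(params, theta_lo, theta_hi,
                          method = if (method == "exact") "exact" else "approx")
  fit <- structure(
    list(
      params = params, c0 = c0, K_D = K_D, sigma = sigma,
      sse = sse_best, r_squared = r_squared,
      range = rng,
      delta_F = free_energy_change(params, rng, method = "matrix"),
      thermo = thermo_summary(rng$c_ini, rng$c_end, sigma, temperature_K),
      residuals = residuals, fitted = fitted, data = data,
      method = method, joint = joint, converged = converged,
      lem = NULL
    ),
    class = "coop_fit"
  )
  if (include_lem) {
    fit$lem <- fit_lem(data, temperature_K = temperature_K,
                       constrained = TRUE)
  }
  fit
}

# vertex of the parabola through three (x, y) points
parabolic_vertex <- function(x, y) {
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (!is.finite(curv) || curv <= 0) return(NA_real_)
  (x[1] + x[2]) / 2 - d21 / (2 * curv)
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("Multistate cooperative fit\n")
  cat(sprintf("  c0 = %.4g M, K_D = 1/c0 = %.4g M^-1\n", x$c0, x$K_D))
  cat(sprintf("  sigma = %.4g  (nu = %d, T = %g K, %s isotherm)\n",
              x$sigma, x$params$nu, x$params$temperature_K, x$method))
  cat(sprintf("  transition %.3g-%.3g M, dF = %.4g kcal/mol\n",
              x$range$c_ini, x$range$c_end, x$delta_F))
  cat(sprintf("  SSE = %.3g, R^2 = %.5f on %d points\n",
              x$sse, x$r_squared, nrow(x$data)))
  if (!is.null(x$lem)) {
    cat(sprintf("  LEM comparator: dG0 = %.4g kcal/mol, m = %.4g kcal L/mol^2\n",
                x$lem$params$delta_G0, x$lem$params$m_value))
  }
  invisible(x)
}

#' Fit the linear extrapolation method to an unfolding isotherm
#'
#' Least-squares fit of the two-state LEM isotherm in theta space. The
#' default constrained form honours the midpoint identity `m = dG0 / c0`
#' (with `c0` interpolated from the data), leaving `dG0` as the single
#' parameter; the unconstrained form fits `dG0` and `m` independently, as
#' is common in spectroscopic practice.
#'
#' @inheritParams fit_cooperative
#' @param constrained fit the one-parameter midpoint-constrained form
#'   (default) or the conventional two-parameter form.
#' @return An object of class `lem_fit` with elements `params`
#'   ([lem_params()]), `sse`, `r_squared`, `residuals`, `fitted`,
#'   `constrained`.
#' @export
fit_lem <- function(data, temperature_K = NULL, constrained = TRUE) {
  data <- as_isotherm(data)
  temperature_K <- temperature_K %||% iso_meta(data, "temperature_K")
  if (is.null(temperature_K)) {
    abort("`temperature_K` must be supplied or carried as an attribute.")
  }
  c0 <- estimate_midpoint(data)
  sse_of <- function(p) {
    sum((lem_fraction_unfolded(p, data$concentration_M, temperature_K) -
           data$theta)^2)
  }
  if (constrained) {
    opt <- optimize(function(dG0) sse_of(lem_params(delta_G0 = dG0, c0 = c0)),
                    interval = c(1e-4, 200), tol = 1e-10)
    params <- lem_params(delta_G0 = opt$minimum, c0 = c0)
    sse <- opt$objective
  } else {
    start <- optimize(function(dG0) sse_of(lem_params(delta_G0 = dG0, c0 = c0)),
                      interval = c(1e-4, 200), tol = 1e-8)$minimum
    opt <- optim(c(start, start / c0),
                 function(par) {
                   if (par[2] <= 0) return(1e6 - par[2])
                   sse_of(lem_params(delta_G0 = par[1], m_value = par[2]))
                 },
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    params <- lem_params(delta_G0 = opt$par[1], m_value = opt$par[2])
    sse <- opt$value
  }
  fitted <- lem_fraction_unfolded(params, data$concentration_M, temperature_K)
  sstot <- sum((data$theta - mean(data$theta))^2)
  structure(
    list(params = params, sse = sse,
         r_squared = if (sstot > 0) 1 - sse / sstot else NA_real_,
         residuals = data$theta - fitted, fitted = fitted,
         temperature_K = temperature_K, data = data,
         constrained = constrained),
    class = "lem_fit"
  )
}

#' @export
print.lem_fit <- function(x, ...) {
  cat(sprintf("LEM fit (%s)\n",
              if (x$constrained) "constrained, m = dG0/c0" else "unconstrained"))
  cat(sprintf("  dG0 = %.4g kcal/mol, m = %.4g kcal L/mol^2, c0 = %.4g M\n",
              x$params$delta_G0, x$params$m_value, x$params$c0))
  cat(sprintf("  SSE = %.3g, R^2 = %.5f\n", x$sse, x$r_squared))
  invisible(x)
}

#' Predicted calorimetric titration heat
#'
#' Cumulative heat released per mole of protein when titrating with
#' denaturant: `Q(c_D) = dH0 * Theta_U(c_D)`, a sigmoidal curve that
#' plateaus at the total unfolding enthalpy `dH0` and passes through
#' `dH0 / 2` at the midpoint.
#'
#' @inheritParams fraction_unfolded
#' @param delta_H0 total unfolding enthalpy, kcal per mol protein.
#' @return Heat(s), kcal per mol protein.
#' @export
predict_titration_heat <- function(params, delta_H0, c_D,
                                   method = c("exact", "approx")) {
  method <- match.arg(method)
  check_number(delta_H0, "delta_H0")
  delta_H0 * fraction_unfolded(params, c_D, method = method)
}

#' Unfolding enthalpy from a calorimetric titration
#'
#' Least-squares scale factor mapping the model isotherm onto measured
#' heats per mole protein: `dH0 = sum(Q * Theta) / sum(Theta^2)`.
#'
#' @param data data frame with columns `concentration_M` and
#'   `heat_kcal_mol` (heat per mole protein).
#' @inheritParams fraction_unfolded
#' @return Fitted `dH0`, kcal per mol protein.
#' @export
fit_titration_enthalpy <- function(data, params,
                                   method = c("exact", "approx")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  need <- c("concentration_M", "heat_kcal_mol")
  if (!all(need %in% names(data))) {
    abort("titration data must have columns `concentration_M`, `heat_kcal_mol`.")
  }
  th <- fraction_unfolded(params, data$concentration_M, method = method)
  if (all(th == 0)) {
    abort("model isotherm is identically zero over these concentrations.")
  }
  sum(data$heat_kcal_mol * th) / sum(th^2)
}
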