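#' Denaturant binding weight
#'
#' Statistical weight of an unfolded residue at the end of a native
#' stretch, relative to a native residue: `q = K_D * c_D`. A residue that
#' starts a new unfolded block inside a native segment carries the reduced
#' weight `sigma * q`. The transition midpoint is the concentration at
#' which `q = 1`, i.e. `c0 = 1/K_D`.
#'
#' @param K_D binding constant, M^-1.
#' @param c_D denaturant concentration(s), M.
#' @return Dimensionless weight(s), one per element of `c_D`.
#' @export
#' @examples
#' binding_weight(0.25, 4.0) # 1 at the midpoint
binding_weight <- function(K_D, c_D) {
  check_number(K_D, "K_D", lower = 0, closed_lower = FALSE)
  check_concentration(c_D)
  K_D * c_D
}

# 2x2 Zimm-Bragg transfer matrix.
# Rows index the state of residue i-1 (n, u); columns the state of
# residue i. Weights: n->n 1, n->u sigma*q, u->n 1, u->u q. The chain is
# generated from a native start vector (1, 0) and closed with (1, 1)', so
# an unfolded block at the chain start pays the nucleation factor sigma.
zb_matrix <- function(q, sigma) {
  matrix(c(1, 1, sigma * q, q), nrow = 2)
}

#' Log partition function of the cooperative unfolding model
#'
#' Evaluates `ln Z(q)` for a chain of `nu` residues, either through the
#' transfer-matrix product (any `nu`, log-space scaled so large chains do
#' not overflow) or by explicit enumeration of all `2^nu` residue-state
#' sequences (an independent brute-force route, only for `nu <= 16`).
#' In the noncooperative limit `sigma = 1` the partition function reduces
#' to `(1 + q)^nu`.
#'
#' @param q binding weight(s), dimensionless, `>= 0`.
#' @param sigma cooperativity parameter in (0, 1].
#' @param nu number of residues, positive integer.
#' @param method `"matrix"` (default) or `"enumerate"`.
#' @return `ln Z`, same length as `q`.
#' @export
#' @examples
#' ln_partition(1.2, sigma = 1, nu = 10) # 10 * log(2.2)
ln_partition <- function(q, sigma, nu, method = c("matrix", "enumerate")) {
  method <- match.arg(method)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    abort("`q` must be non-negative and finite.")
  }
  check_number(sigma, "sigma", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(nu, "nu", lower = 1)
  nu <- as.integer(round(nu))
  if (method == "enumerate" && nu > 16L) {
    abort("enumerate route refuses nu > 16 (2^nu states).")
  }
  fun <- if (method == "matrix") ln_Z_matrix else ln_Z_enumerate
  vapply(q, fun, numeric(1), sigma = sigma, nu = nu)
}

# scaled power iteration; returns ln Z for scalar q
ln_Z_matrix <- function(q, sigma, nu) {
  M <- zb_matrix(q, sigma)
  v <- c(1, 0)
  log_scale <- 0
  for (i in seq_len(nu)) {
    v <- v %*% M
    s <- max(abs(v))
    v <- v / s
    log_scale <- log_scale + log(s)
  }
  log_scale + log(sum(v))
}

# brute-force sum over all residue-state sequences; each maximal block of
# unfolded residues contributes sigma * q^(block length), including a
# block at the chain start
ln_Z_enumerate <- function(q, sigma, nu) {
  bits <- state_bits(nu)
  n_u <- rowSums(bits)
  log(sum(sigma^u_block_counts(bits) * q^n_u))
}

# all 2^nu residue-state sequences as a 0/1 matrix (1 = unfolded)
state_bits <- function(nu) {
  states <- 0:(2L^nu - 1L)
  m <- vapply(0:(nu - 1L),
              function(b) bitwAnd(bitwShiftR(states, b), 1L),
              integer(length(states)))
  matrix(m, ncol = nu)
}

# maximal u-block count per sequence (n->u transitions, chain start
# counted as native)
u_block_counts <- function(bits) {
  nu <- ncol(bits)
  if (nu == 1L) return(bits[, 1])
  interior <- (bits[, -1, drop = FALSE] == 1L) &
    (bits[, -nu, drop = FALSE] == 0L)
  bits[, 1] + rowSums(interior)
}

#' Largest eigenvalue of the transfer matrix
#'
#' Closed-form dominant eigenvalue
#' `lambda0 = ((1 + q) + sqrt((1 - q)^2 + 4 sigma q)) / 2`. For long
#' chains `Z ~ lambda0^nu`, which is the practical approximation for
#' chemical unfolding where `sigma >= 1e-3`. At `sigma = 1` it collapses
#' to `1 + q`; at the midpoint `q = 1` it equals `1 + sqrt(sigma)`.
#'
#' @inheritParams ln_partition
#' @return `lambda0`, same length as `q`.
#' @export
lambda0 <- function(q, sigma) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    abort("`q` must be non-negative and finite.")
  }
  check_number(sigma, "sigma", lower = 0, upper = 1, closed_lower = FALSE)
  ((1 + q) + sqrt((1 - q)^2 + 4 * sigma * q)) / 2
}

#' Fraction of unfolded protein
#'
#' The unfolding isotherm `Theta_U(c_D)`: the mean fraction of residues in
#' the unfolded state at denaturant concentration `c_D`.
#'
#' * `method = "exact"`: `Theta = (1/nu) d ln Z / d ln q` on the
#'   transfer-matrix partition function. The derivative is propagated
#'   analytically through the scaled matrix product, so no numerical
#'   differencing is involved.
#' * `method = "approx"`: the large-chain (largest-eigenvalue) form
#'   `Theta = (1 + (q - 1) / sqrt((1 - q)^2 + 4 sigma q)) / 2`,
#'   independent of `nu` and exactly 1/2 at the midpoint `q = 1`.
#'
#' In the noncooperative limit `sigma = 1` both routes give the Langmuir
#' adsorption isotherm `q / (1 + q)`.
#'
#' @param params an [unfolding_params()] object.
#' @param c_D denaturant concentration(s), M.
#' @param method `"exact"` or `"approx"`.
#' @return Fraction(s) unfolded in `[0, 1]`.
#' @export
#' @examples
#' p <- unfolding_params(0.25, 1e-3, 129, 298.15)
#' fraction_unfolded(p, c(2, 4, 6))
fraction_unfolded <- function(params, c_D, method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "unfolding_params"))
  q <- binding_weight(params$K_D, c_D)
  if (method == "approx") {
    theta_approx(q, params$sigma)
  } else {
    vapply(q, theta_exact, numeric(1),
           sigma = params$sigma, nu = params$nu)
  }
}

theta_approx <- function(q, sigma) {
  0.5 * (1 + (q - 1) / sqrt((1 - q)^2 + 4 * sigma * q))
}

# Theta = q * (dZ/dq) / (nu * Z); dZ/dq carried alongside the scaled
# vector iteration: d(vM) = (dv) M + v (dM/dq), dM/dq = [[0, sigma],[0, 1]]
theta_exact <- function(q, sigma, nu) {
  if (q == 0) return(0)
  M <- zb_matrix(q, sigma)
  dM <- matrix(c(0, 0, sigma, 1), nrow = 2)
  v <- c(1, 0)
  dv <- c(0, 0)
  for (i in seq_len(nu)) {
    dv <- dv %*% M + v %*% dM
    v <- v %*% M
    s <- max(abs(v))
    v <- v / s
    dv <- dv / s
  }
  Z <- sum(v)
  q * sum(dv) / (nu * Z)
}

#' Free-energy change of unfolding
#'
#' `Delta F(c_D)` of the cooperative unit relative to the native protein,
#' whose partition function at `c_D = 0` is `Z(0) = 1` (zero free energy).
#'
#' * `"matrix"`: `-RT ln Z(c_D)`, the exact route.
#' * `"lambda0"`: `-RT nu ln lambda0`, the large-chain approximation.
#' * `"asymptote"`: `-RT nu ln(K_D c_D)`, valid well beyond the midpoint
#'   (`K_D c_D > 1`); outside that regime the value is returned as `NA`
#'   with a warning, since the asymptote would be positive there.
#'
#' @inheritParams fraction_unfolded
#' @param method `"matrix"`, `"lambda0"` or `"asymptote"`.
#' @return Free-energy change(s), kcal/mol of cooperative unit.
#' @export
#' @examples
#' p <- unfolding_params(0.26, 1e-3, 129, 303.15)
#' free_energy(p, 5.3, method = "asymptote") # about -24.9 kcal/mol
free_energy <- function(params, c_D,
                        method = c("matrix", "lambda0", "asymptote")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "unfolding_params"))
  q <- binding_weight(params$K_D, c_D)
  RT <- R_KCAL * params$temperature_K
  switch(method,
    matrix = -RT * ln_partition(q, params$sigma, params$nu),
    lambda0 = -RT * params$nu * log(lambda0(q, params$sigma)),
    asymptote = {
      out <- -RT * params$nu * log(q)
      bad <- q <= 1
      if (any(bad)) {
        warn(sprintf(
          "asymptotic free energy invalid for %d point(s) with K_D*c_D <= 1; returning NA there",
          sum(bad)))
        out[bad] <- NA_real_
      }
      out
    }
  )
}

#' Free-energy profile over a concentration grid
#'
#' Tabulates `Delta F(c_D)` on an ascending concentration grid together
#' with the binding weight and fraction unfolded, ready for plotting or
#' export.
#'
#' @inheritParams free_energy
#' @param c_grid strictly ascending concentrations, M.
#' @return A tibble of class `fe_profile` with columns `concentration_M`,
#'   `q`, `theta`, `delta_F_kcal_mol`, `valid`, and a `method` attribute.
#' @export
free_energy_profile <- function(params, c_grid,
                                method = c("matrix", "lambda0",
                                           "asymptote")) {
  method <- match.arg(method)
  check_concentration(c_grid, "c_grid")
  if (is.unsorted(c_grid, strictly = TRUE)) {
    abort("`c_grid` must be strictly ascending.")
  }
  dF <- withCallingHandlers(
    free_energy(params, c_grid, method = method),
    warning = function(w) invokeRestart("muffleWarning")
  )
  theta_method <- if (method == "matrix") "exact" else "approx"
  out <- tibble::tibble(
    concentration_M = c_grid,
    q = binding_weight(params$K_D, c_grid),
    theta = fraction_unfolded(params, c_grid, method = theta_method),
    delta_F_kcal_mol = dF,
    valid = !is.na(dF)
  )
  structure(out, method = method, params = params,
            class = c("fe_profile", class(out)))
}

#' Concentration at a target fraction unfolded
#'
#' Inverts the monotone isotherm `Theta(c_D)` by bisection, to
#' `|Theta - target| <= 1e-9`. Used to locate transition onset and
#' completion concentrations.
#'
#' @inheritParams fraction_unfolded
#' @param theta_target target fraction in (0, 1).
#' @param tol bisection tolerance on the fraction unfolded.
#' @return Concentration in M at which `Theta = theta_target`.
#' @export
#' @examples
#' p <- unfolding_params(0.258, 1e-3, 129, 303.15)
#' concentration_at_fraction(p, 0.99, method = "approx") # about 5.29 M
concentration_at_fraction <- function(params, theta_target,
                                      method = c("exact", "approx"),
                                      tol = 1e-9) {
  method <- match.arg(method)
  check_number(theta_target, "theta_target", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  f <- function(c_D) fraction_unfolded(params, c_D, method = method)
  lo <- 0
  hi <- 2 / params$K_D
  while (f(hi) < theta_target) {
    hi <- hi * 2
    if (hi > 1e12) abort("failed to bracket the target fraction.")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - theta_target) <= tol) return(mid)
    if (val < theta_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Transition concentration range
#'
#' The interval `[c_ini, c_end]` over which unfolding proceeds from
#' `theta_lo` to `theta_hi` (defaults 0.01 and 0.95, the conventional
#' extent of the chemically observable transition).
#'
#' @inheritParams concentration_at_fraction
#' @param theta_lo,theta_hi fraction-unfolded thresholds,
#'   `0 < theta_lo < theta_hi < 1`.
#' @return A list of class `transition_range` with `c_ini`, `c_end`,
#'   `delta_c`, `theta_lo`, `theta_hi`.
#' @export
transition_range <- function(params, theta_lo = 0.01, theta_hi = 0.95,
                             method = c("exact", "approx")) {
  method <- match.arg(method)
  if (!(theta_lo > 0 && theta_lo < theta_hi && theta_hi < 1)) {
    abort("need 0 < theta_lo < theta_hi < 1.")
  }
  c_ini <- concentration_at_fraction(params, theta_lo, method = method)
  c_end <- concentration_at_fraction(params, theta_hi, method = method)
  structure(list(c_ini = c_ini, c_end = c_end, delta_c = c_end - c_ini,
                 theta_lo = theta_lo, theta_hi = theta_hi),
            class = "transition_range")
}

#' @export
print.transition_range <- function(x, ...) {
  cat(sprintf(
    "Transition range: %.3f M (theta = %g) to %.3f M (theta = %g), delta_c = %.3f M\n",
    x$c_ini, x$theta_lo, x$c_end, x$theta_hi, x$delta_c))
  invisible(x)
}

#' Free-energy change across the unfolding transition
#'
#' `Delta F(c_end) - Delta F(c_ini)` by the chosen free-energy route;
#' never positive, since `Delta F` is non-increasing in concentration.
#'
#' @inheritParams free_energy
#' @param range a [transition_range()] object, or a list with `c_ini` and
#'   `c_end`.
#' @return Free-energy difference, kcal/mol of cooperative unit.
#' @export
free_energy_change <- function(params, range,
                               method = c("matrix", "lambda0",
                                          "asymptote")) {
  method <- match.arg(method)
  if (range$c_end < range$c_ini) {
    abort("`c_end` must not be smaller than `c_ini`.")
  }
  ends <- free_energy(params, c(range$c_ini, range$c_end), method = method)
  ends[2] - ends[1]
}
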