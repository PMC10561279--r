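---
title: "A multistate cooperative model of chemical protein unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multistate cooperative model of chemical protein unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopunfold)
library(ggplot2)
```

## The model

Chemical denaturants such as guanidine HCl, urea and SDS unfold proteins
by binding to backbone and side-chain sites. `coopunfold` treats
unfolding at the level of individual residues: each of the $\nu$ amino
acids of a cooperative unit is either native (n) or unfolded (u), and a
denaturant molecule binding to a residue at the end of a native stretch
converts it with statistical weight

$$q(c_D) = K_D\, c_D,$$

where $K_D$ (M$^{-1}$) is the denaturant binding constant and $c_D$ the
denaturant concentration. Starting a *new* unfolded block inside a
native segment is penalised by the cooperativity (nucleation) parameter
$\sigma \le 1$, so that residue carries weight $\sigma q$. These are the
Zimm–Bragg statistics of the helix–coil transition transplanted to
chemical denaturation. The chain partition function is generated by the
2×2 transfer matrix

$$\mathbf{M} = \begin{pmatrix} 1 & \sigma q \\ 1 & q \end{pmatrix},
\qquad
Z(c_D) = (1,\,0)\, \mathbf{M}^{\nu} \begin{pmatrix}1\\1\end{pmatrix},$$

with rows indexing the state of the preceding residue. The start vector
$(1,0)$ represents a native boundary, so an unfolded block at the chain
start also pays $\sigma$ — the same counting rule the brute-force
enumeration oracle in the test-suite uses (every maximal u-block
contributes one factor of $\sigma$). At $\sigma = 1$ the matrix product
collapses to $Z = (1+q)^\nu$ and the isotherm to the Langmuir form
$q/(1+q)$.

The two observables derived from $Z$ are the fraction of unfolded
residues and the unfolding free energy of the cooperative unit,

$$\Theta_U = \frac{1}{\nu}\frac{\partial \ln Z}{\partial \ln q},
\qquad
\Delta F(c_D) = -RT \ln Z(c_D),$$

with the native protein as reference state: $Z(0) = 1$, hence
$\Delta F(0) = 0$ and $\Delta F$ decreases monotonically with
concentration. The derivative for $\Theta_U$ is propagated analytically
through the scaled matrix product (carrying $dZ/dq$ alongside $Z$), so
the exact isotherm involves no numerical differencing at any chain
length.

For practitioners the package also implements the large-chain
approximation built on the dominant eigenvalue of $\mathbf{M}$,

$$\lambda_0 = \tfrac12\left[(1+q) + \sqrt{(1-q)^2 + 4\sigma q}\right],
\qquad
\Theta_U \approx \tfrac12\left[1 + \frac{q-1}
{\sqrt{(1-q)^2+4\sigma q}}\right],$$

with $\Delta F \approx -RT\nu \ln\lambda_0$, and the deep-unfolding
asymptote $\Delta F \approx -RT\nu\ln(K_D c_D)$, valid for
$K_D c_D > 1$ (points outside that regime are flagged invalid). The
approximate isotherm is exactly $1/2$ at the midpoint $c_0$, which
yields the model's signature relation

$$K_D = 1/c_0:$$

the binding constant is the reciprocal of the midpoint concentration of
unfolding.

## Which route matches the published tables

The three free-energy routes are not interchangeable, and the choice is
a genuine design decision:

* The **matrix** route with the native-start boundary regenerates the
  published lysozyme/GndHCl free-energy changes across the transition
  directly from each row's own parameters: nine of the twelve bundled
  temperature rows agree to ≤ 0.1 kcal/mol (e.g. −21.7 kcal/mol at
  30 °C over 2.9–5.3 M), as do the two 25 °C survey rows (−24.6 and
  −23.3 kcal/mol) and the −2.0 kcal/mol plateau at the midpoint. Three
  rows (40 °C, one 25 °C and marginally one 10 °C source) cannot be
  regenerated from their own printed parameters under any route and are
  treated as source inconsistencies in the tests.
* The **lambda0** route differs from the matrix route by roughly the
  nucleation free energy $RT|\ln\sigma|$ (≈ 4 kcal/mol for
  $\sigma=10^{-3}$ at room temperature), because the finite chain pays
  at least one nucleation event that the eigenvalue limit amortises
  away. It gives ≈ −24.3 kcal/mol for the 30 °C row above.
* The **asymptote** agrees with the lambda0 route to within 2% once
  $K_D c_D \ge 2$ and $\sigma \le 10^{-2}$ (validated in the tests).

The same boundary effect separates the exact and approximate isotherms.
The measured maximum gap over the transition region scales as

$$\max_q |\Theta_{\mathrm{exact}} - \Theta_{\mathrm{approx}}|
\approx \frac{0.62}{\nu\sqrt{\sigma}},$$

so for a lysozyme-sized cooperative unit ($\nu = 129$) at
$\sigma = 10^{-3}$ the exact finite-chain isotherm lags the
approximation by up to 0.15 near the midpoint, and the two only agree
to ≤ 0.02 once $\nu\sqrt{\sigma} \gtrsim 31$ (e.g. $\nu = 1000$ at
$\sigma = 10^{-3}$, or $\nu = 129$ at $\sigma \gtrsim 0.06$). The
property tests assert this validated bound rather than a flat
tolerance; analyses that need the exact-at-$c_0$ = 1/2 identity should
use the approximate isotherm, which is also what the fitting layer uses
by default.

```{r routes, fig.width = 6, fig.height = 4}
p <- unfolding_params(K_D = 0.25, sigma = 1e-3, nu = 129,
                      temperature_K = 298.15)
autoplot(free_energy_profile(p, seq(0, 8, by = 0.1)))
```

## Derived thermodynamics

Unfolding proceeds over a concentration window
$[c_{\mathrm{ini}}, c_{\mathrm{end}}]$, reported by
`transition_range()` for thresholds $\Theta_U$ = 0.01 and 0.95 by
default (the conventional extent of the observable transition; both
thresholds are explicit arguments because published completion points
are sometimes consistent with 0.99). The gradient across the window
carries the diffusive (osmotic) free energy

$$\Delta G_{\mathrm{diff}} = RT\ln\frac{c_{\mathrm{ini}}}{c_{\mathrm{end}}},$$

and the per-residue n→u transition energy is its exact negative,
$\Delta g_{\nu} + \Delta G_{\mathrm{diff}} = 0$ — the reversibility
identity of the model. Result tables mirror the literature convention
by reporting the negative quantity as `g_den`. The nucleation penalty
$-RT\ln\sigma$ is reported alongside.

The temperature dependence of $\Delta F$ gives the unfolding entropy by
ordinary least squares ($\Delta S = -\mathrm{d}\Delta F/\mathrm{d}T$;
the regression is unweighted because published series carry no error
model), and the enthalpy follows per point as
$\Delta H_i = \Delta F_i + T_i\Delta S$:

```{r thermal}
fit_thermal(lysozyme_thermal_series())
```

The bundled series is restricted to the 10–25 °C rows of its single
consistent source; the 35 °C point departs from the linear regime and
is excluded by default (`max_temp_C`).

## The LEM comparator

The linear extrapolation method is the two-state analysis the
cooperative model argues against: $\Delta G = \Delta G_0^{H_2O} - m\,
c_D$, a logistic isotherm $K/(1+K)$ with $K = e^{-\Delta G/RT}$.
Because $\Delta G(c_0) = 0$, the slope is not an independent parameter:
$m = \Delta G_0/c_0$. `fit_lem()` therefore defaults to the
one-parameter constrained fit and offers the conventional unconstrained
two-parameter fit behind a flag. Both models predict exactly 50%
unfolding at the midpoint; they differ radically in the free energy
they assign to the native state (large positive for the LEM, zero for
the cooperative model).

## Fitting strategy

`fit_cooperative()` follows the model's own logic: $c_0$ is read off
the data by linear interpolation of the first crossing of
$\Theta = 1/2$, $K_D$ is pinned at $1/c_0$, and the cooperativity is
the single free parameter, minimising squared residuals in $\Theta$
space (after any baseline normalisation; residuals are unweighted) on a
41-point $\log_{10}\sigma$ grid over $[10^{-6}, 1]$ — wide enough to
reach thermal-unfolding cooperativities — followed by a three-point
parabolic refinement of the grid minimum. A joint $(K_D, \sigma)$
Nelder–Mead fit is available behind `joint = TRUE`; the midpoint is
then reported as $1/K_D$ so the reciprocal identity always holds.
$\nu$ is user-supplied and defaults to the full chain length, the
convention used for the bundled lysozyme parameters ($\nu = 129$).

Calorimetric denaturant titrations are modelled as
$Q(c_D) = \Delta H_0\,\Theta_U(c_D)$; the unfolding enthalpy is the
closed-form least-squares scale factor of the model isotherm onto the
measured heats.

## Synthetic data and what the tests show

The generators in `simulate_isotherm()`, `simulate_thermal_series()`
and `simulate_titration()` emulate the study conditions of the bundled
parameter tables: lysozyme-like cooperative units ($\nu = 129$),
guanidine-HCl-like binding ($K_D \approx 0.25$ M$^{-1}$, midpoints near
4 M), cooperativities $10^{-3}$–$10^{-2}$, 25-point isotherms spanning
$\Theta$ from a few percent to ~98%, additive Gaussian noise in
$\Theta$ space (sd 0.01–0.02, the scatter typical of normalised
spectroscopic data) lightly clipped to $[-0.05, 1.05]$, titration noise
of 1 kcal/mol on heats, and 0.5 kcal/mol on free energies in
temperature series of four points. Recovery tests under fixed seeds
(K_D within 3%, $\log_{10}\sigma$ within ±0.3, $\Delta H_0$ within 5%)
demonstrate estimator consistency under exactly these conditions; they
do not probe instrument drift, correlated baselines, aggregation
artifacts or any systematic error structure of real spectroscopic
data, nor midpoints drifting during slow equilibration.

Problem sizes throughout the suite are desk-scale: enumeration oracles
run to $\nu = 14$ ($2^{14}$ states), Monte-Carlo checks use a few
hundred seeds, and the largest chains evaluated are $\nu = 3000$.

## Numerical choices

* $R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; Celsius offset
  273.15. Published values mixing 298 and 298.15 K differ by < 0.1%.
* All partition-function work is done in log space with per-step
  rescaling of the state vector, so $\nu$ in the thousands poses no
  overflow risk.
* Isotherm inversion is by bisection to $|\Theta - \text{target}| \le
  10^{-9}$ after geometric bracket expansion; $\Theta$ is strictly
  monotone so the root is unique.
* The enumeration route refuses $\nu > 16$ (combinatorial blowup); it
  exists as an independent oracle, not a production path.
* Degenerate inputs fail loudly: non-bracketed midpoints, baseline
  windows with fewer than two points, coincident baselines,
  non-increasing temperature series and malformed isotherm files all
  raise descriptive errors (with line numbers for file input).

## Known limitations

* One homogeneous binding constant per denaturant: no per-residue
  affinities, no intermediate-explicit (three-state) models.
* $K_D(T)$ is not parameterised; each temperature is fitted
  independently, and heat-capacity corrections are out of scope.
* The LEM is implemented as a comparator; its $\Delta G_0^{H_2O}$ is
  reported as fitted, without endorsing it as a thermodynamic quantity.
* Fits assume the supplied $\nu$; misspecifying the cooperative-unit
  size rescales $\sigma$ and $\Delta F$ but leaves $K_D$ untouched.
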