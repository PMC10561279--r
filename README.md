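# coopunfold

Multistate cooperative analysis of chemical protein unfolding.

## The problem

Chemical denaturation — titrating a protein with guanidine HCl, urea or
SDS and recording the fraction unfolded — is a standard assay of
conformational stability, routinely analysed with the empirical linear
extrapolation method (LEM). The LEM assigns a large *positive* free
energy ΔG₀^H₂O to the native protein and extrapolates linearly in
denaturant concentration, which sits uneasily with the view that the
native state is the free-energy minimum. `coopunfold` implements the
alternative: a multistate cooperative model in which the denaturant
binds residue by residue and unfolding propagates through Zimm–Bragg
statistics. It is aimed at biophysicists and protein-stability groups
who want to fit unfolding isotherms, compare the cooperative model
against the LEM on the same data, and extract unfolding entropy and
enthalpy from temperature series.

## The model

Each of the ν residues of a cooperative unit is native (n) or unfolded
(u). A denaturant at concentration c_D converts a residue at the end of
a native stretch with weight q = K_D·c_D; starting a new unfolded block
costs the cooperativity (nucleation) factor σ ≤ 1. The chain partition
function is the Zimm–Bragg transfer-matrix product

    Z(c_D) = (1, 0) · M^ν · (1, 1)ᵀ,   M = | 1  σq |
                                           | 1   q |

with the native protein as reference (Z(0) = 1). From Z follow the
unfolding isotherm Θ_U = (1/ν) ∂lnZ/∂ln q and the free energy
ΔF(c_D) = −RT ln Z(c_D). For long chains the dominant eigenvalue
λ₀ = ½[(1+q) + √((1−q)² + 4σq)] gives the practitioner's approximation
Θ_U ≈ ½[1 + (q−1)/√((1−q)²+4σq)], which is exactly ½ at the midpoint —
hence the model's signature relation **K_D = 1/c₀**: the binding
constant is the reciprocal of the midpoint concentration. At σ = 1 the
model collapses to the Langmuir isotherm q/(1+q). Derived quantities
include the diffusive free energy of the transition gradient
ΔG_diff = RT·ln(c_ini/c_end), its exact negative, the per-residue
transition energy Δg_ν, the nucleation penalty −RT·ln σ, and van't Hoff
entropy/enthalpy from ΔF(T) series. See the methods vignette
(`vignettes/cooperative-unfolding.Rmd`) for conventions and validated
approximation bounds.

## Worked example

Simulate a lysozyme-like guanidine-HCl isotherm (K_D = 0.245 M⁻¹,
σ = 2×10⁻³, ν = 129, 25 °C, Gaussian noise sd 0.01) and fit it:

```r
library(coopunfold)

p   <- unfolding_params(K_D = 0.245, sigma = 2e-3, nu = 129,
                        temperature_K = 298.15)
iso <- simulate_isotherm(p, 1, 8, n_points = 25, noise_sd = 0.01,
                         seed = 42, method = "approx")
fit <- fit_cooperative(iso)
fit
#> Multistate cooperative fit
#>   c0 = 4.067 M, K_D = 1/c0 = 0.2459 M^-1
#>   sigma = 0.002127  (nu = 129, T = 298.15 K, approx isotherm)
#>   transition 2.59-4.92 M, dF = -13.33 kcal/mol
#>   SSE = 0.00358, R^2 = 0.99931 on 25 points
#>   LEM comparator: dG0 = 10.87 kcal/mol, m = 2.672 kcal L/mol^2
```

The fit pins K_D at the reciprocal of the interpolated midpoint
(recovering the generating 0.245 M⁻¹ to 0.4%) and finds the
cooperativity σ as the single free parameter (2.1×10⁻³ vs the
generating 2×10⁻³). `transition` is the 1–95% unfolding window, `dF`
the free-energy change of the cooperative unit across it, and the last
line the two-state LEM fitted to the same points for comparison.
`tidy()`, `glance()`, `augment()` and `autoplot()` give tabular and
graphical views.

Entropy and enthalpy from the bundled lysozyme temperature series:

```r
fit_thermal(lysozyme_thermal_series())
#> van't Hoff analysis of a dF(T) series
#>   n        = 4 temperatures
#>   dS       = 0.28 +/- 0.046 kcal/mol/K (R^2 = 0.948)
#>   mean dH  = 57.78 kcal/mol (sd 0.42)
```

and the diffusive free energy of the 25 °C guanidine-HCl transition
gradient:

```r
diffusive_free_energy(2.8, 5.8, 298.15)
#> [1] -0.4314703
```

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript inst/cli/coopunfold.R simulate --kd 0.25 --sigma 0.002 \
    --nu 129 --cmin 1 --cmax 7 --output iso.csv
Rscript inst/cli/coopunfold.R fit --input iso.csv --model both \
    --output results.csv
Rscript inst/cli/coopunfold.R thermo --input dF_series.csv --output th.csv
Rscript inst/cli/coopunfold.R fixtures --table survey --output survey.csv
```

Every flag can also live in a flat `key=value` config file
(`--config`); explicit flags override it.

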