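---
title: "Models and methods behind biodesulf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind biodesulf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodesulf)
```

`biodesulf` models the removal of inorganic (mostly pyritic) sulfur from
crushed coal by iron-oxidizing acidophiles. This vignette is the package's
account of the underlying science: the four models, their assumptions, the
parameters that matter, the numerical choices, and what the synthetic-data
round trips do and do not demonstrate.

## Orthogonal screening of process conditions

Four process factors — temperature (°C), coal particle size (mesh),
initial pH and bacterial liquid quantity (mL) — are screened at four
levels each in the balanced L16(4⁴) array, with the desulfurization rate
(per cent of inorganic sulfur removed) as response. The array is fixed
(`l16_design()`), every level of every factor appears exactly four times,
and every factor pair is orthogonal, so the additive decomposition of the
response is exact.

Range analysis sums the four responses observed at each level of each
factor (the K table), averages them, and ranks factors by the spread of
level means. The ANOVA uses the classical K-sum identity
`SS_j = sum_i K_ij^2 / 4 - T^2 / 16`; with four factors at 3 df each there
remain 3 error df out of 15, and F ratios are referred to F(3, 3).
Interactions are deliberately not modelled — the design cannot resolve
them — and no multiple-testing correction is applied, matching the
screening character of the experiment.

Two presentation conventions coexist in typeset screening tables: ranges
formed from full-precision level means, and ranges formed after the means
were rounded to two decimals. Both are reported (`R` and
`R_rounded_means`); the full-precision value is canonical. All internal
computation is double precision; only display applies half-up rounding.

The shipped dataset's typeset summary rows contain two internal
inconsistencies: the level-4 K sum of factor D (223.82 as typeset, 226.82
from the run data — the typeset *mean* 56.71 matches the recomputed sum),
and factor C's sum of squares (365.97 as typeset, 270.95 from the K sums,
which also shifts the total from 1348.96 to 1253.93 and F_C from 9.90 to
7.33). `check_reported()` recomputes everything from run-level data and
flags these conflicts; derived statistics are never copied from the
summary rows. The significance order A > C > D > B is unchanged by the
correction.

```{r audit}
subset(check_reported(), !agrees)
```

A note on power: with only 3 error df, F(3, 3) is a weak test. At the
effect scale of the shipped data (F_A ≈ 14) the probability of a factor-A
p-value below 0.05 under resampled Gaussian noise is only about 0.8, while
the probability that factor A carries the *largest* F is ≈ 0.999. The test
suite therefore asserts the detection property (largest F), not a
significance frequency that the design cannot deliver.

## Monod growth on ferrous iron

The bacterium gains energy by oxidizing Fe²⁺ to Fe³⁺, so the Fe²⁺
concentration `p` (g/L) is the limiting substrate and its conversion
`eta = 100 (p0 - p)/p0` proxies growth activity. Growth follows Monod
kinetics with maximum specific rate `u_m` and half-saturation `K`, and a
constant yield `Y` ties biomass to substrate consumed:
`C_l = C_l0 + Y (p0 - p)`. Eliminating biomass gives a single autonomous
ODE,

$$\frac{dp}{dt} = -\,\frac{\mu_m\,p\,[C_l^0 + Y(p_0 - p)]}{Y\,(K + p)},$$

whose dynamics depend only on `(u_m, K, C_l0/Y, p0)`. Absolute biomass and
`Y` are not identifiable from substrate data, so the package fits the
ratio `C_l0/Y` — the same quantity a substrate-only experiment can report.
The closed-form inverse `t(p)` exists but is numerically delicate to
transcribe; the package instead defines it by adaptive quadrature of the
separated ODE and treats mutual consistency of the quadrature and the
integrated trajectory (to 1e-6 relative) as the correctness criterion —
both derive from the same unambiguous differential equation.

Defaults: `p0 = fe2_from_heptahydrate(44.2)` = 8.88 g/L, the Fe²⁺ content
of standard 9 K medium (44.2 g/L FeSO₄·7H₂O; molar masses fixed at 55.845
and 278.01 g/mol). The time unit is whatever the input series uses; `u_m`
is per that unit. Reference parameter values used throughout the tests are
`u_m = 0.0497`, `K = 0.328` g/L, `C_l0/Y = 1.0838` g/L.

Estimation is Levenberg–Marquardt (`minpack.lm`) on the simulated
trajectory (lsoda, relative tolerance 1e-9 inside the fit, 1e-10 for
forward simulation), bounded below at zero, with a coarse multi-start grid
as fallback when the supplied start stalls or explains less than 90% of
the depletion signal. Observations at exactly zero (exhausted substrate)
are legitimate inputs; a completely flat series returns `u_m = 0` flagged
degenerate rather than an error.

Identifiability caveat: `K` only shapes the trajectory in the short window
where `p` is comparable to `K` (≈ 0.3 g/L against `p0` ≈ 8.9 g/L). On a
20-point grid over 100 time units with Gaussian noise of sd 0.05 g/L, `u_m`
and `C_l0/Y` are recovered to within ~10% but `K`'s relative error ranges
from a few per cent to ~50% across noise realizations. Noiseless data
recover all three parameters to better than 0.1%; noisy-data checks in the
test suite therefore target `u_m` and `C_l0/Y`.

## Three-resistance shrinking-core model

Coal particles are treated as spheres of radius `r_s` whose unreacted core
(radius `r_c = r_s (1 - x)^{1/3}`) shrinks as sulfur is oxidized, while a
porous product layer (jarosite and related precipitates) grows around it.
At steady state the external (liquid-film) diffusion, product-layer
diffusion and interfacial reaction rates are equal, and integrating the
combined law gives

$$t = A_1 x + A_2\left[1 - \tfrac{2}{3}x - (1-x)^{2/3}\right]
        + A_3\left[1 - (1-x)^{1/3}\right],$$

one lumped coefficient (in time units) per resistance. The physical
mapping is `A1 = γδρ r_s/(3 M C_l D_1)`, `A2 = γρ r_s²/(2 M C_l D_2)`,
`A3 = ρ r_s/(M C_l k)`; the package uses the initial radius `r_s` in `A2`
(the coefficient is a constant of the integrated law while the core radius
varies), the standard shrinking-core convention. All three coefficients
scale as `1/C_l`, which is what makes the coupling to growth below a pure
rescaling.

The conversion rate is defined as the reciprocal of `dt/dx` of the
integrated law — algebraically equivalent to the differential form but
immune to transcription ambiguity. Wherever `(1-x)^{-1/3}` or
`(1-x)^{-2/3}` is evaluated, `x` is clipped to `1 - 1e-9`; inversion of
`t(x)` is by bisection on `[0, 1 - 1e-9]` to absolute tolerance 1e-10,
after a 129-point monotonicity scan that reports the offending interval if
`t(x)` decreases anywhere.

Coefficients are estimated by ordinary least squares of observed `t` on
the three basis functions without intercept (`t(0) = 0` by construction).
The regression is deliberately unconstrained — empirical fits of this form
can return negative coefficients, which signal model misfit rather than
negative resistances, and hiding them would mask that diagnostic; a
non-negative mode (`nonneg = TRUE`, via `pracma::lsqnonneg`) is available
for strictly physical fits. Each term's Pearson correlation with observed
`t` is reported as `r(A_i)`, the overall `R` is the correlation between
fitted and observed times (with `R²` alongside, since usage varies), and
the controlling step is ranked by descending `|r(A_i)|`. On
internal-diffusion-dominated data this reproduces the characteristic
ordering `r(A2) > r(A3) > r(A1)`.

`simulate_coupled()` joins the two models: since all coefficients scale as
`1/C_l`, the conversion rate at time `t` is the fixed-coefficient rate
multiplied by `C_l(t)/C_l(0) = 1 + (p0 - p(t))/(C_l0/Y)`, with `p(t)` from
the growth ODE; both states are integrated jointly and `x` is capped below
1.

## Activation energy from thermogravimetry

Non-isothermal first-order decomposition at constant heating rate `alpha`
(K per time; default 10) gives `dx/dT = (A/alpha) e^{-E/(RT)} (1 - x)`.
The default linearization used by the package is the decimal-constant
form

$$\ln[-\ln(1-x)] = \ln\!\left(\frac{AE}{\alpha R}\right) - 5.314
                    - 0.1278\,\frac{E}{T},$$

so `E = -slope/0.1278` from the regression of `ln[-ln(1-x)]` on `1/T`.
These constants do not equal the exact SI integration factors (1/R =
0.1203 mol·K/J), so the textbook Coats–Redfern form
`ln[-ln(1-x)/T²] = ln(AR/(αE)) - E/(RT)` is provided as an alternative
convention; the two give different `E` from the same data, and both are
implemented exactly so results under either convention are reproducible.
Conversion is defined from the thermogram as fractional mass loss between
user-supplied (or segment-extremal) initial and final masses. Points with
`x ≤ 0.01` or `x ≥ 0.99` are excluded from the fit by default (the
transform diverges at the endpoints), the fit window in K is
user-restrictable, and fewer than three usable points is an error.

## Synthetic data and what the tests show

The generators emulate: Fe²⁺ depletion curves (ODE trajectory plus
Gaussian concentration noise, clipped to `[0, p0]`), shrinking-core
conversion series (Gaussian time noise, redrawn up to 100 times to keep
`t` strictly monotone), thermogravimetric conversion curves (exact
solutions of the linearized law with Gaussian ordinate noise), and L16
response tables (additive factor effects plus Gaussian noise, balance
preserved by construction). Gaussian noise is the least-assumption
default; none of the generators emulate lag phases, jarosite-induced drift
of the diffusion coefficients, temperature or pH dependence of `u_m`,
particle-size distributions, or heteroscedastic measurement error.
Passing round-trip tests therefore demonstrates estimator correctness —
that each fit recovers the parameters of data generated by its own model —
not that real desulfurization data satisfy these models. Every generator
takes a seed, restores the caller's RNG state, and is byte-identical per
seed.

Problem sizes used throughout the tests and the replication report: the
16-run design, 20-point growth series over 100 time units, 19-point
conversion grids (x = 0.05…0.95), 51-point temperature grids (400–900 K),
200 replicates for the stochastic-bias property and 100 for the
detection property — sizes a desk replication of this kind of study would
use, and small enough that the full suite runs in seconds.

## Known limitations

* Only the lumped coefficients `A_i` are fitted; physical parameters
  (`D_1`, `D_2`, `k`, `δ`) enter forward-only, and no film-transfer
  correlation for `δ` is provided.
* Absolute biomass is reported only when the user supplies `Y`; substrate
  data alone fix `C_l0/Y`.
* The screening module is specific to L16(4⁴); it does not generate other
  fractional-factorial designs and cannot estimate interactions.
* Activation energies under the two linearization conventions differ by
  construction; comparisons across studies must fix the convention first.
* Characteristic thermogram temperatures (ignition point, heat-flow
  extrema) have no computable definition here and are out of scope.
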