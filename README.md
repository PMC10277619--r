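# biodesulf

Kinetic modelling of microbial coal desulfurization in R.

High-sulfur coal self-ignites readily because pyrite (FeS₂) oxidizes fast
and exothermically. Iron-oxidizing acidophiles such as *Acidithiobacillus
ferrooxidans* remove most of the inorganic sulfur from crushed coal in
stirred culture, which raises the coal's ignition point and activation
energy and so lowers its spontaneous-combustion risk. `biodesulf` implements
the quantitative analysis chain of such a study for process engineers and
bioleaching researchers:

1. **Orthogonal screening** — range analysis and ANOVA of an L16(4⁴)
   Taguchi-style design in temperature, particle size, initial pH and
   inoculum volume, with the desulfurization rate *w* = 100·(S_B − S_A)/S_B
   as response. For factor *j*, level sums K_ij, level means K̄_ij, ranges
   R_j = max K̄_ij − min K̄_ij, and sums of squares
   SS_j = Σᵢ K²_ij/4 − T²/16 with F_j = MS_j/MS_error on (3, 3) df.
2. **Monod growth kinetics on Fe²⁺** — the substrate ODE
   dp/dt = −μ_m p [C_l⁰ + Y(p₀ − p)] / [Y(K + p)], its quadrature inverse
   t(p), and Levenberg–Marquardt estimation of (μ_m, K, C_l⁰/Y) from
   Fe²⁺-depletion series (only the ratio C_l⁰/Y is identifiable from
   substrate data).
3. **Three-resistance shrinking-core model** — the integrated law
   t = A₁x + A₂[1 − ⅔x − (1−x)^⅔] + A₃[1 − (1−x)^⅓], linear regression of
   observed time on the three basis functions, per-term correlations r(Aᵢ)
   that rank external diffusion, internal (product-layer) diffusion and
   chemical reaction as the controlling step, and coupling of the
   conversion rate to a growing microbial population C_l(t).
4. **Activation energy from thermogravimetry** — ordinary least squares of
   ln[−ln(1−x)] on 1/T, with E from the slope, in the dataset's own
   decimal-constant convention and the textbook Coats–Redfern form.

Seeded synthetic-data generators produce every input the fits consume, so
each estimator is validated by parameter recovery.

## Worked example

```r
library(biodesulf)

d <- desulf_l16()          # shipped 16-run screening dataset
range_analysis(d)
#> Range analysis of L16(4^4) design
#>            A      B      C      D
#> K1    205.13 207.97 209.16 211.78
#> K2    230.86 233.65 255.23 233.98
#> K3    267.62 235.30 233.15 252.06
#> K4    221.03 247.72 227.10 226.82
#> ...
#> R (full precision): A=15.62  B=9.94  C=11.52  D=10.07
#> Superior levels: A3 B4 C2 D3 (maximizing)

ortho_anova(d)
#> ANOVA of L16(4^4) design (F on 3 and 3 df)
#>  source df      SS     MS     F      p signif
#>       A  3  527.40 175.80 14.28 0.0279      *
#>       B  3  208.84  69.61  5.65 0.0943
#>       C  3  270.95  90.32  7.33 0.0680
#>       D  3  209.80  69.93  5.68 0.0938
#>   Error  3   36.95  12.32    NA     NA
#>   Total 15 1253.93     NA    NA     NA
```

The best operating point is A3 B4 C2 D3 — 30 °C, 120-mesh coal, initial pH
2.0, 15 mL inoculum — and temperature is the most influential factor
(significance order A > C > D > B). The dataset's typeset summary rows
carry two internal inconsistencies, which the audit surfaces instead of
propagating:

```r
check_reported(d)
#> Audit of reported summary values: 26 of 30 entries agree
#> Discrepant entries (recomputed values are canonical):
#>  quantity reported recomputed agrees
#>      K_4D   223.82     226.82  FALSE
#>      SS_C   365.97     270.95  FALSE
#>  SS_Total  1348.96    1253.93  FALSE
#>       F_C     9.90       7.33  FALSE
```

Growth-parameter recovery from a noisy synthetic Fe²⁺ series:

```r
gp  <- growth_params(u_m = 0.0497, K = 0.328, cl0_over_y = 1.0838)
obs <- gen_growth_series(gp, seq(0, 60, by = 5), sd = 0.05, seed = 1)
fit_growth(obs$time, obs$p)
#> Monod growth fit (Levenberg-Marquardt on the ODE trajectory)
#> Monod growth parameters: u_m = 0.051851 /time, K = 0.437456 g/L,
#>   C_l0/Y = 1.02228 g/L, p0 = 8.87863 g/L
#>   RSS = 0.01746; converged: TRUE
```

Shrinking-core regression recovers generating coefficients exactly on
noiseless data and reports the controlling-step ranking:

```r
xs <- seq(0.05, 0.95, 0.05)
fit_sc(sc_time(sc_coefficients(10, 40, 5), xs), xs)
#> Shrinking-core coefficient regression (unconstrained)
#>   A1 = 10, A2 = 40, A3 = 5
#>   r(A1) = 0.9791, r(A2) = 0.9794, r(A3) = 0.9995;  R = 1.0000 (R^2 = 1.0000)
#>   controlling step ranking: chemical > internal > external
```

`run_replication(seed = 1, out_dir = "report")` runs the whole chain —
screening statistics, audit, and parameter-recovery demonstrations for all
three kinetic fits — and writes `report.json` / `report.txt`.

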