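# tabletrom

Reduced-order models (ROMs) of pharmaceutical tablet compaction whose
parameters respond to upstream lubricant and glidant mixing.

Lubricants (magnesium stearate, MgSt) and glidants (colloidal silica, CS)
are added to direct-compression blends in fractions of a percent to improve
friction and flow, but they also change bulk density, compaction force and
— most critically — tablet tensile strength, in ways that depend jointly on
the excipient concentration *c* and the blending time *t<sub>mix</sub>*.
`tabletrom` quantifies these effects end to end:

* **Four-stage tableting ROMs** — die-filling efficacy
  η = W/(ρ<sub>b</sub>V<sub>fill</sub>), a density-based Kawakita
  compaction force
  F = πD²(ρ − ρ<sub>c</sub>) / [4b(ρ(a−1) + ρ<sub>c</sub>)],
  elastic recovery ε<sub>ρ</sub> = ε₀[(ρ − ρ<sub>c,ε</sub>)/(1 −
  ρ<sub>c,ε</sub>)]ⁿ, and a Leuenberger-type tensile strength
  σ<sub>t</sub> = σ₀[1 − (1−ρ)/(1−ρ<sub>c,σ</sub>) e^(ρ−ρ<sub>c,σ</sub>)],
  with Pitt's convex-tablet relation converting measured hardness to
  strength.
* **Rational-function coupling** — each ROM parameter ξ is a constrained
  bivariate rational function of the normalized mixing conditions
  X = [c/(c<sub>max</sub> − c)]^r<sub>X</sub>,
  Y = [t/(t<sub>max</sub> − t)]^r<sub>Y</sub>, built so that
  f(0,0) = f(0,∞) = f(∞,0) = p₄ (no excipient, or no mixing, behaves like
  the plain formulation). A 15-variant library, a 43-member pair library
  and a 41-member compaction triple library bound the search space.
* **Model selection** — seeded multi-start constrained least squares
  (Levenberg–Marquardt core), AIC ranking with the small-sample
  correction for n < 30, a post hoc overfit flag, case-resampling
  bootstrap intervals, and a sequential campaign fit that threads the
  onset-density ordering ρ<sub>c</sub> < ρ<sub>c,ε</sub> < ρ<sub>c,σ</sub>
  through the stages.
* **Global sensitivity** — first-order Sobol indices of the integrated
  stage models (Saltelli-type plan with Latin-hypercube bases).
* **Synthetic campaigns** — Latin-hypercube designs and a forward
  simulator that reproduces the two published campaigns (20 MgSt runs,
  30 CS runs) from the published fitted parameter sets, with configurable
  measurement noise; no experimental run tables are publicly deposited, so
  this generator is the package's data source for testing and studies.

## Worked example

Simulate a noisy lubricant campaign from the published models, rank the
bulk-density library by AIC, and inspect the winner:

```r
library(tabletrom)
spec <- campaign_spec("mgst")            # 20 runs, published input ranges
runs <- simulate_campaign(spec, seed = 42)
ds   <- stage_data(runs, "bulk_density", campaign_norm("mgst"))
sel  <- select_model(ds, seed = 1, n_starts = 12)
print(sel)
#> Model selection for stage `bulk_density` (top 5 of 15):
#>               model Np    SSE    R2    AIC overfit feasible
#>  bulk_density: (11)  5  236.4 0.989  63.68   FALSE     TRUE
#>  bulk_density: (13)  4  305.7 0.985  65.20   FALSE     TRUE
#>  bulk_density: (12)  6  253.4 0.988  69.25   FALSE     TRUE
#>  bulk_density: (10)  7  206.6 0.990  70.04   FALSE     TRUE
#>   bulk_density: (8)  3 4304.0 0.794 114.93   FALSE     TRUE
```

SSE is in (kg/m³)² because bulk density is fit in kg/m³. The second-degree
variants (10–13) dominate the first-degree ones (bottom row): lubricated
bulk density is non-monotone in concentration, which only the second-degree
family can express. The generating model of this campaign is variant 13;
with one 1%-CV noise realization on 20 runs, its 5-parameter superset
(variant 11) edges it out while recovering essentially the same surface:

```r
print(best_model(sel))
#> bulk_density: (11)
#>   Np = 5, SSE = 236.4, R2 = 0.9887, AIC = 63.68
#>  phi.p1  phi.p4  phi.q1  phi.q5  phi.q6
#> 15.2100  0.1735 55.1900  0.2021  0.5460
```

`phi.p4 = 0.174` is the fitted packing fraction of the unlubricated blend
(generating value 0.17) and `phi.p1/phi.q1 = 0.276` its high-lubrication
plateau (generating 0.275).

Sensitivity of the glidant compaction-force model, whose parameters are
constants — all variance must come from the in-die density:

```r
tr <- ground_truth("cs")
b  <- data.frame(input = c("conc", "tmix", "rho_in_die"),
                 lower = c(0, 10, 0.5), upper = c(0.2, 30, 0.95))
round(sobol_stage(tr$compaction, b, campaign_norm("cs"), N = 2^14, seed = 1)[1:3], 4)
#>       conc       tmix rho_in_die
#>     0.0000     0.0000     0.9946
```

A thin command-line interface wraps the same pipeline
(`inst/cli/tabletrom.R`; subcommands `design`, `simulate`, `fit`, `sobol`,
`report`, each taking `--seed` and `--out`).

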