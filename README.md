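# otocarb

Field-metabolic proxies for wild fish from the carbon isotopic composition
of otolith annual increments.

## What it does

Otolith aragonite draws its carbon from two isotopically distinct pools:
seawater dissolved inorganic carbon (DIC, δ¹³C ≈ 0 to +2 ‰ VPDB) and
respired metabolic carbon (δ¹³C ≈ −20 to −17 ‰).  The respired fraction

&nbsp;&nbsp;&nbsp;&nbsp;δ¹³C_oto = C_resp·δ¹³C_diet + (1 − C_resp)·δ¹³C_DIC + ε,&nbsp;&nbsp;ε = 2.7 ‰,

is a proxy for field metabolic rate that can be read from archived
otoliths across a century.  `otocarb` implements the full inference chain
for a two-stock comparison (Icelandic-type `ICE` vs Northeast-Arctic-type
`NEA` cod design):

* **`synthetic_cohort`** — seeded generator of otolith panels (fish ×
  annual increments), temperature series and isotope sources with the
  exact repeated-measures structure the models assume (436 fish, δ¹³C
  milled at ages 3 and 8, first/last increments excluded, century-scale
  Suess trend).
* **`growth_isotope_lmm`** — crossed random-intercept mixed models for
  δ¹³C and log increment width (`fit_lmm`), two-phase AICc selection
  (`select_structure`), `icc`, `r2_nakagawa`, Satterthwaite
  `fixed_effect_tests`, `year_trend`.
* **`trait_covariance_mcmc`** — native Gibbs sampler (`fit_bivariate`)
  decomposing the δ¹³C–growth correlation into within-individual,
  between-individual and between-year components, with parameter-expanded
  covariance priors and missing-response augmentation
  (`level_correlations`, `attribution_table`, `mcmc_diagnostics`).
* **`cresp_mixing`** — Suess correction (`suess_correct`), algebraic
  inversion (`cresp_invert`), hierarchical Bayesian mixing model
  (`fit_mixing`) with fish/year random effects on the logit scale,
  `stock_difference`, `annual_synchrony`.
* **`pipeline_cli`** — `run_pipeline()` and the `inst/cli/otocarb`
  command-line entry point (`synth|fit|covar|cresp|run`).

## Worked example

```r
library(otocarb)

params <- cohort_params(seed = 1)          # full study design, 436 fish
panel  <- generate_cohort(params)
env    <- simulate_temperature(seq(min(panel$year) - 1, max(panel$year)), seed = 1)
panel  <- simulate_widths(panel, params, env)
panel  <- simulate_d13c_lmm(panel, params)

fit <- fit_lmm(lmm_spec("d13c",
                        c("Stock", "Age", "Age:Stock", "TL", "Year", "Year:Stock"),
                        c("fish", "stock_year")), panel)
fit
#> Otolith trait mixed model (d13c, REML)
#>   n = 836 ; groups: fish 436, stock_year 179
#>   variance components:
#>     sigma2       fish stock_year
#>     0.1385     0.1548     0.0369
#>   fixed effects:
#>     (Intercept)        stockNEA           age88            tl_c          year_c
#>         -1.5756         -0.4118          0.0620         -0.4467         -0.0071
#>  stockNEA:age88 stockNEA:year_c
#>          0.0606          0.0037
round(c(icc(fit, "fish"), icc(fit, "stock_year")), 3)
#> [1] 0.469 0.112
year_trend(fit, "ICE")["per_century"]   # simulated Suess decline, ICE
#> per_century
#>  -0.7102711
```

The recovered variance components and the −0.71 ‰/century decline are the
generative values (σ² = 0.144, τ_fish = 0.128, τ_stockyear = 0.034, year
slope −0.007) up to sampling noise at 436 fish.  Continuing to C_resp:

```r
slopes <- c(ICE = unname(year_trend(fit, "ICE")["slope"]),
            NEA = unname(year_trend(fit, "NEA")["slope"]))
posts <- fit_mixing(suess_correct(panel, slopes), source_config(), seed = 1)
posts$ICE
#> C_resp mixing posterior, stock ICE: 2000 draws (2 chains)
#>   global C_resp: 0.287 (posterior SD 0.002)
#>   converged: TRUE | max R-hat: 1.02
stock_difference(posts$ICE, posts$NEA)[c("mean", "lo", "hi", "significant")]
#> $mean [1] 0.010   $lo [1] 0.004   $hi [1] 0.016   $significant [1] TRUE
```

About 29 % of the otolith carbon in this simulated world is respired
carbon, with a small but credibly non-zero stock difference — the
quantities the chain is built to estimate.

Command line:

```sh
Rscript inst/cli/otocarb run --out runs/demo --seed 1 --scale demo
```

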