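# btbiodyn

A biodynamic model of *Bacillus thuringiensis* batch fermentation: four
coupled Gompertz-based equations for the culture's key compounds — biomass,
poly-β-hydroxybutyrate (PHB), dipicolinic acid (DPA, the endospore proxy)
and the insecticidal Cry protein — with simulation, nonlinear least-squares
parameter estimation, a synthetic-kinetics generator and the downstream
bioprocess analyses (phase timing, dry-weight contents, unit conversions,
stoichiometric yield bounds, parameter-vs-substrate regressions).

It is written for bioprocess and fermentation researchers who want to fit
sigmoidal multi-compound kinetics where the phases are *coupled*: endospore
formation consumes vegetative biomass, and DPA and Cry production both
consume PHB.

## The model

Each compound follows a Gompertz sigmoid
`g(t; A, μ, t_c) = A·exp(−exp(−μ(t − t_c)))`. DPA and Cry are free
sigmoids; biomass and PHB are production-minus-consumption balances coupled
by yield coefficients:

    X(t)   = g(t; X_max,   μ_max,  t_c)  − DPA(t)/Y_DPA/X
    PHB(t) = g(t; PHB_max, μ_maxp, t_cp) − DPA(t)/Y_DPA/PHB − Cry(t)/Y_Cry/PHB
    DPA(t) = g(t; DPA_max, μ_maxd, t_cd)
    Cry(t) = g(t; Cry_max, μ_maxc, t_cc)

The 15 parameters of four reference batch fermentations (F1–F4, increasing
glucose–soybean meal at fixed C:N = 7:1) ship with the package
(`bt_param_sets()` and `inst/extdata/F*.cfg`). See the methods vignette
(`vignettes/biodynamic-model.Rmd`) for the model's assumptions, the
estimation strategy and its identifiability limits.

## Worked example

Generate a noisy synthetic fermentation from the F1 reference set (2-h
sampling, 5% multiplicative noise, replicate averaging, detection-limit
censoring), fit the model, and read off the culture phases:

```r
library(btbiodyn)
f1  <- bt_param_sets()$F1
kin <- generate_kinetics(f1, study_design(seed = 42))
fit <- fit_biodynamic(kin)
fit
#> Biodynamic model fit (staged strategy, censored points included)
#>   biomass  SSE = 0.1214     R2 = 0.9980
#>   phb      SSE = 0.0006683  R2 = 0.9977
#>   dpa      SSE = 7.547e-05  R2 = 0.9985
#>   cry      SSE = 0.0001264  R2 = 0.9949
#>   total SSE = 0.1223
#> Biodynamic parameter set 'F1'
#>   biomass  A = 5.74    mu = 0.7697  t_c = 4.546
#>   phb      A = 0.4471  mu = 9.421   t_c = 8.044
#>   dpa      A = 0.1715  mu = 0.6491  t_c = 14.15
#>   cry      A = 0.1615  mu = 0.2607  t_c = 14.22
#>   yields   Y_DPA/X = 0.02414, Y_DPA/PHB = 0.3706, Y_Cry/PHB = 0.8934

phase_boundaries(fit$params)
#> Culture phases (onset = 0.05 of asymptote):
#>   lag until 3.12 h; vegetative growth until 7.93 h;
#>   transition until 12.46 h; sporulation thereafter
```

Every compound is fitted with R² above 0.99 and the recovered biomass and
DPA parameters sit within a few percent of the generating truth (X_max
5.74 vs 5.58; t_c 4.55 vs 4.54). The PHB-equation parameters are only
weakly identified from a single censored series — the vignette explains
why — while the phase boundaries (lag ends ≈ 3.1 h, transition starts
≈ 7.9 h, sporulation ≈ 12.5 h) land in the windows reported for these
cultures.

## The analysis workflow

The numbered scripts under `analysis/` reproduce the full study and write
their tables under `results/`:

1. `01_simulate.R` — reference trajectories (clamped and raw equations)
2. `02_generate_synthetic.R` — the synthetic four-fermentation study
3. `03_fit_recovery.R` — model fits, diagnostics, 20-seed recovery medians
4. `04_phase_yield_analysis.R` — phase boundaries, dry-weight contents,
   CFU conversions, stoichiometric yield-bound checks
5. `05_substrate_meta.R` — parameter-vs-glucose regressions, yield trends

Run each with `Rscript analysis/<script>` from the repository root.

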