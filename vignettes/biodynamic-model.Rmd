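---
title: "A coupled Gompertz model of B. thuringiensis batch fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled Gompertz model of B. thuringiensis batch fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btbiodyn)
```

## The model

A batch culture of *Bacillus thuringiensis* passes through lag, vegetative
growth, transition and sporulation, each phase dominated by one metabolic
route and each route tracked by a measurable key compound: cells (biomass)
for glycolytic growth, poly-β-hydroxybutyrate (PHB) for the transition
phase, and dipicolinic acid (DPA, the endospore constituent) together with
the insecticidal Cry protein for sporulation. The package implements a
biodynamic model that links the phases through four coupled equations built
from the Gompertz sigmoid

$$ g(t; A, \mu, t_c) = A\, e^{-e^{-\mu (t - t_c)}}, $$

with asymptote $A$ (g/L), maximum specific rate $\mu$ (1/h) and critical
(inflection) time $t_c$ (h). The curve equals $A/e$ at $t_c$, where its
slope attains the maximum $\mu A / e$ — two identities the test suite
checks to machine precision.

DPA and Cry are simultaneous, parallel Gompertz processes:

$$ DPA(t) = g(t; DPA_{max}, \mu_{maxd}, t_{cd}), \qquad
   Cry(t) = g(t; Cry_{max}, \mu_{maxc}, t_{cc}). $$

Biomass and PHB are two-term balances. Endospores form from vegetative
cells, so biomass is Gompertz growth minus the biomass consumed by DPA
formation; PHB is the carbon and energy source for both sporulation
products, so its equation subtracts both consumption routes:

$$ X(t) = g(t; X_{max}, \mu_{max}, t_c) - \frac{DPA(t)}{Y_{DPA/X}}, \qquad
   PHB(t) = g(t; PHB_{max}, \mu_{maxp}, t_{cp})
          - \frac{DPA(t)}{Y_{DPA/PHB}} - \frac{Cry(t)}{Y_{Cry/PHB}}. $$

The three yield coefficients (g product per g precursor consumed) are what
couple the phases. Two exact conservation identities follow — adding the
consumption terms back to $X$ or $PHB$ recovers the corresponding
production sigmoid — and the suite verifies them to $10^{-12}$ relative
error on all bundled parameter sets.

### Negativity and clamping

With realistic parameter sets the consumption terms eventually exceed the
production asymptote, so the raw $X$ and $PHB$ equations go negative late
in culture (F1 biomass reaches −1.08 g/L at 20 h). The equations are
reported faithfully by default; `clamp = TRUE` reports negative values as
0 and flags them, which is what an assay observes. The same choice
reappears in fitting (below).

### Reference parameter sets

`bt_param_sets()` bundles the parameter sets of four batch fermentations
(F1–F4) of *B. thuringiensis* var. *kurstaki* HD-73 run at increasing
glucose–soybean meal concentrations (25.1/4.4 to 54.1/35.37 g/L, C:N fixed
at 7:1). They serve as generating truths for the synthetic study and as
inputs to the cross-fermentation analyses. The same sets ship as flat
`key = value` configs under `inst/extdata/`.

## The synthetic-data generator

`generate_kinetics()` emulates the measurement process of those
fermentations on top of the clamped model trajectory:

* **sampling** every 2 h over 0–20 h (11 points), the default
  `study_design()`;
* **noise**: each technical replicate is $v(1+\varepsilon)$,
  $\varepsilon \sim N(0, 0.05)$. The noise is multiplicative because the
  compounds span two orders of magnitude (biomass ~13 g/L, DPA ~0.17 g/L);
  an additive model at biomass scale would drown the minor compounds. The
  assays' true error magnitudes are not reported anywhere, so 5% is a
  declared assumption, chosen once;
* **replicates** averaged before censoring: quadruplicate PHB and Cry
  assays, duplicate DPA photoluminescence, a single biomass count;
* **detection limits** (biomass 0.01, PHB 0.05, DPA 0.01, Cry 0.02 g/L):
  averages below the limit are recorded as exactly 0 and flagged censored.
  These defaults reproduce the reported non-detect windows — no PHB in the
  first ~6 h, no DPA or Cry in the first ~10–14 h — for all four sets.

What the generator does **not** emulate: substrate depletion, pH/DO
dynamics, autocorrelated assay drift, sample-volume effects, or any direct
endospore count (DPA is the endospore proxy throughout). Passing recovery
tests therefore show that the estimator inverts the model under its own
noise assumptions, not that the model is correct for any particular real
culture.

## Estimation

`fit_biodynamic()` estimates the 15 parameters by nonlinear minimum sum of
squares with a Levenberg–Marquardt (damped least-squares) minimizer
(`minpack.lm::nls.lm`; tolerances $10^{-8}$ on step and residual, at most
1000 iterations; all parameters bounded below by 0 except the critical
times, which are free).

The **staged** strategy follows the model's one-way coupling: (1) DPA and
Cry are fitted as free sigmoids; (2) the biomass triple plus $Y_{DPA/X}$
are fitted with the fitted DPA curve inserted; (3) the PHB triple plus
$Y_{DPA/PHB}$ and $Y_{Cry/PHB}$ are fitted with both fitted curves
inserted. The **joint** strategy pools the residuals of all four compounds
into one 15-parameter problem initialized at the staged solution, so its
total SSE never exceeds the staged one (a tested invariant). Because the
pooled objective is unweighted, the joint refinement can trade a little
DPA/Cry fit (0.1–0.2 g/L scale) for biomass fit (10 g/L scale); when
per-compound diagnostics matter, the staged fit is the more even-handed
choice and is the default.

Initial values: asymptote ← max observation; $t_c$ ← midpoint of the
steepest finite-difference rise; $\mu$ ← $e \cdot$ max slope / asymptote
(from the max-slope identity); yields ← ratios of terminal consumed
amounts. Censored points enter as zeros by default (`censoring_policy =
"include"`), matching how non-detects appear in observed kinetics; an
`"exclude"` option drops them.

**Clamped predictions.** Observed concentrations are non-negative while
the raw equations go negative, so by default predictions are clamped at 0
during fitting (`clamp_predictions = TRUE`). Without this, the late-culture
zeros pull $Y_{DPA/X}$ upward to shrink a death term the data never
actually measured below zero. When fitting *unclamped* model output (e.g.
the noiseless self-consistency checks), set `clamp_predictions = FALSE`;
the suite verifies that such fits recover the generating parameters to
machine-level SSE.

### What the design can and cannot identify

The recovery study (`analysis/03_fit_recovery.R`; also run by the test
suite) generates 20 noise realizations per reference set and takes the
median recovered value of each parameter. The biomass and DPA triples,
all four critical times, $X_{max}$ and $DPA_{max}$ (within 5%) and
$Y_{DPA/X}$ recover well for every set, as do $PHB_{max}$ and $Cry_{max}$
for the three higher-substrate sets.

The **PHB-consumption split is not statistically identifiable** under this
design: detection-limit censoring leaves only ~4 informative PHB points
for the 5 parameters of the PHB equation, and for the low-substrate F1 the
least-squares optimum interpolates the data with SSE far *below* the SSE
at the generating truth — so no optimizer, however good, can recover
$Y_{DPA/PHB}$ and $Y_{Cry/PHB}$ from a single 11-point series. F1's slow
Cry sigmoid ($\mu_{maxc} = 0.20$/h, $t_{cc} = 14.9$ h) reaches only ~70%
of its asymptote by 20 h, which likewise limits its asymptote/rate
recovery. Estimating the PHB partition reliably would need either denser
late-culture sampling or replicated fermentations; the package reports
these parameters but the recovery tests cover only the identifiable
subset.

## Derived analyses

* **Phase boundaries** (`phase_boundaries()`): a Gompertz term reaches the
  fraction $f$ of its asymptote at $t = t_c - \ln(-\ln f)/\mu$, in closed
  form. With the default onset fraction $f = 0.05$ the biomass onset marks
  the end of lag (F1: 3.13 h, inside the reported 3 ± 1 h window), the PHB
  onset the start of transition (F1: 7.43 h, inside 7 ± 1 h) and the DPA
  onset the start of sporulation. The 5% fraction is a reproducible
  criterion calibrated so the four reference sets land in the reported
  windows; onsets increase strictly with $f$ (tested).
* **Unit conversions** (`cfu_to_biomass()`): direct counts are expressed
  as dry biomass with a 2.3 pg single-cell weight; the two worked
  literature conversions (1.65×10⁹ CFU/cm³ → 3.79 g/L, 3.8×10⁸ → 0.87 g/L)
  are reproduced to their printed precision. The first product is exactly
  3.795, a 2-decimal rounding boundary, so the tests assert agreement to
  half a printed unit rather than a specific rounding rule.
* **Dry-weight contents** (`percent_dry_weight()`): maximum compound over
  maximum biomass concentration; Cry is ~6% of dry cell weight in the
  highest-substrate run, against literature extremes up to 98%.
* **Stoichiometric ceiling** (`max_anaerobic_yield()`): with the standard
  biomass composition CH₁.₈O₀.₅N₀.₂, glucose as CH₂O, IUPAC 2021 atomic
  masses (declared once, rounded to 3 decimals) and no CO₂ formation, the
  carbon balance gives 24.626/30.026 = 0.820 g biomass/g glucose. Ceilings
  near 0.86 g/g quoted in the bioprocess literature presuppose different
  mass conventions; this package reports the explicit carbon-balance
  value. Any observed $Y_{X/S}$ above the ceiling (`check_yield_bound()`)
  implies glucose is not the limiting substrate.
* **Cross-fermentation regressions**
  (`parameter_substrate_regression()`, `yield_trend()`): ordinary least
  squares of a named parameter on initial glucose with Pearson $r$ and its
  two-sided t-test; with only four fermentations every result carries a
  `small_n` caveat and no multiple-testing correction is applied (three
  pre-named responses). $X_{max}$, $PHB_{max}$ and $Cry_{max}$ scale
  linearly with glucose ($r \ge 0.97$) while $DPA_{max}$ shows no
  relationship ($p = 0.33$). Spearman rank correlations of the
  PHB-partition yields with glucose are exactly +1 ($Y_{Cry/PHB}$) and −1
  ($Y_{DPA/PHB}$): endospore formation takes its PHB share first and the
  surplus goes to Cry. Ties in glucose are rejected rather than
  tie-corrected.
* **Normalization** (`normalize_series()`): divide-by-maximum per
  compound, yielding dimensionless [0, 1] curves comparable across
  assays and conditions; idempotent, censoring flags preserved. The time
  axis is left unnormalized.

## Numerical and design choices

* Time is hours since inoculation, continuous; the Gompertz form needs no
  time-zero special case. Concentrations are g/L throughout; CFU
  conversions live in the analysis layer.
* Text formats are fixed, not sniffed: comma-separated, dot-decimal,
  UTF-8, header required. Numbers are written with the shortest decimal
  representation that parses back to the identical double, so write/read
  round-trips are bitwise.
* Degenerate inputs fail loudly and specifically: all-equal observations,
  fewer than 4 points, constant observations in $R^2$, all-zero series in
  normalization, tied glucose in trend tests. A degenerate compound fails
  its stage without aborting the others; the partial result is flagged.
* Randomness is confined to `study_design(seed)`; generation restores the
  caller's RNG stream, and per-fermentation seeds are derived
  deterministically from the study seed, so every analysis is reproducible
  from a single integer.
* Problem sizes were chosen to mirror the emulated study: 11-point grids,
  20 noise realizations per set for recovery medians, 500 draws for the
  law-of-large-numbers check of the generator.

## Organization

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` narrate the study — simulate the reference
fermentations, generate the synthetic study, fit and quantify recovery,
derive phase/yield quantities, run the cross-fermentation analyses — and
write their tables under `results/`, while every computation lives in the
package functions so the tests and `scripts/acceptance.R` exercise exactly
the same code paths.

## Known limitations

The model has no substrate state variable: glucose enters only as a
per-fermentation covariate, and the regressions on it are descriptive,
four-point relationships. The PHB-partition yields are structurally hard
to identify from a single censored series (above). Censoring is handled by
inclusion-as-zero or exclusion, not by a likelihood-based Tobit-style
treatment, matching how non-detects enter the observed kinetics rather
than claiming statistical optimality.
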