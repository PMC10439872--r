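# pacsel

Treatment-selection modelling for primary angle closure (PAC): should a
given eye get **lens extraction (LE)** or **laser peripheral iridotomy
(LPI)**?

Both interventions lower intraocular pressure (IOP), but not equally in
every eye. `pacsel` implements a machine-learning workflow for making the
choice quantitative, built for ophthalmic researchers and biostatisticians
working with anterior-segment biometry:

1. **Group similarity** of the two treatment arms is verified with a
   data-driven SIMCA one-class classifier (chi-squared-scaled score and
   orthogonal distances, `c = N_h h/h0 + N_v v/v0`), which also provides
   the multiplicity-corrected outlier screen used before any regression.
2. **Per-arm models** of the hypotensive effect
   `ΔIOP = IOP_pre − IOP_post` are fitted by 2-component **principal
   component regression** on 37 pre-treatment clinical and anatomical
   parameters, with calibration error RMSEC and a cross-validated error
   RMSECV obtained by **Procrustes cross-validation** (a pseudo-validation
   set that reproduces segment-wise CV predictions under the global
   model).
3. **Counterfactual prediction**: each arm's patients are pushed through
   the *other* arm's model with ±3·RMSEP tolerance intervals — the
   hypothetical outcome had the alternative treatment been chosen.
4. **Decision indicators**: subtracting the two models gives the full
   37-parameter hyperplane
   `Ind_Full(x) = A₀ + Σ Aᵢxᵢ = ŷ_LE(x) − ŷ_LPI(x)`,
   the predicted mm Hg advantage of LE; backward elimination (F-tests on
   the change of RMSEC and RMSECV when a variable is dropped from both
   arm models, p = 0.05) reduces it to a short bedside indicator. Values
   inside the gray zone `|Ind| ≤ 1` mm Hg yield no recommendation.

The published 4-parameter indicator ships ready to use:

```
Ind_Short = 16.80 − 0.28·gender + 0.24·IOP − 0.65·AL − 2.36·ACD
```

(gender 0 = male / 1 = female; IOP in mm Hg; axial length AL and anterior
chamber depth ACD in mm).

Because no patient-level data are public, the package includes a
**calibrated synthetic cohort generator**: correlated anterior-segment
biometry with the published marginal means/SDs, and latent linear
response surfaces per arm whose noise is calibrated so that 2-PC fits at
n = 30 reproduce the published model tolerances (RMSEC ≈ 0.79 / RMSECV ≈
0.87 for LE; 0.39 / 0.41 for LPI) and treatment effects (ΔIOP
7.33 ± 3.40 vs 4.87 ± 2.42 mm Hg). All downstream functionality is
exercised end-to-end on these cohorts.

## Worked example

```r
library(pacsel)

## score a patient with the published bedside indicator
x <- tibble::tibble(gender = 0, IOP = 25.5, AL = 23.5, ACD = 2.33)
recommend_treatment(published_short_indicator(), x)
#> # A tibble: 1 × 2
#>   value decision
#>   <dbl> <fct>
#> 1  2.15 LE
```

The value 2.15 means: for this male patient (baseline IOP 25.5 mm Hg,
AL 23.5 mm, ACD 2.33 mm) lens extraction is predicted to lower IOP about
2.1 mm Hg more than iridotomy — outside the ±1 mm Hg gray zone, so LE is
recommended.

A complete synthetic study (generation, similarity check, model fits,
counterfactuals, indicator derivation, recommendations):

```r
study <- run_study(study_config(n_per_arm = 30, seed = 1))
study
#> Treatment-selection study report
#>   arms: LE n = 30, LPI n = 30
#>   similarity (empirical power): LPI vs LE model 1.00; LE vs LPI model 0.93
#>   LE model: RMSEC 0.81, RMSECV 0.93 | LPI model: RMSEC 0.38, RMSECV 0.46
#>   short indicator: 3 features, replacement RMS 0.74 mm Hg
#>
#>   LE  LPI GRAY
#>   55    0    5
```

Both arms accept each other's one-class model (empirical power 1.00 and
0.93 at α = 0.01), the fitted tolerances sit at the calibrated magnitudes,
and replacing the 37-parameter indicator by the reduced one costs
0.74 mm Hg RMS on this seed — the "about 1 mm Hg" regime in which the
short form remains clinically usable. Most synthetic patients are
recommended LE, reflecting the built-in mean advantage of 2.46 mm Hg;
5 of 60 fall in the gray zone. Note the refitted short indicator selects
its own features per seed (here three anatomy variables) and is not the
published coefficient set.

Useful pieces: `fit_pcr()`, `rmsecv()`, `pcv_set()`,
`fit_with_outlier_removal()`, `predict_with_interval()`, `fit_simca()`,
`similarity_test()`, `detect_outliers()`, `derive_full_indicator()`,
`select_short_indicator()`, `backward_select()`, `recommend()`,
`counterfactual_table()`, `report_render()`, plus broom-style `tidy()` /
`glance()` / `augment()` and `autoplot()` / `plot_*()` figures. The
methods vignette (`vignettes/pacsel-methods.Rmd`) documents the models,
the generator's assumptions and the numerical choices.

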