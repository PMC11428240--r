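# bovitherm

Core body temperature (CBT) prediction for lactating dairy cows.

Rectal temperature is the reference measure of heat stress in dairy cattle
(normal range 38.3–38.7 °C), but it cannot be measured continuously at scale.
`bovitherm` is an R implementation of a machine-learning pipeline that
predicts CBT from observables a farm can collect passively:

- **environment**: air temperature *Ta*, black-globe temperature *Tbg*,
  relative humidity *RH*, wind speed *U*, solar radiation *Qsr*;
- **animal covariates**: milk yield, days in lactation, parity, posture, and
  the A.M./P.M. sampling block;
- **infrared thermography**: mean/maximum surface temperature of nine body
  regions (trunk, legs, udder, head, eyes, face, ears, neck).

## What is inside

1. **Biophysical feature engineering** — seven thermal-comfort indices
   (THI, BGHI, ATHI, CCI, DHLI, ETIC, STIC), e.g.
   `THI = 1.8·Ta + 32 − (0.55 − 0.0055·RH)(1.8·Ta − 26)`, and a
   cow-as-cylinder heat-flux model partitioning losses into latent
   (`Qlat = Qresp + Qevap`) and sensible (`Qsens = Qconv + Qrad`) components
   per m² of body surface.
2. **Preprocessing protocol** — categorical encoding (A.M./P.M. → 0/1,
   standing/lying → 0/1), median imputation, and z-score outlier capping at
   `mean ± 3·sd` (population sd, pre-replacement statistics).
3. **Feature-set benchmarking** — 33 feature sets in five groups, an 80/20
   shuffled split, 5-fold cross-validation, and six model families: elastic
   net, a multilayer perceptron, random forest, and three gradient-boosting
   variants (an internal Rcpp tree engine backs the ensemble families, since
   no external boosting/SHAP libraries are assumed).
4. **Grey wolf optimizer** — the canonical alpha/beta/delta swarm search over
   each family's published hyperparameter space, warm-started at the
   midpoint defaults, minimizing cross-validated RMSE.
5. **TreeSHAP interpretation** — native path-dependent TreeSHAP with exact
   local accuracy, validated against brute-force Shapley enumeration, plus
   the data behind summary, dependence and waterfall plots.
6. **Synthetic cohort generator** — because the original farm data are not
   deposited, a generator with a *known* CBT model
   (`38.4 + 0.12·max(0, IRTave_TK − 34) + 0.10·TZ + 0.08·BP −
   0.15·max(0, DOL − 200)/200 + ε`, ε ~ N(0, 0.25 °C)) makes every stage
   testable against ground truth.

## Worked example

```r
library(bovitherm)

co  <- gen_cohort(generator_config(seed = 42))   # ~3000 rows, 30 days
co
#> Synthetic cow cohort: 3108 observations over 30 days; 3006 missing cells

ft  <- add_thermal_features(preprocess_cohort(co$data)$table)
reg <- build_registry()
mat <- materialize(ft, reg$IRTave_TK)            # trunk IRT + animal vars

tn <- tune("XGBoost", mat$X, mat$y, split = split_config(seed = 42),
           gwo = gwo_config(population = 6, epochs = 4, seed = 42))
round(tn$test_metrics, 3)
#>    r2   mae  rmse
#> 0.268 0.203 0.256
```

The tuned boosting model reaches a held-out RMSE of 0.256 °C against a
generative noise floor of 0.25 °C, and its cross-validated RMSE (0.2516)
improves on the midpoint-default baseline (0.2743) — the warm start makes
that improvement a guarantee, not luck. The R² of 0.268 is bounded by the
cohort's theoretical ceiling `r2_ceiling(co$truth)` ≈ 0.34: most CBT
variance here is irreducible measurement noise, by design.

```r
sh <- explain(tn$model, tn$split$X_train)
summary_stats(sh)
#>     feature mean_abs_shap
#> 1 IRTave_TK        0.1248
#> 2        TZ        0.0418
#> 3       DOL        0.0402
#> 4        BP        0.0284
#> 5        MY        0.0136
#> 6        PA        0.0101
```

SHAP recovers the generative drivers in order: trunk infrared temperature
dominates, followed by time zone, lactation stage and posture — the
attribution of each prediction sums exactly to that prediction
(`waterfall_data(sh, i)`), and `dependence_data(sh, "IRTave_TK")` exposes
the 34 °C hinge.

One-command runs:

```sh
Rscript -e 'bovitherm::bovitherm_cli()' all --seed 42 --out run_dir --quick
```

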