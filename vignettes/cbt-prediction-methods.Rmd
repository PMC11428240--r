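---
title: "Methods: predicting dairy-cow core body temperature from environment, animal covariates and infrared thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting dairy-cow core body temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovitherm)
```

## The problem

The core body temperature (CBT) of a lactating dairy cow — in practice her
rectal temperature, normally 38.3–38.7 °C — is the reference indicator of
heat stress, but measuring it is invasive and slow. `bovitherm` implements a
prediction pipeline that estimates CBT from quantities a farm can observe
continuously: the barn micro-environment (air temperature Ta, black-globe
temperature Tbg, relative humidity RH, wind speed U, solar radiation Qsr),
per-animal covariates (milk yield MY, days in lactation DOL, parity PA, body
posture BP, the A.M./P.M. sampling block TZ), and infrared surface
temperatures (mean and maximum, `IRTave_*` / `IRTmax_*`) of nine body
regions.

The pipeline has six stages: synthetic cohort generation, preprocessing,
biophysical feature engineering, feature-set benchmarking across six
regression families, grey-wolf-optimizer (GWO) hyperparameter search, and
TreeSHAP interpretation.

## Biophysical feature engineering

Two families of engineered features summarize the thermal environment.

**Thermal-comfort indices.** Seven scalar indices combine Ta, Tbg, RH, U and
Qsr into heat-stress proxies: THI, BGHI, ATHI, CCI, DHLI, ETIC and STIC.
THI, BGHI, ATHI and ETIC are short closed forms and are tested against hand
evaluations. The CCI, DHLI and STIC formulas circulate in typographically
mangled variants; this package documents the exact parenthesisation it uses
in each function's help page and pins behavior with *limit and monotonicity
tests* (e.g. ETIC reduces to Ta at saturation/calm/no-sun; DHLI is bounded
on a 0–100-type scale and increasing in Tbg; the STIC vapor-deficit term
vanishes at RH = 100) rather than with golden constants whose provenance
could not be verified. BGHI needs the dew point, which the index literature
leaves undefined; we use the Magnus formula with a = 17.625, b = 243.04 °C,
the standard meteorological parameterisation.

**Heat fluxes.** The cow is modelled as a 0.8 m cylinder with 5.4 m² of
surface exchanging heat by respiration (Qresp), cutaneous evaporation
(Qevap = Rsw·λ/3600), convection (Qconv = (Tc − Ta)·k·Nu/d) and radiation,
with totals Qlat = Qresp + Qevap and Qsens = Qconv + Qrad holding as exact
identities by construction. Empirical sub-models supply skin temperature,
coat temperature, exhaled-air temperature, sweating rate (piecewise at
Ts = 35 °C, with Ts = 35 assigned to the linear branch), saturation vapor
pressures, respiratory frequency, tidal volume and respiratory resistance.
Three numerical choices were genuinely open and are fixed as follows:

* **Nusselt number.** No published form accompanies the convection model, so
  we use the Hilpert cylinder-in-crossflow correlation
  (Nu = C·Re^m·Pr^(1/3), Re = U·d/ν, ν = 1.5 × 10⁻⁵ m²/s, Pr = 0.71) with
  the usual Reynolds-banded coefficients, and Nu = 0 in still air — natural
  convection is out of scope. The choice is isolated in one function and the
  constants are configurable via `thermal_constants()`.
* **Radiation in Kelvin.** The linearized radiation term
  (Tc − Trad)·4σε·T̄³ is evaluated with the mean temperature converted to
  Kelvin; cubing a Celsius value would be physically meaningless.
* **Respiratory vapor term.** The tabulated sub-models define only the
  *saturation* pressure at Ta, but a saturation-minus-saturation difference
  would ignore humidity entirely. The default uses actual ambient vapor
  pressure (RH/100 × saturation at Ta); the literal saturation reading is
  available via `thermal_constants(ambient_vapor = "saturation")`, and the
  convention in force is recorded with the constants.
* **Tidal volume floor.** The linear tidal-volume model goes negative below
  a respiratory frequency of ~24.5 breaths/min; Vt is floored at 10⁻⁴ m³
  (configurable) rather than silently producing a nonphysical negative flux.

## Preprocessing protocol

Order is fixed: **encode → impute → cap**. TZ is encoded A.M. → 0,
P.M. → 1 and BP standing → 0, lying down → 1 (case-insensitive; unseen
labels are an error). Missing cells — realistic only in milk yield and the
infrared columns — are replaced by the column median. Outliers are then
detected by z-score with **population** standard deviation (divide by n) and
threshold 3: cells with z > 3 become mean + 3·sd and cells with z < −3
become mean − 3·sd. Two readings were possible here: capping low outliers at
mean + 3·sd (the literal upper-side rule) would move them to the *high*
tail, contradicting the purpose of the rule, so the sign-aware symmetric cap
is used. Statistics are computed once from pre-replacement data and not
updated between replacements; the target CBT is never imputed or capped.
Zero-variance columns are skipped. `preprocess_cohort()` returns a report
(counts, statistics, encoding maps) that the tests use to verify the
|z| ≤ 3 contract against the original statistics.

## Synthetic cohort: the stated world

No farm data accompany the method, so the package ships a generator whose
defaults encode the survey design: 30 sampling days, 90–120 cows per day
(~3000 rows), observations confined to 8:00–12:00 and 14:00–18:00, CBT
residual sd 0.25 °C, 5% missingness in MY and each infrared column, 0.5%
multiplicative outliers (factor 1.5), thermometer clipping to [32, 42] °C.
The generative CBT model is

CBT = 38.4 + 0.12·max(0, IRTave_TK − 34) + 0.10·TZ + 0.08·BP
      − 0.15·max(0, DOL − 200)/200 + ε,  ε ~ N(0, 0.25²),

whose hinge at a trunk temperature of 34 °C, afternoon/lying increments and
lactation-stage decline after day 200 encode the effect directions the
interpretation stage is expected to recover with known ground truth.

The covariate marginals are declared stand-ins (the study never reports
them): Ta follows a diurnal sinusoid (mean 27 °C, amplitude 5 °C, peak
15:00) with day-level (sd 1.5 °C) and observation (sd 0.5 °C) noise; RH is
anti-correlated with Ta and clipped to [20, 100]; U is Weibull (right-
skewed); Qsr peaks at midday; Tbg = Ta + 3 °C per kW/m² of Qsr. Trunk
infrared temperature is exogenous (25.0 + 0.33·Ta + N(0, 1.5), i.e. mean
≈ 34 °C, sd ≈ 2 °C — realistic for summer thermography) and *drives* CBT;
the other eight regions are conditioned on the realized CBT with weaker
couplings (0.4–0.8 °C/°C), making the trunk the most informative region by
construction. This resolves a circularity in the design sketch (trunk IRT
cannot both drive CBT and be regressed on it) while preserving the exact
oracle property: with corruption and noise disabled the stored CBT equals
the generative formula evaluated on the table's own row. Cow identity and
repeated measures are deliberately not modelled — the downstream pipeline
treats rows as exchangeable (shuffled row-wise split), so modelling them
would change nothing it could detect. RH receives no multiplicative
outliers: a 1.5× spike would leave the physical domain (>100%) instead of
emulating a sensor error.

Consequently, a green pipeline test establishes that the machinery recovers
a known signal at the stated noise level; it does *not* establish the
real-world accuracy figures, which depend on the unavailable farm data.

## Benchmarking and models

Feature sets come in five groups (33 sets by default): `ENV`
(environment + TZ), `ANM` (ENV + animal covariates), one set per infrared
region for IRTmax and IRTave, one per comfort index and one per heat-flux
variable; all non-ENV sets include MY, DOL, PA, BP and TZ. Whether the
index/flux sets should carry TZ is not fully pinned down in the source
design; they do here, mirroring the ANM template, and the registry is
configurable.

Rows are shuffled and split 80/20; models are scored by R², MAE and RMSE,
with 5-fold cross-validation on the training partition used for tuning
fitness and reporting. Six families are benchmarked: elastic net (glmnet),
a multilayer perceptron (in-package: full-batch Adam, Glorot init, relu/tanh,
L2 penalty, standardized inputs — the sklearn-style parameter names of its
search space), random forest, and three gradient-boosting variants. The
environment provides none of the usual tree-ensemble or SHAP libraries, so
the tree families run on an internal Rcpp engine: exact-greedy CART with
second-order leaf weights and L1/L2 regularization, stagewise boosting with
row subsampling, or bootstrap-averaged forests with per-split feature
sampling. Each family exposes exactly its published hyperparameter space;
"non-optimized" defaults are range midpoints (geometric for log-scaled
dimensions, first option for categoricals), a declared convention since no
pre-optimization defaults are published.

The generator also yields a leakage guard: the deterministic CBT component
gives a theoretical R² ceiling (`r2_ceiling()`), and no model may beat it by
more than sampling noise.

## Grey wolf optimizer

`gwo_minimize()` is the canonical algorithm on the unit hypercube: the three
best wolves (alpha, beta, delta) guide every move via
X_i = L − A_i·|C_i·L − X| with A = 2a·r1 − a, C = 2·r2, the new position the
mean of the three guided ones, clipped to [0, 1], and a decaying linearly
2 → 0 over the epochs. All randomness comes from one seeded generator;
r1, r2 are i.i.d. uniform per wolf, per dimension, per leader. Mixed search
spaces are handled by decoding: linear for continuous, geometric for
multiplicative parameters (learning rates, penalties — a standard practice
the source design leaves open), floor-and-clamp for integers, index for
categoricals. Tuning fitness is the mean 5-fold CV RMSE on the training
partition (RMSE rather than R² because it is scale-stable and directly the
quantity reported; configurable), and the test partition is never touched.
One wolf is warm-started at the default-midpoint candidate, so the tuned CV
RMSE is never worse than the baseline's on the same folds — this makes the
optimizer-versus-default dominance a property rather than a hope. Other
metaheuristics are not re-implemented; any `minimize(objective, space,
config)` function can be plugged in.

## TreeSHAP interpretation

`explain()` computes per-row additive attributions with the path-dependent
polynomial-time TreeSHAP algorithm over the internal tree structures,
implemented natively (no SHAP library exists in the target environment).
Conditioning is tree-path-dependent — absent features are marginalized by
the training cover of each node — and that convention is recorded in the
result object. The base value is the cover-weighted expected model output,
and local accuracy (base + Σ attributions = prediction) holds to numerical
precision on every row. The explainer is validated against an independent
brute-force oracle (`shap_brute_force()`): exhaustive subset enumeration of
the same tree value function, tractable for small trees. Explanations are
computed for the final model refit on the full training partition (which
fold-model to explain is unspecified in the source design; the refit is the
deployable object). The tested artifacts are the data products behind the
summary (mean |SHAP|, ties broken lexicographically), dependence and
waterfall plots; rendering is left to the user.

## Reproducibility

Every stochastic stage takes a seed; `run_pipeline()` fans a single seed out
to per-stage seeds via a documented hash of the stage name, and identical
configs reproduce evaluation and SHAP tables byte-for-byte. Model fits are
deterministic given (data, hyperparameters, seed), including the C++ engine,
which uses its own seeded generator.

## Worked example

```{r example, eval = FALSE}
co <- gen_cohort(generator_config(seed = 42))
ft <- add_thermal_features(preprocess_cohort(co$data)$table)
reg <- build_registry()
mat <- materialize(ft, reg$IRTave_TK)
tn <- tune("XGBoost", mat$X, mat$y, split = split_config(seed = 42),
           gwo = gwo_config(population = 6, epochs = 4, seed = 42))
tn$test_metrics
sh <- explain(tn$model, tn$split$X_train)
head(summary_stats(sh))
```

## Known limitations

* The synthetic world is far simpler than a barn: rows are independent, the
  generative model is a four-term hinge, and covariate marginals are
  declared rather than estimated. Absolute performance numbers on it do not
  transfer.
* The boosting families share one engine; they differ in their
  hyperparameter spaces and growth settings, not in the vendor-specific
  algorithmic details (histogram binning, ordered boosting, oblivious
  trees).
* CCI, DHLI and STIC implement one documented resolution of ambiguous
  printed formulas; their tests pin qualitative behavior, not third-party
  reference values.
* Natural convection (U = 0 gives Qconv = 0), long-wave sky radiation and
  transient heat-balance simulation are out of scope.
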