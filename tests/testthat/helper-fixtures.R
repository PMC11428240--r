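# Shared fixtures: all test data is generated in code.

# small cohort for fast unit tests
small_cohort <- function(seed = 7, n_days = 4, noise = 0.25,
                         missing = 0.05, outlier = 0.01) {
  gen_cohort(generator_config(
    n_days = n_days, cows_per_day_range = c(30L, 40L), seed = seed,
    noise_sd_cbt = noise, missing_rate_my = missing,
    missing_rate_irt = missing, outlier_rate = outlier))
}

# preprocessed + feature-engineered small table
small_featured <- function(...) {
  co <- small_cohort(...)
  add_thermal_features(preprocess_cohort(co$data)$table)
}

# hand-built tree-ensemble model objects (bypassing the fitting path) for
# SHAP oracle tests; trees use the engine's flat 0-based layout
manual_tree_model <- function(trees, n_features, base = 0) {
  structure(list(family = "XGBoost", params = NULL, engine = "tree",
                 fit = list(trees = trees, base = base, mode = "gbt",
                            n_features = n_features),
                 feature_names = paste0("x", seq_len(n_features)),
                 seed = 1L),
            class = c("bovitherm_tree", "bovitherm_model"))
}

# a stump: split on feature `f` (1-based) at `thr`, left value vl (cover cl),
# right value vr (cover cr)
stump_tree <- function(f, thr, vl, vr, cl = 50, cr = 50) {
  list(feature = c(f - 1L, -1L, -1L), threshold = c(thr, 0, 0),
       left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
       value = c(0, vl, vr), cover = c(cl + cr, cl, cr))
}

small_xgb_params <- function() {
  list(n_estimators = 100, learning_rate = 0.1, subsample = 1.0,
       reg_alpha = 0.01, reg_lambda = 0.01)
}
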