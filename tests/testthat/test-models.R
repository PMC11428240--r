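# Metrics, splitting, folds, hyperparameter validation, and the six model
# families behind the uniform fit/predict interface.

test_that("metrics match their defining formulas", {
  expect_identical(metrics(c(1, 2, 3), c(1, 2, 3)),
                   c(r2 = 1, mae = 0, rmse = 0))
  expect_identical(metrics(c(38, 40), c(39, 39)),
                   c(r2 = 0, mae = 1, rmse = 1))
  y <- c(2, 4, 6, 8)
  expect_identical(metrics(y, rep(mean(y), 4))[["r2"]], 0)
  expect_warning(m <- metrics(c(3, 3, 3), c(1, 2, 3)), "undefined")
  expect_true(is.na(m[["r2"]]))
  expect_error(metrics(1:3, 1:2), "equal")
})

test_that("rmse >= mae for arbitrary prediction vectors", {
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(50)
    p <- rnorm(50)
    m <- metrics(y, p)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
})

test_that("train/test split is deterministic, disjoint, right-sized", {
  X <- matrix(rnorm(3005 * 2), 3005)
  y <- rnorm(3005)
  sp <- split_train_test(X, y, split_config(seed = 4))
  expect_length(sp$test_idx, 601)   # round(3005 * 0.2)
  expect_length(sp$train_idx, 2404)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  sp2 <- split_train_test(X, y, split_config(seed = 4))
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_false(identical(
    sp$train_idx, split_train_test(X, y, split_config(seed = 5))$train_idx))
  expect_error(split_config(test_fraction = 0), "test_fraction")
  expect_error(split_config(n_folds = 1), "n_folds")
  expect_error(split_train_test(X[1:3, ], y[1:3], split_config(n_folds = 5)),
               "fewer rows")
})

test_that("cv folds partition the rows exactly", {
  f <- make_folds(103, 5, seed = 2)
  expect_length(f, 103)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_identical(f, make_folds(103, 5, seed = 2))
})

test_that("hyperparameters outside the printed ranges are rejected", {
  p <- default_hyperparams("XGBoost")
  p$n_estimators <- 1500
  expect_error(validate_hyperparams("XGBoost", p), "\\[100, 1000\\]")
  p <- default_hyperparams("RF")
  p$max_features <- "all"
  expect_error(validate_hyperparams("RF", p), "max_features")
  p <- default_hyperparams("EN")
  p$alpha <- 0
  expect_error(validate_hyperparams("EN", p), "alpha")
  expect_silent(validate_hyperparams("ANN", default_hyperparams("ANN")))
})

test_that("default hyperparameters sit at range midpoints", {
  p <- default_hyperparams("XGBoost")
  expect_identical(p$n_estimators, 550L)
  expect_equal(p$subsample, 0.55)
  expect_equal(p$learning_rate, sqrt(0.01 * 0.2))
  expect_identical(default_hyperparams("ANN")$activation, "relu")
  expect_identical(default_hyperparams("ANN")$hidden_layer_sizes, c(100L))
})

test_that("near-unregularized elastic net recovers a noiseless linear truth", {
  set.seed(6)
  X <- matrix(rnorm(600), 200, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5)) + 5
  m <- fit_model("EN", X, y, params = list(alpha = 1e-4, l1_ratio = 0.5))
  expect_gt(metrics(y, predict(m, X))[["r2"]], 0.999)
})

test_that("tree families and the MLP fit a nonlinear signal; refits are identical", {
  set.seed(7)
  X <- matrix(rnorm(300 * 3), 300, 3)
  colnames(X) <- c("a", "b", "c")
  y <- 2 * (X[, 1] > 0) + 0.5 * X[, 2] + rnorm(300, 0, 0.05)
  for (fam in c("RF", "XGBoost", "LightGBM", "CatBoost", "ANN")) {
    params <- default_hyperparams(fam)
    if (fam %in% c("XGBoost", "CatBoost")) params[[1]] <- 150L
    if (fam == "LightGBM") params$num_iteration <- 150L
    if (fam == "RF") params$n_estimators <- 150L
    if (fam == "ANN") params$max_iter <- 300L
    m1 <- fit_model(fam, X, y, params, seed = 3)
    m2 <- fit_model(fam, X, y, params, seed = 3)
    p1 <- predict(m1, X)
    expect_identical(p1, predict(m2, X))
    expect_gt(metrics(y, p1)[["r2"]], 0.5, label = fam)
  }
})

test_that("cross-validated metrics are deterministic given the config", {
  set.seed(10)
  X <- matrix(rnorm(150 * 2), 150, 2)
  y <- X[, 1] + rnorm(150, 0, 0.1)
  p <- small_xgb_params()
  cfg <- split_config(seed = 11)
  expect_identical(cv_metrics("XGBoost", X, y, p, cfg),
                   cv_metrics("XGBoost", X, y, p, cfg))
  tm <- train_model("XGBoost", X, y, p, cfg)
  expect_s3_class(tm$model, "bovitherm_model")
  expect_true(all(c("r2", "mae", "rmse") %in% names(tm$cv)))
})

test_that("benchmark emits one row per set, family and split plus aggregates", {
  ft <- small_featured(seed = 23)
  reg <- build_registry(roi_list = "TK", index_list = "THI",
                        flux_list = "Qsens")
  fams <- c("EN", "XGBoost")
  params <- list(XGBoost = small_xgb_params())
  b <- benchmark(reg, ft, fams, split_config(seed = 3), params = params)
  expect_identical(nrow(b$results), length(reg) * length(fams) * 2L)
  expect_setequal(unique(b$results$split), c("train", "test"))
  expect_identical(nrow(b$by_set), length(reg))
  expect_identical(unique(b$by_set$n_models), length(fams))
  # aggregation over identical results has zero spread
  b1 <- benchmark(reg["ENV"], ft, c("EN", "EN"), split_config(seed = 3))
  expect_identical(b1$by_set$r2_sd, 0)
  # paired comparison runs and reports the right fields
  pt <- paired_set_test(b$results, "ANM", "ENV", "r2")
  expect_identical(pt$df, length(fams) - 1)
  expect_true(is.finite(pt$t))
})
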