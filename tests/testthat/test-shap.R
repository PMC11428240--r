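# TreeSHAP attributions: local accuracy, agreement with brute-force Shapley
# enumeration over the tree value function, and the plot-data products.

test_that("non-tree models are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  m <- fit_model("EN", X, rnorm(20),
                 params = list(alpha = 0.01, l1_ratio = 0.5))
  expect_error(explain(m, X), "tree-ensemble")
})

test_that("a constant model attributes nothing", {
  set.seed(14)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(3.7, 100)
  m <- fit_model("XGBoost", X, y, small_xgb_params())
  sh <- explain(m, X)
  expect_equal(max(abs(sh$values)), 0)
  expect_equal(sh$base_value, 3.7)
})

test_that("single-split stump: only the split feature gets attribution, equal to brute force", {
  tr <- stump_tree(f = 2, thr = 0.0, vl = -1, vr = 3, cl = 30, cr = 70)
  m <- manual_tree_model(list(tr), n_features = 3)
  x_hi <- c(0.4, 0.7, -2)
  x_lo <- c(0.4, -0.7, -2)
  sh <- explain(m, rbind(x_hi, x_lo))
  # E[f] = 0.3*(-1) + 0.7*3 = 1.8; phi_2 = f(x) - E[f], others zero
  expect_equal(sh$base_value, 1.8)
  expect_equal(unname(sh$values[1, ]), c(0, 3 - 1.8, 0))
  expect_equal(unname(sh$values[2, ]), c(0, -1 - 1.8, 0))
  bf <- shap_brute_force(m, x_hi)
  expect_equal(unname(sh$values[1, ]), bf, tolerance = 1e-12)
})

test_that("depth-2 tree with distinct features matches brute-force Shapley", {
  # x1 <= 0 -> leaf 5; else split on x3 <= 1: 10 / 20
  tr <- list(feature = c(0L, -1L, 2L, -1L, -1L),
             threshold = c(0, 0, 1, 0, 0),
             left = c(1L, -1L, 3L, -1L, -1L),
             right = c(2L, -1L, 4L, -1L, -1L),
             value = c(0, 5, 0, 10, 20),
             cover = c(100, 40, 60, 45, 15))
  m <- manual_tree_model(list(tr), n_features = 3)
  for (x in list(c(-1, 0, 0), c(1, 0, 0.5), c(1, 0, 2), c(0, 9, 1))) {
    expect_equal(unname(explain(m, matrix(x, 1))$values[1, ]),
                 shap_brute_force(m, x), tolerance = 1e-12)
  }
})

test_that("fitted boosted ensemble agrees with brute force on 3 features", {
  set.seed(15)
  X <- matrix(rnorm(240), 80, 3)
  colnames(X) <- c("a", "b", "c")
  y <- 1.5 * (X[, 1] > 0) + 0.4 * X[, 2] + rnorm(80, 0, 0.05)
  m <- fit_model("XGBoost", X, y, small_xgb_params())
  rows <- X[1:6, , drop = FALSE]
  sh <- explain(m, rows)
  bf <- t(vapply(1:6, function(i) shap_brute_force(m, rows[i, ]),
                 numeric(3)))
  expect_equal(unname(sh$values), unname(bf), tolerance = 1e-10)
})

test_that("local accuracy holds on a synthetic-cohort model", {
  ft <- small_featured(seed = 41)
  reg <- build_registry()
  mat <- materialize(ft, reg$IRTave_TK)
  m <- fit_model("XGBoost", mat$X, mat$y, small_xgb_params(), seed = 2)
  sh <- explain(m, mat$X)
  resid <- abs(sh$base_value + rowSums(sh$values) - predict(m, mat$X))
  expect_lt(max(resid), 1e-6)
  # base value ~ mean prediction over the background
  expect_equal(sh$base_value, mean(predict(m, mat$X)), tolerance = 0.02)
})

test_that("summary ranking is order-invariant, non-negative, tie-broken by name", {
  ft <- small_featured(seed = 41)
  mat <- materialize(ft, build_registry()$IRTave_TK)
  m <- fit_model("XGBoost", mat$X, mat$y, small_xgb_params(), seed = 2)
  sh <- explain(m, mat$X)
  s1 <- summary_stats(sh)
  expect_true(all(s1$mean_abs_shap >= 0))
  expect_true(all(diff(s1$mean_abs_shap) <= 0))
  perm <- sample(nrow(mat$X))
  s2 <- summary_stats(explain(m, mat$X[perm, ]))
  expect_identical(s1$feature, s2$feature)
  expect_equal(s1$mean_abs_shap, s2$mean_abs_shap)
  # all-zero attributions rank lexicographically
  mz <- manual_tree_model(list(stump_tree(1, 0, 0, 0)), n_features = 3)
  sz <- summary_stats(explain(mz, matrix(rnorm(9), 3)))
  expect_identical(sz$feature, c("x1", "x2", "x3"))
  expect_identical(sz$mean_abs_shap, rep(0, 3))
})

test_that("dependence data preserves rows and colors by the interaction feature", {
  m <- manual_tree_model(list(stump_tree(1, 0, -1, 1)), n_features = 2)
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("x1", "x2")
  sh <- explain(m, X)
  d_self <- dependence_data(sh, "x1")
  expect_identical(nrow(d_self), 20L)
  expect_identical(d_self$color, d_self$x)
  d_int <- dependence_data(sh, "x1", "x2")
  expect_identical(d_int$color, X[, "x2"])
  expect_identical(d_int$attribution, unname(sh$values[, "x1"]))
  expect_error(dependence_data(sh, "nope"), "unknown feature")
})

test_that("waterfall data orders by impact and ends at the prediction", {
  ft <- small_featured(seed = 41)
  mat <- materialize(ft, build_registry()$IRTave_TK)
  m <- fit_model("XGBoost", mat$X, mat$y, small_xgb_params(), seed = 2)
  sh <- explain(m, mat$X[1:20, ])
  wf <- waterfall_data(sh, 7)
  expect_setequal(wf$steps$feature, colnames(mat$X))  # permutation of all
  expect_true(all(diff(abs(wf$steps$attribution)) <= 1e-12))
  pred <- predict(m, mat$X[7, , drop = FALSE])
  expect_equal(wf$prediction, pred, tolerance = 1e-6)
  expect_equal(wf$steps$cumulative[nrow(wf$steps)], pred, tolerance = 1e-6)
  expect_error(waterfall_data(sh, 100), "out of range")
})
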