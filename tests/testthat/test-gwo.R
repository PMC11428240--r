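# Grey wolf optimizer: decoding, canonical search behavior, tuning front-end.

unit_space <- function(d, lo = -10, hi = 10) {
  make_search_space(lapply(seq_len(d), function(i)
    list(name = paste0("x", i), kind = "continuous", bounds = c(lo, hi))))
}

test_that("decode maps the unit hypercube onto every dimension kind", {
  space <- make_search_space(list(
    list(name = "lr", kind = "log-continuous", bounds = c(0.01, 0.2)),
    list(name = "sub", kind = "continuous", bounds = c(0.1, 1.0)),
    list(name = "n", kind = "integer", bounds = c(100, 1000)),
    list(name = "act", kind = "categorical", options = c("relu", "tanh"))))
  d0 <- decode(c(0, 0, 0, 0), space)
  expect_equal(d0$lr, 0.01)
  expect_equal(d0$sub, 0.1)
  expect_identical(d0$n, 100L)
  expect_identical(d0$act, "relu")
  d1 <- decode(c(1, 1, 1, 1), space)
  expect_equal(d1$lr, 0.2)
  expect_identical(d1$n, 1000L)
  expect_identical(d1$act, "tanh")      # index clamped at k - 1
  dm <- decode(c(0.5, 0.5, 0.5, 0.4), space)
  expect_equal(dm$lr, sqrt(0.01 * 0.2)) # geometric midpoint
  expect_identical(dm$n, 550L)
  expect_identical(dm$act, "relu")
  expect_error(decode(c(0.5, 2, 0.5, 0.5), space), "\\[0, 1\\]")
  expect_error(decode(c(0.5, 0.5), space), "length")
})

test_that("search-space invariants are enforced", {
  expect_error(make_search_space(list(
    list(name = "a", kind = "continuous", bounds = c(1, 1)))), "low < high")
  expect_error(make_search_space(list(
    list(name = "a", kind = "categorical", options = list()))), "empty")
  expect_error(make_search_space(list(
    list(name = "a", kind = "continuous", bounds = c(0, 1)),
    list(name = "a", kind = "continuous", bounds = c(0, 1)))), "unique")
  expect_error(gwo_config(population = 3), "population")
})

test_that("GWO minimizes the sphere and its curve never increases", {
  sphere <- function(p) sum(unlist(p)^2)
  run <- gwo_minimize(sphere, unit_space(5),
                      gwo_config(population = 15, epochs = 40, seed = 2))
  expect_lt(run$best$fitness, 0.1)
  expect_true(all(diff(run$curve) <= 0))
  expect_identical(run$curve[length(run$curve)], run$best$fitness)
  # determinism
  run2 <- gwo_minimize(sphere, unit_space(5),
                       gwo_config(population = 15, epochs = 40, seed = 2))
  expect_identical(run$curve, run2$curve)
  expect_identical(run$best$position, run2$best$position)
})

test_that("a single epoch with a tiny pack returns the best initial sample", {
  seen <- new.env(); seen$vals <- numeric(0)
  obj <- function(p) {
    v <- sum(unlist(p)^2)
    seen$vals <- c(seen$vals, v)
    v
  }
  run <- gwo_minimize(obj, unit_space(2),
                      gwo_config(population = 4, epochs = 1, seed = 3))
  expect_lte(run$best$fitness, min(seen$vals[1:4]))
})

test_that("the pack contracts toward the leader as exploration decays", {
  # 1-dim toy: record per-epoch spread of evaluated positions
  trace <- new.env(); trace$x <- list()
  obj <- function(p) {
    trace$x[[length(trace$x) + 1]] <- p$x1
    (p$x1 - 1)^2
  }
  run <- gwo_minimize(obj, unit_space(1, 0, 4),
                      gwo_config(population = 10, epochs = 30, seed = 4))
  xs <- unlist(trace$x)
  early <- stats::sd(xs[11:40])            # first epochs after init
  late <- stats::sd(xs[(length(xs) - 29):length(xs)])
  expect_lt(late, early / 5)
  expect_lt(abs(mean(xs[(length(xs) - 9):length(xs)]) - 1), 0.2)
})

test_that("non-finite objective values are quarantined, not propagated", {
  obj <- function(p) if (p$x1 > 2) NaN else (p$x1 - 1)^2
  warns <- testthat::capture_warnings(
    run <- gwo_minimize(obj, unit_space(1, 0, 4),
                        gwo_config(population = 6, epochs = 5, seed = 5)))
  expect_true(any(grepl("non-finite", warns)))
  expect_true(is.finite(run$best$fitness))
})

test_that("every candidate evaluated on a model space decodes within bounds", {
  space <- hyperparam_space("XGBoost")
  obj <- function(params) {
    validate_hyperparams("XGBoost", params)  # errors if out of range
    abs(params$learning_rate - 0.05) + abs(params$subsample - 0.8)
  }
  run <- gwo_minimize(obj, space, gwo_config(population = 8, epochs = 10,
                                             seed = 6))
  expect_true(is.finite(run$best$fitness))
  expect_silent(validate_hyperparams("XGBoost", run$best$decoded))
})

test_that("tuning never returns worse cross-validated RMSE than the defaults", {
  set.seed(12)
  X <- matrix(rnorm(150 * 3), 150, 3)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(150, 0, 0.2)
  tn <- tune("XGBoost", X, y, split = split_config(seed = 9),
             gwo = gwo_config(population = 4, epochs = 2, seed = 9))
  expect_lte(tn$cv_rmse, tn$default_cv_rmse)
  expect_silent(validate_hyperparams("XGBoost", tn$best_params))
  expect_true(all(diff(tn$curve) <= 0))
  expect_s3_class(tn$model, "bovitherm_model")
  expect_true(all(c("r2", "mae", "rmse") %in% names(tn$test_metrics)))
})
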