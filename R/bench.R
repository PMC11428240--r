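# Train/test split, k-fold cross-validation, the three evaluation metrics,
# and the feature-set x model-family benchmark grid.

#' Split configuration
#'
#' @param test_fraction fraction of rows held out for testing, in (0, 1).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param shuffle shuffle rows before splitting (always TRUE here; kept for
#'   config serialization).
#' @param seed integer seed controlling the shuffle and fold assignment.
#' @return list of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.2, n_folds = 5, shuffle = TRUE,
                         seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "split_config")
}

#' Shuffled train/test split
#'
#' Deterministic given the seed. Test size is `round(n * test_fraction)`.
#'
#' @param X feature matrix. @param y target vector.
#' @param config a [split_config()].
#' @return list with `X_train`, `y_train`, `X_test`, `y_test`, `train_idx`,
#'   `test_idx`.
#' @export
split_train_test <- function(X, y, config = split_config()) {
  stopifnot(inherits(config, "split_config"))
  n <- nrow(X)
  if (length(y) != n) stop("X and y must be row-aligned")
  if (n < config$n_folds) stop("fewer rows than folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  perm <- sample.int(n)
  n_test <- round(n * config$test_fraction)
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  list(X_train = X[train_idx, , drop = FALSE], y_train = y[train_idx],
       X_test = X[test_idx, , drop = FALSE], y_test = y[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Balanced cross-validation fold assignment
#'
#' Every row lands in exactly one held-out fold; fold sizes differ by at
#' most one. Deterministic given the seed.
#'
#' @param n number of rows. @param n_folds number of folds. @param seed seed.
#' @return integer vector of fold labels in `1..n_folds`.
#' @export
make_folds <- function(n, n_folds = 5, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Regression metrics: R^2, MAE, RMSE
#'
#' `r2 = 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)`,
#' `mae = mean(|yt - yp|)`, `rmse = sqrt(mean((yt - yp)^2))`.
#' With zero variance in `y_true`, R^2 is undefined and returned as `NA`
#' with a warning.
#'
#' @param y_true observed values. @param y_pred predictions.
#' @return named numeric vector `c(r2, mae, rmse)`.
#' @export
#' @examples
#' metrics(c(38, 40), c(39, 39))  # r2 0, mae 1, rmse 1
metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop("y_true and y_pred must have equal non-zero length")
  }
  err <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in y_true; R^2 undefined")
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  c(r2 = r2, mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Cross-validated RMSE (and companion metrics) of one family
#'
#' Mean over `n_folds` held-out folds of the metrics on that fold; the model
#' is refit on the remaining folds each time.
#'
#' @inheritParams fit_model
#' @param config a [split_config()] (its `n_folds` and `seed` are used).
#' @return named numeric vector `c(r2, mae, rmse)` of fold means.
#' @export
cv_metrics <- function(family, X, y, params = NULL,
                       config = split_config()) {
  folds <- make_folds(nrow(X), config$n_folds, seed = config$seed)
  res <- vapply(seq_len(config$n_folds), function(k) {
    tr <- folds != k
    m <- fit_model(family, X[tr, , drop = FALSE], y[tr], params,
                   seed = config$seed)
    suppressWarnings(metrics(y[!tr],
                             stats::predict(m, X[!tr, , drop = FALSE])))
  }, numeric(3))
  rowMeans(res)
}

#' Train one family and report its cross-validated performance
#'
#' Fits the model on the full training data and evaluates it by
#' `config$n_folds`-fold cross-validation on the same data.
#'
#' @inheritParams cv_metrics
#' @return list with `model` (fitted on all rows) and `cv` (named metric
#'   vector of fold means).
#' @export
train_model <- function(family, X, y, params = NULL,
                        config = split_config()) {
  if (is.null(params)) params <- default_hyperparams(family)
  validate_hyperparams(family, params)
  list(model = fit_model(family, X, y, params, seed = config$seed),
       cv = cv_metrics(family, X, y, params, config))
}

#' Benchmark model families over a registry of feature sets
#'
#' For each (feature set, family) pair: split, fit (default-midpoint or
#' supplied hyperparameters), and record train/test metrics. Also aggregates
#' per feature set across families (mean and sd over the `N = |families|`
#' models).
#'
#' @param registry list from [build_registry()] (or a subset).
#' @param table fully preprocessed cohort table.
#' @param families character vector of model families.
#' @param config a [split_config()].
#' @param params optional named list `family -> hyperparameters`.
#' @param cv if TRUE also record cross-validated metrics on the training
#'   partition (slower).
#' @return list with `results` (tidy data frame: one row per set x family x
#'   split) and `by_set` (per-set mean and sd of test metrics across
#'   families).
#' @export
benchmark <- function(registry, table, families = MODEL_FAMILIES,
                      config = split_config(), params = NULL, cv = FALSE) {
  rows <- list()
  for (spec in registry) {
    mat <- materialize(table, spec)
    sp <- split_train_test(mat$X, mat$y, config)
    for (fam in families) {
      pp <- params[[fam]]
      model <- fit_model(fam, sp$X_train, sp$y_train, pp,
                         seed = config$seed)
      m_tr <- suppressWarnings(
        metrics(sp$y_train, stats::predict(model, sp$X_train)))
      m_te <- suppressWarnings(
        metrics(sp$y_test, stats::predict(model, sp$X_test)))
      rows[[length(rows) + 1]] <- data.frame(
        feature_set = spec$name, group = spec$group, model_family = fam,
        split = c("train", "test"),
        r2 = c(m_tr["r2"], m_te["r2"]),
        mae = c(m_tr["mae"], m_te["mae"]),
        rmse = c(m_tr["rmse"], m_te["rmse"]),
        row.names = NULL)
      if (cv) {
        m_cv <- cv_metrics(fam, sp$X_train, sp$y_train, pp, config)
        rows[[length(rows) + 1]] <- data.frame(
          feature_set = spec$name, group = spec$group, model_family = fam,
          split = "cv", r2 = m_cv["r2"], mae = m_cv["mae"],
          rmse = m_cv["rmse"], row.names = NULL)
      }
    }
  }
  results <- do.call(rbind, rows)
  test <- results[results$split == "test", ]
  by_set <- do.call(rbind, lapply(split(test, test$feature_set), function(d) {
    data.frame(feature_set = d$feature_set[1], group = d$group[1],
               n_models = nrow(d),
               r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
               mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               row.names = NULL)
  }))
  list(results = results, by_set = by_set)
}

#' Paired comparison of two feature sets across model families
#'
#' Paired t-statistic over the per-family differences of a test metric
#' (the N = number-of-families pairing used when comparing e.g. an
#' environment-only set against one augmented with animal covariates).
#'
#' @param bench_results the `results` data frame from [benchmark()].
#' @param set_a,set_b feature-set names to compare.
#' @param metric one of "r2", "mae", "rmse".
#' @return list with `t`, `df`, `p` (two-sided), `mean_diff` (a - b).
#' @export
paired_set_test <- function(bench_results, set_a, set_b, metric = "r2") {
  te <- bench_results[bench_results$split == "test", ]
  a <- te[te$feature_set == set_a, ]
  b <- te[te$feature_set == set_b, ]
  b <- b[match(a$model_family, b$model_family), ]
  d <- a[[metric]] - b[[metric]]
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Theoretical R^2 ceiling of the synthetic generative model
#'
#' From the truth table's variance decomposition: the deterministic CBT
#' component `CBT_mu` is the best possible prediction, so
#' `r2_max = var(CBT_mu) / var(CBT)` (estimated on the generated rows). No
#' model evaluated on this cohort should exceed it by more than sampling
#' noise; a large excess indicates leakage.
#'
#' @param truth the `truth` table from [gen_cohort()].
#' @return the ceiling estimate (scalar).
#' @export
r2_ceiling <- function(truth) {
  stats::var(truth$CBT_mu) / stats::var(truth$CBT)
}
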