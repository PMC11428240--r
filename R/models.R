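# Uniform model interface over six regression families. Elastic net is
# delegated to glmnet; the neural network is a compact multilayer perceptron
# (Adam, full batch) mirroring the scikit-learn MLPRegressor parameterisation;
# random forest and the three gradient-boosting variants run on the package's
# internal Rcpp tree engine. Each family exposes exactly the hyperparameters
# of its published search space and validates candidate values against it.

MODEL_FAMILIES <- c("EN", "ANN", "RF", "XGBoost", "LightGBM", "CatBoost")

#' Hyperparameter search space of a model family
#'
#' Dimensions are `(name, kind, bounds-or-options)` with kind one of
#' `continuous`, `log-continuous`, `integer`, `categorical`. Multiplicative
#' parameters (learning rates, penalty strengths) use log-continuous
#' decoding.
#'
#' @param family one of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @return list of class `search_space` with element `dims`.
#' @export
hyperparam_space <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  dim_c <- function(name, lo, hi) list(name = name, kind = "continuous",
                                       bounds = c(lo, hi))
  dim_l <- function(name, lo, hi) list(name = name, kind = "log-continuous",
                                       bounds = c(lo, hi))
  dim_i <- function(name, lo, hi) list(name = name, kind = "integer",
                                       bounds = c(lo, hi))
  dim_k <- function(name, opts) list(name = name, kind = "categorical",
                                     options = opts)
  dims <- switch(family,
    EN = list(dim_l("alpha", 1e-4, 10),
              dim_c("l1_ratio", 1e-4, 1.0)),
    ANN = list(dim_i("max_iter", 200, 1000),
               dim_l("learning_rate_init", 0.001, 0.1),
               dim_l("alpha", 1e-4, 10),
               dim_k("activation", c("relu", "tanh")),
               dim_k("hidden_layer_sizes", list(c(100L), c(100L, 50L)))),
    RF = list(dim_i("n_estimators", 100, 1000),
              dim_i("max_depth", 3, 10),
              dim_c("min_samples_split", 0.002, 0.2),
              dim_c("min_samples_leaf", 0.001, 0.1),
              dim_k("max_features", c("sqrt", "log2"))),
    XGBoost = list(dim_i("n_estimators", 100, 1000),
                   dim_l("learning_rate", 0.01, 0.2),
                   dim_c("subsample", 0.1, 1.0),
                   dim_l("reg_alpha", 0.01, 10),
                   dim_l("reg_lambda", 0.01, 10)),
    LightGBM = list(dim_i("num_iteration", 100, 1000),
                    dim_l("learning_rate", 0.01, 0.2),
                    dim_c("bagging_fraction", 0.1, 1.0),
                    dim_l("lambda_l1", 0.01, 10),
                    dim_l("lambda_l2", 0.01, 10)),
    CatBoost = list(dim_i("iterations", 100, 1000),
                    dim_l("learning_rate", 0.01, 0.2),
                    dim_l("l2_leaf_reg", 0.01, 10),
                    dim_c("subsample", 0.1, 1.0),
                    dim_i("depth", 3, 10)))
  make_search_space(dims)
}

#' Construct a search space from a list of dimensions
#'
#' @param dims list of dimension definitions (see [hyperparam_space()]).
#' @return list of class `search_space`.
#' @export
make_search_space <- function(dims) {
  nm <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("dimension names must be unique")
  for (d in dims) {
    if (d$kind %in% c("continuous", "log-continuous", "integer")) {
      if (d$bounds[1] >= d$bounds[2]) {
        stop("bounds must satisfy low < high for '", d$name, "'")
      }
      if (d$kind == "log-continuous" && d$bounds[1] <= 0) {
        stop("log-continuous bounds must be positive for '", d$name, "'")
      }
    } else if (d$kind == "categorical") {
      if (length(d$options) == 0) stop("empty options for '", d$name, "'")
    } else stop("unknown dimension kind: ", d$kind)
  }
  structure(list(dims = dims), class = "search_space")
}

#' Default hyperparameters of a family (midpoint of each range)
#'
#' Numeric ranges use their midpoint (geometric midpoint for log-scaled
#' dimensions, integer-rounded for counts); categorical dimensions use the
#' first listed option.
#'
#' @inheritParams hyperparam_space
#' @return named list of hyperparameter values.
#' @export
default_hyperparams <- function(family) {
  space <- hyperparam_space(family)
  out <- list()
  for (d in space$dims) {
    out[[d$name]] <- switch(d$kind,
      continuous = mean(d$bounds),
      `log-continuous` = exp(mean(log(d$bounds))),
      integer = as.integer(round(mean(d$bounds))),
      categorical = d$options[[1]])
  }
  out
}

#' Validate hyperparameters against a family's search space
#'
#' @inheritParams hyperparam_space
#' @param params named list of candidate values.
#' @return `params`, invisibly; errors name the violated bound.
#' @export
validate_hyperparams <- function(family, params) {
  space <- hyperparam_space(family)
  for (d in space$dims) {
    if (is.null(params[[d$name]])) {
      stop("missing hyperparameter '", d$name, "' for ", family)
    }
    v <- params[[d$name]]
    if (d$kind %in% c("continuous", "log-continuous", "integer")) {
      if (!is.numeric(v) || v < d$bounds[1] || v > d$bounds[2]) {
        stop("hyperparameter '", d$name, "' = ", v, " outside [",
             d$bounds[1], ", ", d$bounds[2], "] for ", family)
      }
    } else {
      hit <- any(vapply(d$options, identical, logical(1),
                        if (is.list(d$options)) v else as.character(v)))
      if (!hit && !is.list(d$options)) hit <- as.character(v) %in% d$options
      if (!hit) {
        ok <- if (is.list(d$options)) {
          paste(vapply(d$options, function(o) paste(o, collapse = ","),
                       character(1)), collapse = " | ")
        } else paste(d$options, collapse = " | ")
        stop("hyperparameter '", d$name, "' not among {", ok, "} for ",
             family)
      }
    }
  }
  invisible(params)
}

#' Fit one regression model family
#'
#' @inheritParams hyperparam_space
#' @param X numeric feature matrix.
#' @param y numeric target vector.
#' @param params hyperparameters (default: [default_hyperparams()]).
#' @param seed integer seed for all stochastic learners.
#' @return fitted model of class `bovitherm_model` (with subclass per
#'   family). Tree-ensemble families carry the tree structure used by
#'   [explain()].
#' @export
fit_model <- function(family, X, y, params = NULL, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(params)) params <- default_hyperparams(family)
  validate_hyperparams(family, params)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)

  fit <- switch(family,
    EN = {
      f <- glmnet::glmnet(X, y, alpha = params$l1_ratio,
                          lambda = params$alpha, standardize = TRUE)
      list(engine = "glmnet", fit = f)
    },
    ANN = {
      hidden <- params$hidden_layer_sizes
      if (is.character(hidden)) {
        hidden <- if (identical(hidden, "100,50")) c(100L, 50L) else
          as.integer(strsplit(hidden, ",")[[1]])
      }
      f <- mlp_fit(X, y, hidden = as.integer(hidden),
                   activation = params$activation,
                   alpha = params$alpha,
                   learning_rate_init = params$learning_rate_init,
                   max_iter = as.integer(params$max_iter), seed = seed)
      list(engine = "mlp", fit = f)
    },
    RF = {
      k <- switch(params$max_features,
                  sqrt = max(1L, floor(sqrt(ncol(X)))),
                  log2 = max(1L, floor(log2(ncol(X)))))
      f <- cpp_fit_forest(X, y, "rf",
                          n_trees = as.integer(params$n_estimators),
                          learning_rate = 1,
                          max_depth = as.integer(params$max_depth),
                          min_split = max(2L, ceiling(
                            params$min_samples_split * n)),
                          min_leaf = max(1L, ceiling(
                            params$min_samples_leaf * n)),
                          subsample = 1, k_features = k,
                          reg_alpha = 0, reg_lambda = 0, seed = seed)
      list(engine = "tree", fit = f)
    },
    XGBoost = {
      f <- cpp_fit_forest(X, y, "gbt",
                          n_trees = as.integer(params$n_estimators),
                          learning_rate = params$learning_rate,
                          max_depth = 6L, min_split = 2L, min_leaf = 1L,
                          subsample = params$subsample, k_features = 0L,
                          reg_alpha = params$reg_alpha,
                          reg_lambda = params$reg_lambda, seed = seed)
      list(engine = "tree", fit = f)
    },
    LightGBM = {
      f <- cpp_fit_forest(X, y, "gbt",
                          n_trees = as.integer(params$num_iteration),
                          learning_rate = params$learning_rate,
                          max_depth = 6L, min_split = 2L, min_leaf = 20L,
                          subsample = params$bagging_fraction,
                          k_features = 0L,
                          reg_alpha = params$lambda_l1,
                          reg_lambda = params$lambda_l2, seed = seed)
      list(engine = "tree", fit = f)
    },
    CatBoost = {
      f <- cpp_fit_forest(X, y, "gbt",
                          n_trees = as.integer(params$iterations),
                          learning_rate = params$learning_rate,
                          max_depth = as.integer(params$depth),
                          min_split = 2L, min_leaf = 1L,
                          subsample = params$subsample, k_features = 0L,
                          reg_alpha = 0,
                          reg_lambda = params$l2_leaf_reg, seed = seed)
      list(engine = "tree", fit = f)
    })

  structure(list(family = family, params = params, engine = fit$engine,
                 fit = fit$fit, feature_names = colnames(X), seed = seed),
            class = c(paste0("bovitherm_", fit$engine), "bovitherm_model"))
}

#' Predict from a fitted bovitherm model
#'
#' @param object a model from [fit_model()].
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.bovitherm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  switch(object$engine,
    glmnet = as.numeric(glmnet::predict.glmnet(
      object$fit, newx = newdata, s = object$params$alpha)),
    mlp = mlp_predict(object$fit, newdata),
    tree = as.numeric(cpp_predict_forest(object$fit, newdata)))
}

#' @export
print.bovitherm_model <- function(x, ...) {
  cat("bovitherm model:", x$family, "(engine:", x$engine, ")\n")
  invisible(x)
}

is_tree_model <- function(model) {
  inherits(model, "bovitherm_model") && identical(model$engine, "tree")
}

# ----------------------- multilayer perceptron -----------------------------
# Compact MLP regressor: full-batch Adam on squared loss with L2 penalty
# `alpha`, matching the scikit-learn MLPRegressor parameter names used in
# the search space. Inputs and target are standardized internally.

mlp_fit <- function(X, y, hidden = c(100L), activation = "relu",
                    alpha = 1e-4, learning_rate_init = 1e-3,
                    max_iter = 200L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0 | !is.finite(xs)] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yc <- (y - ym) / ys

  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))  # Glorot uniform
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  dact <- if (activation == "relu") function(a) (a > 0) * 1 else
    function(a) 1 - a^2

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  n <- nrow(Xs)

  for (it in seq_len(max_iter)) {
    A <- vector("list", L + 1L)
    A[[1]] <- Xs
    for (l in seq_len(L)) {
      Z <- A[[l]] %*% W[[l]] + matrix(b[[l]], n, sizes[l + 1], byrow = TRUE)
      A[[l + 1]] <- if (l < L) act(Z) else Z
    }
    delta <- (A[[L + 1]] - yc) / n           # dLoss/dZ_L for 0.5*MSE
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta) + alpha * W[[l]] / n
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * dact(A[[l]])
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      W[[l]] <- W[[l]] - learning_rate_init * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + epsl)
      b[[l]] <- b[[l]] - learning_rate_init * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + epsl)
    }
  }
  list(W = W, b = b, activation = activation, xm = xm, xs = xs,
       ym = ym, ys = ys, sizes = sizes)
}

mlp_predict <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$xm), 2, fit$xs, "/")
  A <- Xs
  L <- length(fit$W)
  act <- if (fit$activation == "relu") function(z) pmax(z, 0) else tanh
  for (l in seq_len(L)) {
    Z <- A %*% fit$W[[l]] +
      matrix(fit$b[[l]], nrow(A), length(fit$b[[l]]), byrow = TRUE)
    A <- if (l < L) act(Z) else Z
  }
  as.numeric(A) * fit$ys + fit$ym
}
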