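# Grey wolf optimizer over a unit hypercube, with mixed-type decoding onto
# hyperparameter search spaces, and the tuning front-end that couples it to
# cross-validated model fitness. Alternative optimizers can be plugged in via
# the minimize(objective, space, config) signature.

#' Decode a unit-hypercube position into hyperparameter values
#'
#' Per dimension kind: continuous `low + p (high - low)`; log-continuous
#' `exp(log low + p (log high - log low))`; integer
#' `floor(low + p (high - low))` clamped to the bounds; categorical index
#' `min(floor(p k), k - 1)` (0-based) into the option list.
#'
#' @param position numeric vector in `[0, 1]^d` (coordinates are clamped to
#'   `[0, 1]`; values beyond a small tolerance outside are rejected).
#' @param space a `search_space` (e.g. [hyperparam_space()]).
#' @return named list of decoded values.
#' @export
#' @examples
#' decode(c(0.5), make_search_space(list(
#'   list(name = "n", kind = "integer", bounds = c(100, 1000)))))  # 550
decode <- function(position, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(position) != length(space$dims)) {
    stop("position length must equal the number of dimensions")
  }
  if (any(position < -1e-9) || any(position > 1 + 1e-9)) {
    stop("position coordinates must lie in [0, 1]")
  }
  position <- pmin(1, pmax(0, position))
  out <- list()
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    p <- position[i]
    out[[d$name]] <- switch(d$kind,
      continuous = min(max(d$bounds[1] + p * (d$bounds[2] - d$bounds[1]),
                           d$bounds[1]), d$bounds[2]),
      `log-continuous` = if (p <= 0) d$bounds[1] else if (p >= 1)
        d$bounds[2] else min(max(
          exp(log(d$bounds[1]) + p * (log(d$bounds[2]) - log(d$bounds[1]))),
          d$bounds[1]), d$bounds[2]),
      integer = {
        v <- floor(d$bounds[1] + p * (d$bounds[2] - d$bounds[1]))
        as.integer(min(max(v, d$bounds[1]), d$bounds[2]))
      },
      categorical = {
        k <- length(d$options)
        d$options[[min(floor(p * k), k - 1) + 1]]
      })
  }
  out
}

#' Grey wolf optimizer configuration
#'
#' @param population pack size (>= 4: alpha, beta, delta plus followers).
#' @param epochs number of iterations; the exploration coefficient `a`
#'   decays linearly from 2 to 0 over them.
#' @param seed integer seed (one generator drives all draws).
#' @param warm_start optional position in `[0,1]^d` injected as the first
#'   wolf (e.g. the default-midpoint candidate, guaranteeing the search
#'   never returns anything worse than the baseline on the same objective).
#' @return list of class `gwo_config`.
#' @export
gwo_config <- function(population = 30, epochs = 200, seed = 1L,
                       warm_start = NULL) {
  if (population < 4) stop("population must be >= 4")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(population = as.integer(population),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 warm_start = warm_start), class = "gwo_config")
}

#' Minimize an objective with the grey wolf optimizer
#'
#' Canonical update: the three best wolves (alpha, beta, delta) guide the
#' pack. For wolf X and leader L, a leader-guided position is
#' `X_i = L - A_i |C_i L - X|` with `A = 2 a r1 - a`, `C = 2 r2`,
#' `r1, r2 ~ U(0,1)` i.i.d. per wolf, per dimension, per leader; the new
#' position is the mean of the three guided positions, clipped to `[0,1]`.
#' The coefficient `a` decays linearly from 2 to 0 over the epochs
#' (encircling -> attacking). Non-finite objective values are treated as
#' `+Inf` and logged.
#'
#' @param objective function taking a decoded candidate (named list) and
#'   returning a finite scalar fitness (lower is better).
#' @param space a `search_space`.
#' @param config a [gwo_config()].
#' @return list with `best` (list: `position`, `decoded`, `fitness`),
#'   `curve` (best-ever fitness per epoch, non-increasing) and
#'   `n_evaluations`.
#' @export
gwo_minimize <- function(objective, space, config = gwo_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "gwo_config"))
  d <- length(space$dims)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  evaluate <- function(pos) {
    f <- objective(decode(pos, space))
    if (!is.finite(f)) {
      warning("objective returned non-finite fitness; treated as +Inf")
      f <- Inf
    }
    f
  }

  pos <- matrix(stats::runif(config$population * d), config$population, d)
  if (!is.null(config$warm_start)) {
    if (length(config$warm_start) != d) {
      stop("warm_start length must equal the number of dimensions")
    }
    pos[1, ] <- pmin(1, pmax(0, config$warm_start))
  }
  fit <- apply(pos, 1, evaluate)
  n_eval <- config$population

  best_pos <- pos[which.min(fit), ]
  best_fit <- min(fit)
  curve <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    a <- 2 - 2 * (epoch - 1) / max(1, config$epochs - 1)
    ord <- order(fit)
    leaders <- pos[ord[1:3], , drop = FALSE]
    for (w in seq_len(config$population)) {
      guided <- matrix(0, 3, d)
      for (l in 1:3) {
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
        A <- 2 * a * r1 - a
        C <- 2 * r2
        D <- abs(C * leaders[l, ] - pos[w, ])
        guided[l, ] <- leaders[l, ] - A * D
      }
      pos[w, ] <- pmin(1, pmax(0, colMeans(guided)))
      fit[w] <- evaluate(pos[w, ])
      n_eval <- n_eval + 1
      if (fit[w] < best_fit) {
        best_fit <- fit[w]
        best_pos <- pos[w, ]
      }
    }
    curve[epoch] <- best_fit
  }
  list(best = list(position = best_pos,
                   decoded = decode(best_pos, space),
                   fitness = best_fit),
       curve = curve, n_evaluations = n_eval)
}

#' Tune a model family's hyperparameters on a feature set
#'
#' Fitness is the mean `n_folds`-fold cross-validated RMSE on the training
#' partition (the test partition is never touched). The first wolf is warm
#' started at the default-midpoint candidate, so the tuned cross-validated
#' RMSE can never exceed the default's on the same folds. Any
#' `minimize(objective, space, config)` implementation with the
#' [gwo_minimize()] signature can be substituted via `optimizer`.
#'
#' @inheritParams fit_model
#' @param split a [split_config()]; controls the train/test split and folds.
#' @param gwo a [gwo_config()] (budget `population x epochs` objective
#'   evaluations, each a full cross-validation).
#' @param optimizer optimizer function; defaults to [gwo_minimize()].
#' @return list with `best_params`, `cv_rmse` (achieved fitness),
#'   `default_cv_rmse` (midpoint baseline on the same folds), `curve`,
#'   `model` (best candidate refit on the full training partition),
#'   `split` (the realized partition) and `test_metrics`.
#' @export
tune <- function(family, X, y, split = split_config(),
                 gwo = gwo_config(), optimizer = gwo_minimize) {
  space <- hyperparam_space(family)
  sp <- split_train_test(X, y, split)
  objective <- function(params) {
    unname(cv_metrics(family, sp$X_train, sp$y_train, params,
                      config = split)["rmse"])
  }
  if (is.null(gwo$warm_start)) {
    # midpoint candidate; categorical coordinates at 0 so the decoded warm
    # start equals default_hyperparams() (first-listed option) exactly
    kinds <- vapply(space$dims, `[[`, character(1), "kind")
    gwo$warm_start <- ifelse(kinds == "categorical", 0, 0.5)
  }
  run <- optimizer(objective, space, gwo)
  default_rmse <- objective(default_hyperparams(family))
  model <- fit_model(family, sp$X_train, sp$y_train, run$best$decoded,
                     seed = split$seed)
  test_m <- suppressWarnings(
    metrics(sp$y_test, stats::predict(model, sp$X_test)))
  list(family = family, best_params = run$best$decoded,
       cv_rmse = run$best$fitness, default_cv_rmse = default_rmse,
       curve = run$curve, model = model, split = sp,
       test_metrics = test_m, n_evaluations = run$n_evaluations)
}
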