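# TreeSHAP explanations for the internal tree-ensemble models, plus the data
# products behind summary, dependence and waterfall plots. A brute-force
# Shapley enumerator over the same tree value function is provided as an
# independent oracle for small trees.

#' SHAP attributions for a fitted tree-ensemble model
#'
#' Computes per-row, per-feature additive attributions with the
#' polynomial-time path-dependent TreeSHAP algorithm: feature perturbations
#' are propagated through the tree using the training cover of each node (the
#' tree-path-dependent conditioning convention, recorded in the result).
#' Local accuracy holds: for every row,
#' `base_value + sum(attributions) = prediction` to numerical precision.
#'
#' @param model a tree-backed model from [fit_model()] (families RF,
#'   XGBoost, LightGBM, CatBoost). Other engines are rejected.
#' @param X fully numeric matrix of rows to explain (typically the training
#'   partition).
#' @return object of class `shap_matrix`: list with `values` (n x p matrix),
#'   `base_value` (expected model output over the trees' training covers),
#'   `feature_values` (X), `feature_names`, `perturbation`
#'   (`"tree_path_dependent"`).
#' @export
explain <- function(model, X) {
  if (!is_tree_model(model)) {
    stop("SHAP explanations require a tree-ensemble model ",
         "(RF, XGBoost, LightGBM or CatBoost); got engine '",
         model$engine, "'")
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  phi <- cpp_tree_shap(model$fit, X)
  nms <- model$feature_names
  if (is.null(nms)) nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  colnames(phi) <- nms
  structure(list(values = phi,
                 base_value = cpp_expected_value(model$fit),
                 feature_values = X,
                 feature_names = nms,
                 perturbation = "tree_path_dependent"),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("SHAP matrix:", nrow(x$values), "rows x", ncol(x$values),
      "features; base value", format(x$base_value, digits = 6), "\n")
  invisible(x)
}

#' Global feature importance: mean absolute SHAP value per feature
#'
#' @param shap a `shap_matrix` from [explain()].
#' @return data frame (`feature`, `mean_abs_shap`) in descending order of
#'   importance; ties broken lexicographically by feature name.
#' @export
summary_stats <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  imp <- colMeans(abs(shap$values))
  ord <- order(-imp, names(imp), method = "radix")
  data.frame(feature = names(imp)[ord], mean_abs_shap = unname(imp[ord]),
             row.names = NULL)
}

#' Data behind a SHAP dependence plot
#'
#' One triple per row: the feature's value (x), its attribution (y), and the
#' interaction feature's value (color). No aggregation is applied.
#'
#' @param shap a `shap_matrix`.
#' @param feature feature whose attribution is plotted.
#' @param interaction_feature feature whose value colors the points
#'   (defaults to `feature` itself).
#' @return data frame with columns `x`, `attribution`, `color`.
#' @export
dependence_data <- function(shap, feature, interaction_feature = feature) {
  stopifnot(inherits(shap, "shap_matrix"))
  for (f in unique(c(feature, interaction_feature))) {
    if (!f %in% shap$feature_names) stop("unknown feature: ", f)
  }
  data.frame(x = shap$feature_values[, feature],
             attribution = shap$values[, feature],
             color = shap$feature_values[, interaction_feature])
}

#' Data behind a SHAP waterfall plot for one row
#'
#' Features ordered by decreasing absolute attribution for that row; the
#' cumulative sum starting from the base value ends at the model prediction.
#'
#' @param shap a `shap_matrix`.
#' @param row_index row to explain (1-based).
#' @return list with `base_value`, `prediction`, and `steps` (data frame:
#'   `feature`, `feature_value`, `attribution`, `cumulative`).
#' @export
waterfall_data <- function(shap, row_index) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (row_index < 1 || row_index > nrow(shap$values)) {
    stop("row_index out of range")
  }
  v <- shap$values[row_index, ]
  ord <- order(-abs(v), names(v), method = "radix")
  steps <- data.frame(feature = names(v)[ord],
                      feature_value = shap$feature_values[row_index, ord],
                      attribution = unname(v[ord]),
                      row.names = NULL)
  steps$cumulative <- shap$base_value + cumsum(steps$attribution)
  list(base_value = shap$base_value,
       prediction = shap$base_value + sum(v),
       steps = steps)
}

#' Brute-force Shapley values over the tree value function (test oracle)
#'
#' Enumerates all feature subsets S and computes
#' `phi_i = sum_S |S|! (|F|-|S|-1)! / |F|! (v(S + i) - v(S))` with the
#' tree-path-dependent value function: features in S follow the row,
#' features outside S are marginalized by node cover. Exponential in the
#' number of features; intended as an independent oracle for models with at
#' most a handful of features.
#'
#' @param model a tree-backed model from [fit_model()].
#' @param x a single numeric row (vector).
#' @return numeric vector of Shapley values, one per feature.
#' @export
shap_brute_force <- function(model, x) {
  if (!is_tree_model(model)) stop("tree-ensemble model required")
  trees <- model$fit$trees
  p <- model$fit$n_features
  if (p > 12) stop("brute force is exponential; use explain() instead")

  expvalue <- function(tree, node, S) {
    f <- tree$feature[node + 1]
    if (f < 0) return(tree$value[node + 1])
    l <- tree$left[node + 1]; r <- tree$right[node + 1]
    if ((f + 1) %in% S) {
      nxt <- if (x[f + 1] <= tree$threshold[node + 1]) l else r
      return(expvalue(tree, nxt, S))
    }
    (tree$cover[l + 1] * expvalue(tree, l, S) +
       tree$cover[r + 1] * expvalue(tree, r, S)) /
      (tree$cover[l + 1] + tree$cover[r + 1])
  }
  v <- function(S) {
    sum(vapply(trees, function(tr) expvalue(tr, 0, S), numeric(1)))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  vals <- vapply(subsets, v, numeric(1))
  key <- vapply(subsets, function(s) sum(2^(s - 1)), numeric(1))
  lookup <- function(S) vals[match(sum(2^(S - 1)), key)]
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (m in 0:(2^(p - 1) - 1)) {
      S <- others[which(bitwAnd(m, 2^(seq_len(p - 1) - 1)) > 0)]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (lookup(c(S, i)) - lookup(S))
    }
  }
  phi
}
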