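# Preprocessing protocol: categorical encoding, median imputation of missing
# cells, and z-score outlier capping. Order is fixed (encode -> impute ->
# cap) and the target column is never altered.

#' Encode the two categorical survey variables
#'
#' Time zone: `A.M.` -> 0, `P.M.` -> 1. Body posture: `standing` -> 0,
#' `lying down` -> 1. Matching is case-insensitive after trimming. Columns
#' already numeric 0/1 pass through unchanged, so encoding is idempotent.
#'
#' @param table cohort data frame with columns `TZ` and `BP`.
#' @return list with elements `table` (encoded) and `encoding_maps` (named
#'   list of category -> integer maps).
#' @export
encode_categoricals <- function(table) {
  maps <- list(TZ = c("A.M." = 0L, "P.M." = 1L),
               BP = c("standing" = 0L, "lying down" = 1L))
  for (col in names(maps)) {
    if (!col %in% names(table)) next
    x <- table[[col]]
    if (is.numeric(x)) {
      if (!all(x %in% c(0, 1) | is.na(x))) {
        stop("column ", col, " is numeric but not 0/1 coded")
      }
      next
    }
    key <- tolower(trimws(as.character(x)))
    lut <- stats::setNames(unname(maps[[col]]), tolower(names(maps[[col]])))
    bad <- !is.na(key) & !(key %in% names(lut))
    if (any(bad)) {
      stop("unseen category in ", col, ": '",
           x[which(bad)[1]], "'")
    }
    table[[col]] <- unname(lut[key])
  }
  list(table = table, encoding_maps = maps)
}

#' Median imputation of missing numeric cells
#'
#' Every missing cell in the listed columns is replaced by that column's
#' median over non-missing values. The target column `CBT` is refused.
#'
#' @param table data frame.
#' @param columns character vector of column names to impute.
#' @return list with `table` (imputed), `n_imputed` (named counts) and
#'   `medians` (named medians used).
#' @export
impute_median <- function(table, columns) {
  if ("CBT" %in% columns) stop("the target column CBT is never imputed")
  columns <- intersect(columns, names(table))
  n_imp <- stats::setNames(integer(length(columns)), columns)
  meds <- stats::setNames(numeric(length(columns)), columns)
  for (col in columns) {
    x <- table[[col]]
    isna <- is.na(x)
    if (all(isna)) stop("column ", col, " is entirely missing; ",
                        "median undefined")
    med <- stats::median(x[!isna])
    x[isna] <- med
    table[[col]] <- x
    n_imp[col] <- sum(isna)
    meds[col] <- med
  }
  list(table = table, n_imputed = n_imp, medians = meds)
}

#' Z-score outlier capping
#'
#' Per column, z = (x - mean) / sd with population sd (divide by n) computed
#' once from the pre-replacement data. Cells with z above `threshold` are
#' replaced by mean + threshold * sd; cells below `-threshold` by
#' mean - threshold * sd (sign-aware capping). Statistics are not recomputed
#' between replacements. Zero-variance columns are skipped (no cell can be an
#' outlier). Missing cells are not allowed: impute first.
#'
#' @param table data frame with no missing cells in `columns`.
#' @param columns columns to treat (the target `CBT` is refused).
#' @param threshold z-score threshold (default 3).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return list with `table`, `n_capped` (named counts), `means`, `sds`.
#' @export
cap_outliers_zscore <- function(table, columns, threshold = 3,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if ("CBT" %in% columns) stop("the target column CBT is never capped")
  columns <- intersect(columns, names(table))
  n_cap <- stats::setNames(integer(length(columns)), columns)
  mns <- stats::setNames(numeric(length(columns)), columns)
  sds <- stats::setNames(numeric(length(columns)), columns)
  for (col in columns) {
    x <- table[[col]]
    if (anyNA(x)) stop("column ", col, " has missing cells; impute first")
    m <- mean(x)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    mns[col] <- m
    sds[col] <- s
    if (!is.finite(s) || s == 0) next  # z undefined: nothing flagged
    z <- (x - m) / s
    hi <- z > threshold
    lo <- z < -threshold
    x[hi] <- m + threshold * s
    x[lo] <- m - threshold * s
    table[[col]] <- x
    n_cap[col] <- sum(hi) + sum(lo)
  }
  list(table = table, n_capped = n_cap, means = mns, sds = sds)
}

#' Full preprocessing pipeline for a cohort table
#'
#' Applies, in order: categorical encoding (TZ, BP), median imputation of
#' all numeric predictor columns, and z-score outlier capping of the
#' continuous predictors. The target `CBT` and the encoded categoricals are
#' excluded from imputation targets that do not need it and from capping.
#'
#' @param table raw cohort data frame (e.g. `gen_cohort()$data`).
#' @param impute_columns columns to impute; default: all numeric predictor
#'   columns except `CBT`, `day`, `hour`.
#' @param cap_columns columns to z-cap; default: continuous predictors
#'   (environment, MY, DOL, infrared), excluding `CBT` and the 0/1 and count
#'   categoricals.
#' @param threshold z threshold for capping.
#' @return list of class `preprocess_result` with `table` (processed) and
#'   `report` (class `preprocess_report`: counts, statistics, encoding maps).
#' @export
preprocess_cohort <- function(table, impute_columns = NULL,
                              cap_columns = NULL, threshold = 3) {
  enc <- encode_categoricals(table)
  tab <- enc$table
  irt_cols <- grep("^IRT(ave|max)_", names(tab), value = TRUE)
  if (is.null(impute_columns)) {
    num <- names(tab)[vapply(tab, is.numeric, logical(1))]
    impute_columns <- setdiff(num, c("CBT", "day", "hour", "TZ", "BP"))
  }
  if (is.null(cap_columns)) {
    cap_columns <- intersect(c("Ta", "Tbg", "RH", "U", "Qsr", "MY", "DOL",
                               irt_cols), names(tab))
  }
  imp <- impute_median(tab, impute_columns)
  cap <- cap_outliers_zscore(imp$table, cap_columns, threshold = threshold)
  report <- structure(list(
    n_imputed_per_column = imp$n_imputed,
    n_outliers_capped_per_column = cap$n_capped,
    column_medians = imp$medians,
    column_means = cap$means,
    column_stds = cap$sds,
    encoding_maps = enc$encoding_maps,
    threshold = threshold), class = "preprocess_report")
  structure(list(table = cap$table, report = report),
            class = "preprocess_result")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocess report:",
      sum(x$n_imputed_per_column), "cells imputed;",
      sum(x$n_outliers_capped_per_column), "outliers capped (|z| >",
      x$threshold, ")\n")
  invisible(x)
}

#' Serialize a preprocess report as JSON
#'
#' @param report a `preprocess_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
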