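# Benchmark feature sets. Five groups: environment-only (ENV), environment
# plus animal covariates (ANM), one set per infrared region for IRTmax and
# IRTave, one set per thermal-comfort index, one set per heat-flux variable.
# All non-ENV sets carry the animal covariates (MY, DOL, PA, BP) and the
# sampling block TZ.

INDEX_LIST <- c("THI", "BGHI", "ATHI", "CCI", "DHLI", "ETIC", "STIC")
FLUX_LIST <- c("Qresp", "Qevap", "Qconv", "Qrad", "Qlat", "Qsens")
ANIMAL_VARS <- c("MY", "DOL", "PA", "BP")

#' Build the registry of benchmark feature sets
#'
#' Templates:
#' \itemize{
#'   \item `ENV` = Ta, Tbg, RH, U, Qsr, TZ
#'   \item `ANM` = ENV plus MY, DOL, PA, BP
#'   \item one set per region `r`: `IRTmax_r` (and `IRTave_r`) =
#'     that infrared column plus MY, DOL, PA, BP, TZ
#'   \item one set per index / per flux variable, same template.
#' }
#' Registry size is `2 + 2 |roi| + |index| + |flux|` (33 with defaults).
#'
#' @param roi_list infrared regions (default the 9 regions of [ROI_LIST]).
#' @param index_list thermal-comfort indices (default all 7).
#' @param flux_list heat-flux variables (default all 6).
#' @param target target column name.
#' @return named list of `feature_set_spec` objects, each with fields
#'   `name`, `group`, `columns`, `target`.
#' @export
#' @examples
#' length(build_registry())  # 33
build_registry <- function(roi_list = ROI_LIST,
                           index_list = INDEX_LIST,
                           flux_list = FLUX_LIST,
                           target = "CBT") {
  if (!all(roi_list %in% ROI_LIST)) {
    stop("unknown region: ",
         paste(setdiff(roi_list, ROI_LIST), collapse = ", "))
  }
  if (!all(index_list %in% INDEX_LIST)) {
    stop("unknown index: ",
         paste(setdiff(index_list, INDEX_LIST), collapse = ", "))
  }
  if (!all(flux_list %in% FLUX_LIST)) {
    stop("unknown flux variable: ",
         paste(setdiff(flux_list, FLUX_LIST), collapse = ", "))
  }
  spec <- function(name, group, columns) {
    structure(list(name = name, group = group, columns = columns,
                   target = target), class = "feature_set_spec")
  }
  env_cols <- c("Ta", "Tbg", "RH", "U", "Qsr", "TZ")
  satellite <- function(key) c(key, ANIMAL_VARS, "TZ")
  out <- list(
    ENV = spec("ENV", "environment", env_cols),
    ANM = spec("ANM", "environment", c(env_cols, ANIMAL_VARS)))
  for (r in roi_list) {
    nm <- paste0("IRTmax_", r)
    out[[nm]] <- spec(nm, "irtmax", satellite(nm))
  }
  for (r in roi_list) {
    nm <- paste0("IRTave_", r)
    out[[nm]] <- spec(nm, "irtave", satellite(nm))
  }
  for (ix in index_list) out[[ix]] <- spec(ix, "index", satellite(ix))
  for (fl in flux_list) out[[fl]] <- spec(fl, "flux", satellite(fl))
  out
}

#' Materialize a feature set from a processed table
#'
#' @param table fully preprocessed data frame (encoded, imputed, capped; no
#'   missing cells in the spec's columns).
#' @param spec a `feature_set_spec` from [build_registry()].
#' @return list with `X` (numeric matrix, columns in spec order) and `y`
#'   (target vector).
#' @export
materialize <- function(table, spec) {
  stopifnot(inherits(spec, "feature_set_spec"))
  miss <- setdiff(c(spec$columns, spec$target), names(table))
  if (length(miss)) stop("table lacks columns: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(table[, spec$columns, drop = FALSE])
  storage.mode(X) <- "double"
  y <- table[[spec$target]]
  if (anyNA(X) || anyNA(y)) {
    stop("residual missing cells in feature set '", spec$name,
         "'; preprocess first")
  }
  list(X = X, y = as.numeric(y))
}

#' Serialize a feature-set registry as JSON
#' @param registry list from [build_registry()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(lapply(registry, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
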