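# End-to-end orchestration: generate -> preprocess -> features -> benchmark
# -> tune -> explain, with a single user-facing seed fanned out to per-stage
# seeds, JSON config, and a manifest of outputs.

#' Run configuration for the end-to-end pipeline
#'
#' @param seed single global seed; per-stage seeds are derived from it (see
#'   [stage_seed()]).
#' @param generator a [generator_config()]; its seed is overridden by the
#'   derived generate-stage seed.
#' @param groups feature-set groups to benchmark (subset of `environment`,
#'   `irtmax`, `irtave`, `index`, `flux`).
#' @param families model families to benchmark.
#' @param tune_family family to tune with the grey wolf optimizer (a
#'   tree-ensemble family; `NULL` skips tuning and SHAP).
#' @param tune_set feature set on which to tune and explain.
#' @param split a [split_config()] (seed overridden by the derived seed).
#' @param gwo a [gwo_config()] (seed overridden); reduce `population` /
#'   `epochs` for quick runs.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 42L,
                       generator = generator_config(),
                       groups = c("environment", "irtmax", "irtave",
                                  "index", "flux"),
                       families = MODEL_FAMILIES,
                       tune_family = "XGBoost",
                       tune_set = "IRTave_TK",
                       split = split_config(),
                       gwo = gwo_config(),
                       out_dir = tempfile("bovitherm_run_")) {
  structure(list(seed = as.integer(seed), generator = generator,
                 groups = groups, families = families,
                 tune_family = tune_family, tune_set = tune_set,
                 split = split, gwo = gwo, out_dir = out_dir),
            class = "run_config")
}

#' Derive a per-stage seed from the global seed
#'
#' `stage_seed = (global * 7919 + sum of the stage name's character codes)
#' mod (2^31 - 1)`, so stages draw from isolated streams while one
#' user-facing seed controls the run.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

#' Run the full pipeline
#'
#' Stages: (1) generate the synthetic cohort; (2) preprocess (encode,
#' impute, cap); (3) append thermal indices and heat fluxes; (4) benchmark
#' the selected families over the selected feature-set groups; (5) tune one
#' tree-ensemble family with the grey wolf optimizer on one feature set;
#' (6) explain the tuned model with TreeSHAP. All outputs are written under
#' `config$out_dir` as CSV/JSON plus a manifest; the same objects are
#' returned invisibly. A stage failure aborts with the stage name after
#' persisting the manifest of completed stages.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `cohort`, `processed`, `registry`,
#'   `bench`, `tuned`, `shap`, `shap_summary`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("bovitherm")),
                   stages = list())
  persist_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      persist_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seed = stage_seed(config$seed, name))
    res
  }

  # generate
  gen_cfg <- config$generator
  gen_cfg$seed <- stage_seed(config$seed, "generate")
  cohort <- stage("generate", {
    co <- gen_cohort(gen_cfg)
    write_cohort(co, file.path(config$out_dir, "cohort"))
    co
  })

  # preprocess
  processed <- stage("preprocess", {
    pr <- preprocess_cohort(cohort$data)
    utils::write.csv(pr$table,
                     file.path(config$out_dir, "processed.csv"),
                     row.names = FALSE)
    write_preprocess_report(pr$report,
                            file.path(config$out_dir,
                                      "preprocess_report.json"))
    pr
  })

  # features
  featured <- stage("features", {
    ft <- add_thermal_features(processed$table)
    utils::write.csv(ft, file.path(config$out_dir, "featured.csv"),
                     row.names = FALSE)
    ft
  })

  registry <- build_registry()
  registry <- registry[vapply(registry, function(s)
    s$group %in% config$groups, logical(1))]
  write_registry(registry, file.path(config$out_dir, "registry.json"))

  split_cfg <- config$split
  split_cfg$seed <- stage_seed(config$seed, "bench")
  bench_res <- stage("bench", {
    b <- benchmark(registry, featured, config$families, split_cfg)
    utils::write.csv(b$results,
                     file.path(config$out_dir, "eval_results.csv"),
                     row.names = FALSE)
    utils::write.csv(b$by_set,
                     file.path(config$out_dir, "eval_by_set.csv"),
                     row.names = FALSE)
    b
  })

  tuned <- NULL
  shap <- NULL
  shap_summary <- NULL
  if (!is.null(config$tune_family) &&
      config$tune_set %in% names(registry)) {
    gwo_cfg <- config$gwo
    gwo_cfg$seed <- stage_seed(config$seed, "tune")
    tuned <- stage("tune", {
      mat <- materialize(featured, registry[[config$tune_set]])
      tn <- tune(config$tune_family, mat$X, mat$y, split = split_cfg,
                 gwo = gwo_cfg)
      jsonlite::write_json(
        list(family = tn$family, feature_set = config$tune_set,
             best_params = tn$best_params, cv_rmse = tn$cv_rmse,
             default_cv_rmse = tn$default_cv_rmse,
             test_metrics = as.list(tn$test_metrics),
             curve = tn$curve, seed = gwo_cfg$seed),
        file.path(config$out_dir, "tuned_model.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      tn
    })

    shap <- stage("explain", {
      sh <- explain(tuned$model, tuned$split$X_train)
      utils::write.csv(as.data.frame(sh$values),
                       file.path(config$out_dir, "shap_values.csv"),
                       row.names = FALSE)
      sh
    })
    shap_summary <- summary_stats(shap)
    utils::write.csv(shap_summary,
                     file.path(config$out_dir, "shap_summary.csv"),
                     row.names = FALSE)
  }

  persist_manifest()
  invisible(list(cohort = cohort, processed = processed,
                 featured = featured, registry = registry,
                 bench = bench_res, tuned = tuned, shap = shap,
                 shap_summary = shap_summary, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `generate`, `all` (full pipeline). Options: `--seed`,
#' `--out`, `--quick` (reduced optimizer budget and fewer feature groups).
#' Usable via `Rscript -e 'bovitherm::bovitherm_cli()' generate --seed 1
#' --out dir`.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly (0 on success).
#' @export
bovitherm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: bovitherm_cli <generate|all> [--seed N] [--out DIR]",
            " [--quick]")
    return(invisible(1L))
  }
  cmd <- args[1]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  seed <- as.integer(getopt("--seed", "42"))
  out <- getopt("--out", file.path(tempdir(), "bovitherm_run"))
  quick <- "--quick" %in% args

  status <- 0L
  if (cmd == "generate") {
    co <- gen_cohort(generator_config(seed = seed))
    write_cohort(co, out)
    message("cohort written to ", out, " (", nrow(co$data), " rows)")
  } else if (cmd == "all") {
    cfg <- run_config(seed = seed, out_dir = out)
    if (quick) {
      cfg$groups <- c("environment", "irtave")
      cfg$gwo <- gwo_config(population = 5, epochs = 3)
      cfg$families <- c("EN", "XGBoost")
    }
    run_pipeline(cfg)
    message("pipeline outputs written to ", out)
  } else {
    message("unknown subcommand: ", cmd)
    status <- 1L
  }
  invisible(status)
}
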