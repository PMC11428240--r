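# Encoding, imputation, z-score capping, and the composed pipeline.

test_that("categorical encoding matches the survey convention", {
  tab <- data.frame(TZ = c("A.M.", "P.M.", " a.m. "),
                    BP = c("standing", "lying down", "LYING DOWN"))
  enc <- encode_categoricals(tab)
  expect_identical(enc$table$TZ, c(0L, 1L, 0L))
  expect_identical(enc$table$BP, c(0L, 1L, 1L))
  expect_identical(enc$encoding_maps$TZ, c("A.M." = 0L, "P.M." = 1L))
  expect_identical(enc$encoding_maps$BP,
                   c("standing" = 0L, "lying down" = 1L))
  expect_error(encode_categoricals(data.frame(TZ = "evening", BP = "standing")),
               "evening")
  # idempotent on an already-encoded table
  expect_identical(encode_categoricals(enc$table)$table, enc$table)
})

test_that("median imputation replaces only missing cells", {
  tab <- data.frame(a = c(1, 2, NA, 4), b = c(5, 6, 7, 8))
  out <- impute_median(tab, c("a", "b"))
  expect_identical(out$table$a, c(1, 2, 2, 4))      # median of {1,2,4} = 2
  expect_identical(out$table$b, tab$b)
  expect_identical(out$n_imputed, c(a = 1L, b = 0L))
  expect_identical(out$medians[["a"]], 2)
  # imputation preserves the column median
  expect_identical(median(out$table$a), median(tab$a, na.rm = TRUE))
  expect_error(impute_median(data.frame(a = c(NA_real_, NA_real_)), "a"),
               "entirely missing")
  expect_error(impute_median(data.frame(CBT = 1), "CBT"), "never imputed")
})

test_that("z-score capping uses pre-replacement statistics, both tails", {
  set.seed(8)
  x <- rnorm(200)
  x[1] <- 5.0    # planted high outlier
  x[2] <- -5.0   # planted low outlier
  m <- mean(x)
  s <- sd(x) * sqrt(199 / 200)  # population sd
  stopifnot((5 - m) / s > 3)
  out <- cap_outliers_zscore(data.frame(v = x), "v")
  expect_equal(out$table$v[1], m + 3 * s)
  expect_equal(out$table$v[2], m - 3 * s)
  expect_identical(out$table$v[3:200], x[3:200])
  expect_identical(out$n_capped[["v"]], 2L)
  expect_equal(out$means[["v"]], m)
  expect_equal(out$sds[["v"]], s)
  # after capping, |z| wrt the ORIGINAL statistics is within the threshold
  expect_true(all(abs((out$table$v - m) / s) <= 3 + 1e-9))
})

test_that("capping edge cases: constant column, infinite threshold, NA", {
  const <- data.frame(v = rep(2, 10))
  out <- cap_outliers_zscore(const, "v")
  expect_identical(out$table$v, const$v)
  expect_identical(out$n_capped[["v"]], 0L)
  x <- data.frame(v = c(rnorm(50), 10))
  expect_identical(cap_outliers_zscore(x, "v", threshold = Inf)$table$v, x$v)
  expect_error(cap_outliers_zscore(data.frame(v = c(1, NA)), "v"),
               "impute first")
  expect_error(cap_outliers_zscore(data.frame(CBT = 1), "CBT"),
               "never capped")
})

test_that("sample-sd option widens the cap", {
  set.seed(9)
  x <- c(rnorm(100), 6)
  pop <- cap_outliers_zscore(data.frame(v = x), "v")
  samp <- cap_outliers_zscore(data.frame(v = x), "v", sd_type = "sample")
  expect_gt(samp$table$v[101], pop$table$v[101])
})

test_that("full preprocessing pipeline leaves no missing predictors", {
  co <- small_cohort(seed = 31, outlier = 0.02)
  pr <- preprocess_cohort(co$data)
  expect_s3_class(pr$report, "preprocess_report")
  num <- pr$table[vapply(pr$table, is.numeric, logical(1))]
  expect_false(anyNA(num))
  expect_true(all(pr$table$TZ %in% 0:1))
  expect_true(all(pr$table$BP %in% 0:1))
  # the target is untouched
  expect_identical(pr$table$CBT, co$data$CBT)
  expect_gt(sum(pr$report$n_imputed_per_column), 0)
  expect_gt(sum(pr$report$n_outliers_capped_per_column), 0)
  # capped columns satisfy the z contract wrt the recorded statistics
  for (col in names(pr$report$n_outliers_capped_per_column)) {
    s <- pr$report$column_stds[[col]]
    if (!is.finite(s) || s == 0) next
    z <- (pr$table[[col]] - pr$report$column_means[[col]]) / s
    expect_true(all(abs(z) <= 3 + 1e-9), label = paste("column", col))
  }
  # report serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_report(pr$report, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "\n")))
})
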