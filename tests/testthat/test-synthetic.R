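# Synthetic cohort generator: determinism, schema, generative-model
# recovery, corruption placement.

test_that("identical config and seed give identical tables", {
  a <- small_cohort(seed = 99)
  b <- small_cohort(seed = 99)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c2 <- small_cohort(seed = 100)
  expect_false(identical(a$data, c2$data))
})

test_that("row count is bounded by the per-day draw range", {
  co <- gen_cohort(generator_config(n_days = 5,
                                    cows_per_day_range = c(90L, 120L),
                                    seed = 1))
  expect_gte(nrow(co$data), 5 * 90)
  expect_lte(nrow(co$data), 5 * 120)
  expect_identical(sort(unique(co$data$day)), 1:5)
})

test_that("environment generator honors sampling windows and the sinusoid", {
  cfg <- generator_config()
  expect_error(gen_environment(1, 6, cfg), "sampling window")
  expect_error(gen_environment(1, 13, cfg), "sampling window")
  # noise-free peak value: mean + amplitude at the peak hour
  e <- gen_environment(1, 15, cfg, day_effect = 0, noise = FALSE)
  expect_equal(e$Ta, cfg$env$ta_mean + cfg$env$ta_amp)
  e8 <- gen_environment(1, 8, cfg, day_effect = 0, noise = FALSE)
  expect_lt(e8$Ta, e$Ta)
  expect_gt(e8$RH, e$RH)                 # humidity anti-correlated
  expect_true(e$Qsr > 0 && e$Tbg > e$Ta) # radiation load on the globe
  co <- small_cohort(seed = 5)
  expect_true(all(in_hours <- (co$data$hour >= 8 & co$data$hour <= 12) |
                    (co$data$hour >= 14 & co$data$hour <= 18)))
  expect_true(all(co$data$RH >= 20 & co$data$RH <= 100))
  expect_true(all(co$data$U >= 0) && all(co$data$Qsr >= 0))
})

test_that("generative CBT model matches hand evaluation", {
  cfg <- generator_config()
  expect_equal(gen_cbt(data.frame(IRTave_TK = 34, TZ = 0, BP = 0,
                                  DOL = 100), cfg, eps = 0), 38.4)
  expect_equal(gen_cbt(data.frame(IRTave_TK = 36, TZ = 1, BP = 1,
                                  DOL = 100), cfg, eps = 0), 38.82)
  expect_equal(gen_cbt(data.frame(IRTave_TK = 30, TZ = 0, BP = 0,
                                  DOL = 400), cfg, eps = 0),
               38.4 - 0.15 * 200 / 200)
  # clipping to the thermometer range
  expect_equal(gen_cbt(data.frame(IRTave_TK = 80, TZ = 1, BP = 1,
                                  DOL = 5), cfg, eps = 0), 42)
  expect_error(gen_cbt(data.frame(TZ = 0, BP = 0, DOL = 1), cfg),
               "IRTave_TK")
  expect_error(gen_cbt(data.frame(IRTave_TK = NA, TZ = 0, BP = 0,
                                  DOL = 1), cfg), "non-missing")
})

test_that("zero-noise, zero-corruption cohort equals its own truth exactly", {
  cfg <- generator_config(n_days = 3, cows_per_day_range = c(20L, 25L),
                          seed = 13, noise_sd_cbt = 0,
                          missing_rate_my = 0, missing_rate_irt = 0,
                          outlier_rate = 0)
  co <- gen_cohort(cfg)
  expect_identical(co$data, co$truth[, setdiff(names(co$truth), "CBT_mu")])
  expect_identical(co$data$CBT, co$truth$CBT_mu)
  # CBT reproduces the generative formula evaluated on its own row
  enc <- encode_categoricals(co$data)$table
  expect_equal(co$data$CBT, gen_cbt(enc, cfg, eps = 0))
})

test_that("missingness hits only milk yield and infrared columns", {
  co <- gen_cohort(generator_config(n_days = 10,
                                    cows_per_day_range = c(80L, 100L),
                                    seed = 21))
  na_cols <- names(co$data)[vapply(co$data, anyNA, logical(1))]
  irt_cols <- grep("^IRT", names(co$data), value = TRUE)
  expect_true(all(na_cols %in% c("MY", irt_cols)))
  expect_false(anyNA(co$data$CBT))
  expect_false(anyNA(co$data$TZ))
  expect_false(anyNA(co$data$BP))
  # observed missing fraction within 2 binomial SDs of the configured rate
  n <- nrow(co$data)
  rate <- mean(is.na(co$data$MY))
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / n) + 1e-12)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n_days = 0), "n_days")
  expect_error(generator_config(cows_per_day_range = c(10L, 5L)), "interval")
  expect_error(generator_config(missing_rate_my = 1.5), "rates")
  expect_error(generator_config(noise_sd_cbt = -1), "noise_sd_cbt")
})

test_that("cohort round-trips through CSV/JSON output", {
  co <- small_cohort(seed = 2, n_days = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "truth.csv",
                                               "generator_config.json")))))
  back <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), nrow(co$data))
  expect_equal(back$CBT, co$data$CBT)
})
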