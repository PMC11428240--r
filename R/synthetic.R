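# Synthetic cohort generation. The generator emulates the schema and the
# statistical structure of a summer rectal-temperature survey on a commercial
# dairy farm: ~30 sampling days, 90-120 cows per day, sampling restricted to
# the 8:00-12:00 and 14:00-18:00 windows, environment with diurnal structure,
# infrared surface temperatures correlated with air temperature and core
# temperature, missingness confined to milk yield and infrared columns, and
# occasional gross outliers. The core-temperature generative model is known
# and configurable so downstream stages can be tested against ground truth.

#' Regions of interest for infrared thermography
#'
#' Trunk, hind legs, front legs, udder, head, eyes, face, ears, neck.
#' @export
ROI_LIST <- c("TK", "HL", "FL", "UD", "HD", "EY", "FA", "ER", "NK")

#' Configuration of the synthetic cohort generator
#'
#' @param n_days number of sampling days (>= 1).
#' @param cows_per_day_range integer interval (low, high): cows observed per
#'   day are drawn uniformly from this range.
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   table.
#' @param noise_sd_cbt residual standard deviation of the core body
#'   temperature around its generative mean, degC.
#' @param missing_rate_my fraction of milk-yield cells set missing.
#' @param missing_rate_irt fraction of each infrared column set missing.
#' @param outlier_rate fraction of eligible numeric cells multiplied by
#'   `outlier_factor` to emulate gross sensor errors.
#' @param outlier_factor multiplicative corruption factor (default 1.5).
#' @param generative_coefficients named list with elements `intercept`
#'   (baseline CBT, degC), `b_irt` (degC per degC of trunk infrared
#'   temperature above the 34 degC hinge), `b_tz` (degC added in the
#'   afternoon block), `b_bp` (degC added when lying), `b_dol` (degC of
#'   decline across days in lactation beyond day 200), `irt_hinge` (hinge
#'   location, degC) and `dol_knee` (lactation-day knee, days).
#' @param env list of environment-model settings: `ta_mean`, `ta_amp`
#'   (diurnal sinusoid, degC, peak at `peak_hour`), `ta_day_sd` (day-level
#'   noise), `ta_obs_sd` (within-day noise), `rh_slope` (RH decrease per degC
#'   above `ta_mean`), `rh_base`, `rh_sd`, `tbg_qsr_coef` (degC of black-globe
#'   excess per kW/m^2 of solar radiation), `tbg_sd`, `qsr_peak`.
#'
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_days = 30,
                             cows_per_day_range = c(90L, 120L),
                             seed = 1L,
                             noise_sd_cbt = 0.25,
                             missing_rate_my = 0.05,
                             missing_rate_irt = 0.05,
                             outlier_rate = 0.005,
                             outlier_factor = 1.5,
                             generative_coefficients = list(
                               intercept = 38.4, b_irt = 0.12, b_tz = 0.10,
                               b_bp = 0.08, b_dol = 0.15, irt_hinge = 34,
                               dol_knee = 200),
                             env = list(
                               ta_mean = 27, ta_amp = 5, peak_hour = 15,
                               ta_day_sd = 1.5, ta_obs_sd = 0.5,
                               rh_base = 85, rh_slope = 1.8, rh_sd = 5,
                               tbg_qsr_coef = 3, tbg_sd = 0.3,
                               qsr_peak = 900)) {
  cfg <- list(n_days = as.integer(n_days),
              cows_per_day_range = as.integer(cows_per_day_range),
              seed = as.integer(seed),
              noise_sd_cbt = noise_sd_cbt,
              missing_rate_my = missing_rate_my,
              missing_rate_irt = missing_rate_irt,
              outlier_rate = outlier_rate,
              outlier_factor = outlier_factor,
              generative_coefficients = generative_coefficients,
              env = env)
  if (cfg$n_days < 1) stop("n_days must be >= 1")
  if (length(cfg$cows_per_day_range) != 2 ||
      cfg$cows_per_day_range[1] > cfg$cows_per_day_range[2]) {
    stop("cows_per_day_range must be an interval low <= high")
  }
  rates <- c(cfg$missing_rate_my, cfg$missing_rate_irt, cfg$outlier_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$noise_sd_cbt < 0) stop("noise_sd_cbt must be non-negative")
  class(cfg) <- "generator_config"
  cfg
}

# Sampling windows of the survey protocol (hours of day).
in_sampling_window <- function(hour) {
  (hour >= 8 & hour <= 12) | (hour >= 14 & hour <= 18)
}

#' Generate one environmental observation
#'
#' Air temperature follows a diurnal sinusoid (default mean 27 degC,
#' amplitude 5 degC, peak at 15:00) plus day-level and observation noise;
#' RH is anti-correlated with Ta and clipped to \[20, 100\]; wind speed is
#' right-skewed (Weibull); solar radiation has a midday peak; black-globe
#' temperature is Ta plus a radiation load (default 3 degC per kW/m^2).
#' Hours must fall in the survey windows 8:00-12:00 or 14:00-18:00.
#'
#' @param day_index sampling-day number (1-based).
#' @param hour hour of day (decimal), within the sampling windows.
#' @param config a [generator_config()].
#' @param day_effect optional fixed day-level temperature offset, degC; drawn
#'   from N(0, ta_day_sd) when NULL. Pass 0 for the noise-free sinusoid.
#' @param noise if FALSE all noise terms are suppressed (closed-form limit).
#' @return one-row data frame: `day`, `hour`, `Ta`, `Tbg`, `RH`, `U`, `Qsr`,
#'   `Tdp`.
#' @export
gen_environment <- function(day_index, hour, config = generator_config(),
                            day_effect = NULL, noise = TRUE) {
  if (any(!in_sampling_window(hour))) {
    stop("hour outside the sampling windows 8:00-12:00 / 14:00-18:00")
  }
  e <- config$env
  n <- max(length(day_index), length(hour))
  day_index <- rep_len(day_index, n); hour <- rep_len(hour, n)
  if (is.null(day_effect)) {
    day_effect <- if (noise) stats::rnorm(n, 0, e$ta_day_sd) else 0
  }
  Ta <- e$ta_mean + day_effect +
    e$ta_amp * cos(2 * pi * (hour - e$peak_hour) / 24) +
    if (noise) stats::rnorm(n, 0, e$ta_obs_sd) else 0
  RH <- pmin(100, pmax(20, e$rh_base - e$rh_slope * (Ta - e$ta_mean) +
                         if (noise) stats::rnorm(n, 0, e$rh_sd) else 0))
  U <- if (noise) stats::rweibull(n, shape = 1.5, scale = 1.2) else
    rep(1.2 * gamma(1 + 1 / 1.5), n)
  Qsr <- pmax(0, e$qsr_peak * sin(pi * (hour - 6) / 12) *
                (if (noise) stats::runif(n, 0.6, 1.0) else 0.8))
  Tbg <- Ta + e$tbg_qsr_coef * Qsr / 1000 +
    if (noise) stats::rnorm(n, 0, e$tbg_sd) else 0
  data.frame(day = day_index, hour = hour, Ta = Ta, Tbg = Tbg, RH = RH,
             U = U, Qsr = Qsr, Tdp = dew_point(Ta, RH))
}

#' Generative core-body-temperature model
#'
#' The deterministic part of the synthetic CBT model is
#' `CBT = intercept + b_irt * max(0, IRTave_TK - irt_hinge) + b_tz * TZ
#'  + b_bp * BP - b_dol * max(0, DOL - dol_knee) / dol_knee + eps`,
#' with `eps ~ N(0, noise_sd_cbt)`. The hinge on trunk infrared temperature
#' (at 34 degC) and the lactation-day decline (after day 200) encode the
#' dominant effect directions the pipeline is expected to recover. Output is
#' clipped to the veterinary-thermometer range \[32, 42\] degC.
#'
#' @param obs data frame with numeric columns `IRTave_TK`, `TZ` (0/1), `BP`
#'   (0/1), `DOL`.
#' @param config a [generator_config()].
#' @param eps residual vector; drawn from N(0, noise_sd_cbt) when NULL.
#' @return numeric vector of CBT values, degC.
#' @export
#' @examples
#' cfg <- generator_config()
#' gen_cbt(data.frame(IRTave_TK = 36, TZ = 1, BP = 1, DOL = 100),
#'         cfg, eps = 0)  # 38.82
gen_cbt <- function(obs, config = generator_config(), eps = NULL) {
  need <- c("IRTave_TK", "TZ", "BP", "DOL")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing generative drivers: ",
                         paste(miss, collapse = ", "))
  if (anyNA(obs[need])) stop("generative drivers must be non-missing")
  b <- config$generative_coefficients
  mu <- b$intercept +
    b$b_irt * pmax(0, obs$IRTave_TK - b$irt_hinge) +
    b$b_tz * obs$TZ +
    b$b_bp * obs$BP -
    b$b_dol * pmax(0, obs$DOL - b$dol_knee) / b$dol_knee
  if (is.null(eps)) eps <- stats::rnorm(nrow(obs), 0, config$noise_sd_cbt)
  pmin(42, pmax(32, mu + eps))
}

# Infrared model: baseline intercepts per region (degC at Ta = 0 after the
# air-temperature slope is applied), air-temperature slope, and coupling of
# the non-trunk regions to core temperature. The trunk is generated
# exogenously (from air temperature plus local noise) and drives CBT
# directly through the hinge in gen_cbt(); the remaining regions are
# conditioned on the realized CBT with weaker couplings, so the trunk is by
# construction the most informative region.
irt_params <- function() {
  base <- c(TK = 25.0, HL = 24.0, FL = 23.5, UD = 25.5, HD = 23.0,
            EY = 26.5, FA = 22.5, ER = 20.0, NK = 22.0)
  alpha2 <- c(TK = NA, HL = 0.5, FL = 0.5, UD = 0.6, HD = 0.6,
              EY = 0.8, FA = 0.5, ER = 0.4, NK = 0.5)
  list(base = base, alpha1 = 0.33, alpha2 = alpha2,
       sd_tk = 1.5, sd_other = 0.8, max_offset_mean = 1.2,
       max_offset_sd = 0.4)
}

#' Generate a synthetic cohort table
#'
#' Draws per-day cow counts, sampling hours within the survey windows,
#' environment, animal covariates, infrared temperatures and core body
#' temperature from the documented generative model, then injects
#' missingness (milk yield and infrared columns only) and multiplicative
#' outliers. The uncorrupted table is returned alongside as a test oracle.
#'
#' @param config a [generator_config()].
#' @return list of class `cow_cohort`:
#'   \describe{
#'     \item{data}{the corrupted analysis table (one row per observation)}
#'     \item{truth}{the pre-corruption table, plus `CBT_mu`, the
#'       deterministic part of the generative CBT model}
#'     \item{config}{the generating configuration}
#'   }
#' @export
gen_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  rng <- config$cows_per_day_range
  n_per_day <- sample(seq(rng[1], rng[2]), config$n_days, replace = TRUE)
  day <- rep(seq_len(config$n_days), n_per_day)
  n <- length(day)

  # half the observations in each sampling block
  am <- stats::runif(n) < 0.5
  hour <- ifelse(am, stats::runif(n, 8, 12), stats::runif(n, 14, 18))
  day_effect <- stats::rnorm(config$n_days, 0, config$env$ta_day_sd)
  env <- gen_environment(day, hour, config, day_effect = day_effect[day])

  TZ <- as.integer(!am)                       # 0 = A.M., 1 = P.M.
  BP <- stats::rbinom(n, 1, 0.35)             # 1 = lying down
  MY <- pmax(5, stats::rnorm(n, 32, 6))
  DOL <- round(stats::runif(n, 5, 400))
  PA <- 1L + stats::rpois(n, 1.2)

  p <- irt_params()
  irt_tk <- p$base[["TK"]] + p$alpha1 * env$Ta + stats::rnorm(n, 0, p$sd_tk)
  eps <- stats::rnorm(n, 0, config$noise_sd_cbt)
  drivers <- data.frame(IRTave_TK = irt_tk, TZ = TZ, BP = BP, DOL = DOL)
  CBT <- gen_cbt(drivers, config, eps = eps)
  mu <- gen_cbt(drivers, config, eps = 0)

  irt_ave <- matrix(NA_real_, n, length(ROI_LIST),
                    dimnames = list(NULL, paste0("IRTave_", ROI_LIST)))
  irt_ave[, "IRTave_TK"] <- irt_tk
  for (roi in setdiff(ROI_LIST, "TK")) {
    irt_ave[, paste0("IRTave_", roi)] <-
      p$base[[roi]] + p$alpha1 * env$Ta +
      p$alpha2[[roi]] * (CBT - config$generative_coefficients$intercept) +
      stats::rnorm(n, 0, p$sd_other)
  }
  offs <- matrix(abs(stats::rnorm(n * length(ROI_LIST), p$max_offset_mean,
                                  p$max_offset_sd)), n)
  irt_max <- irt_ave + offs
  colnames(irt_max) <- paste0("IRTmax_", ROI_LIST)

  truth <- data.frame(
    day = day, hour = hour,
    Ta = env$Ta, Tbg = env$Tbg, RH = env$RH, U = env$U, Qsr = env$Qsr,
    TZ = ifelse(TZ == 1, "P.M.", "A.M."),
    BP = ifelse(BP == 1, "lying down", "standing"),
    MY = MY, DOL = DOL, PA = PA,
    irt_max, irt_ave,
    CBT = CBT, CBT_mu = mu,
    stringsAsFactors = FALSE)

  data <- truth[, setdiff(names(truth), "CBT_mu")]

  # corruption: outliers first (multiplicative factor on eligible numeric
  # cells), then missingness in MY and infrared columns only. RH is exempt
  # from outlier injection: it is hard-bounded at 100% and a multiplicative
  # spike would leave the physical domain rather than emulate a sensor error.
  irt_cols <- c(colnames(irt_max), colnames(irt_ave))
  eligible <- c("Ta", "Tbg", "U", "Qsr", "MY", irt_cols)
  if (config$outlier_rate > 0) {
    for (col in eligible) {
      hit <- stats::runif(n) < config$outlier_rate
      data[[col]][hit] <- data[[col]][hit] * config$outlier_factor
    }
  }
  if (config$missing_rate_my > 0) {
    data$MY[stats::runif(n) < config$missing_rate_my] <- NA_real_
  }
  if (config$missing_rate_irt > 0) {
    for (col in irt_cols) {
      data[[col]][stats::runif(n) < config$missing_rate_irt] <- NA_real_
    }
  }
  structure(list(data = data, truth = truth, config = config),
            class = "cow_cohort")
}

#' @export
print.cow_cohort <- function(x, ...) {
  cat("Synthetic cow cohort:", nrow(x$data), "observations over",
      x$config$n_days, "days;",
      sum(is.na(x$data)), "missing cells\n")
  invisible(x)
}

#' Write a cohort (data + truth + config) to plain-text files
#'
#' @param cohort a `cow_cohort` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Writes `cohort.csv`, `truth.csv`,
#'   `generator_config.json`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$data, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# save/restore the global RNG state so generator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
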