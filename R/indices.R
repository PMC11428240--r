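#' Dew point temperature (Magnus formula)
#'
#' Computes the dew point from air temperature and relative humidity using
#' the Magnus approximation with constants a = 17.625, b = 243.04 degC, the
#' standard meteorological parameterisation. Needed as an input to [bghi()].
#'
#' @param Ta air temperature, degC.
#' @param RH relative humidity, percent, in (0, 100].
#' @return Dew point temperature, degC. Vectorized over inputs.
#' @export
#' @examples
#' dew_point(25, 100)  # saturation: equals Ta
#' dew_point(25, 50)   # ~13.86 degC
dew_point <- function(Ta, RH) {
  stopifnot(is.numeric(Ta), is.numeric(RH))
  if (any(!is.finite(Ta)) || any(!is.finite(RH))) {
    stop("Ta and RH must be finite")
  }
  if (any(RH <= 0) || any(RH > 100)) {
    stop("RH must be in (0, 100] percent")
  }
  a <- 17.625
  b <- 243.04
  g <- log(RH / 100) + a * Ta / (b + Ta)
  b * g / (a - g)
}

#' Temperature-humidity index (THI)
#'
#' THI = 1.8 Ta + 32 - (0.55 - 0.0055 RH) (1.8 Ta - 26). The classical
#' livestock heat-stress index on the Fahrenheit-like scale; values above
#' ~72 indicate heat stress for lactating cows.
#'
#' @inheritParams dew_point
#' @return THI (unitless index scale). Vectorized.
#' @export
#' @examples
#' thi(25, 50)  # 71.775
thi <- function(Ta, RH) {
  1.8 * Ta + 32 - (0.55 - 0.0055 * RH) * (1.8 * Ta - 26)
}

#' Black globe humidity index (BGHI)
#'
#' BGHI = Tbg + 0.36 Tdp + 41.5, where Tbg is the black-globe temperature
#' (radiation-loaded) and Tdp the dew point.
#'
#' @param Tbg black-globe temperature, degC.
#' @param Tdp dew point temperature, degC (see [dew_point()]).
#' @return BGHI (unitless index scale). Vectorized.
#' @export
#' @examples
#' bghi(30, 15)  # 76.9
bghi <- function(Tbg, Tdp) {
  Tbg + 0.36 * Tdp + 41.5
}

#' Adjusted temperature-humidity index (ATHI)
#'
#' Mader-type THI adjusted for wind speed and solar radiation:
#' ATHI = 4.51 + \[0.8 Ta + (RH/100)(Ta - 14.4) + 46.4\] - 1.992 U + 0.0068 Qsr.
#' Wind cools (negative coefficient), radiation heats.
#'
#' @inheritParams dew_point
#' @param U wind speed, m/s.
#' @param Qsr solar radiation intensity, W/m^2.
#' @return ATHI (unitless index scale). Vectorized.
#' @export
#' @examples
#' athi(25, 50, 1, 500)  # 77.618
athi <- function(Ta, RH, U, Qsr) {
  4.51 + (0.8 * Ta + (RH / 100) * (Ta - 14.4) + 46.4) - 1.992 * U +
    0.0068 * Qsr
}

# Comprehensive-climate-index correction terms. The composite index is
# Ta + wind + radiation + humidity corrections; each correction is the
# published component form.
cci_eq_u <- function(U) {
  expo <- (1 / (2.26 * U + 0.23)^0.45) *
    (2.9 + 1.14e-6 * U^2.5 - log(2.26 * U + 0.33, base = 0.3))
  -6.56 / exp(expo) - 0.00566 * U^2 + 3.33
}

cci_eq_qsr <- function(Qsr, Ta) {
  0.0076 * Qsr - 0.00002 * Qsr * Ta + 0.00005 * Ta^2 * Qsr + 0.1 * Ta - 2
}

cci_eq_rh <- function(RH, Ta) {
  exp(0.00182 * RH + 1.8e-5 * Ta * RH) *
    (0.000054 * Ta^2 + 0.00192 * Ta - 0.0246) * (RH - 30)
}

#' Comprehensive climate index (CCI)
#'
#' Apparent-temperature index: air temperature plus additive corrections
#' for humidity, wind and solar radiation,
#' CCI = Ta + eq(U) + eq(Qsr) + eq(RH).
#' The correction components are the published forms of the comprehensive
#' climate index for cattle; e.g. the radiation correction is
#' 0.0076 Qsr - 2e-5 Qsr Ta + 5e-5 Ta^2 Qsr + 0.1 Ta - 2.
#'
#' @inheritParams athi
#' @return CCI, degC-equivalent apparent temperature. Vectorized.
#' @export
cci <- function(Ta, RH, U, Qsr) {
  if (any(U < 0)) stop("U must be non-negative")
  Ta + cci_eq_u(U) + cci_eq_qsr(Qsr, Ta) + cci_eq_rh(RH, Ta)
}

#' Dairy heat load index (DHLI)
#'
#' Sigmoid (complementary log-log) heat-load index in black-globe
#' temperature and relative humidity, rescaled to a 0-100 scale:
#' DHLI = 100 (1.681813 (1 - exp(-exp(-8.50749 + 0.206149 Tbg +
#' 4.088399 rh))) - 0.0002) / (1.6812 - 0.0002), with rh = RH/100.
#' Monotone increasing in Tbg and bounded on the 0-100-type scale.
#'
#' @param Tbg black-globe temperature, degC.
#' @param RH relative humidity, percent (converted internally to a fraction).
#' @return DHLI (index scale, approximately 0-100). Vectorized.
#' @export
dhli <- function(Tbg, RH) {
  rh <- RH / 100
  z <- -8.50749 + 0.206149 * Tbg + 4.088399 * rh
  100 * (1.681813 * (1 - exp(-exp(z))) - 0.0002) / (1.6812 - 0.0002)
}

#' Equivalent temperature index for cattle (ETIC)
#'
#' ETIC = Ta - 0.0038 Ta (100 - RH) - 0.1173 U^0.7073 (39.2 - Ta)
#'      + 1.86e-4 Ta Qsr.
#' A degC-equivalent index: at saturation, calm air and no sun it reduces
#' to the air temperature.
#'
#' @inheritParams athi
#' @return ETIC, degC-equivalent. Vectorized.
#' @export
#' @examples
#' etic(20, 100, 0, 0)  # 20
etic <- function(Ta, RH, U, Qsr) {
  Ta - 0.0038 * Ta * (100 - RH) - 0.1173 * U^0.7073 * (39.2 - Ta) +
    1.86e-4 * Ta * Qsr
}

#' Skin temperature index for cows (STIC)
#'
#' Empirical skin-temperature-scale index combining air temperature, vapor
#' pressure deficit, wind and solar radiation:
#' STIC = \[1.73 Ta - (1 - RH/100) 10^(7.5 Ta / (237 + Ta))
#'          + 0.116 U^0.53 (10 Ta - 300) + 0.05 Qsr + 16.08\]
#'        / (0.116 U^0.53 + 1).
#' The vapor-deficit term vanishes at RH = 100; wind both adds a term in the
#' numerator and inflates the denominator, reproducing the convective
#' coupling of skin temperature to air temperature.
#'
#' @inheritParams athi
#' @return STIC (skin-temperature index scale). Vectorized.
#' @export
stic <- function(Ta, RH, U, Qsr) {
  wind <- 0.116 * U^0.53
  num <- 1.73 * Ta - (1 - RH / 100) * 10^(7.5 * Ta / (237 + Ta)) +
    wind * (10 * Ta - 300) + 0.05 * Qsr + 16.08
  num / (wind + 1)
}

#' Compute all seven thermal comfort indices for a table of environment rows
#'
#' @param env data frame with columns `Ta`, `Tbg`, `RH`, `U`, `Qsr`.
#' @return data frame with columns `THI`, `BGHI`, `ATHI`, `CCI`, `DHLI`,
#'   `ETIC`, `STIC` (one row per input row).
#' @export
thermal_indices <- function(env) {
  need <- c("Ta", "Tbg", "RH", "U", "Qsr")
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("missing environment columns: ",
                         paste(miss, collapse = ", "))
  tdp <- dew_point(env$Ta, env$RH)
  data.frame(
    THI  = thi(env$Ta, env$RH),
    BGHI = bghi(env$Tbg, tdp),
    ATHI = athi(env$Ta, env$RH, env$U, env$Qsr),
    CCI  = cci(env$Ta, env$RH, env$U, env$Qsr),
    DHLI = dhli(env$Tbg, env$RH),
    ETIC = etic(env$Ta, env$RH, env$U, env$Qsr),
    STIC = stic(env$Ta, env$RH, env$U, env$Qsr)
  )
}
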