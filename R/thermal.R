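#' Intermediate physiological state of the cow-environment heat exchange
#'
#' Evaluates the empirical physiological sub-models that feed the heat-flux
#' equations: skin and coat temperature, exhaled-air temperature, sweating
#' rate, saturation vapor pressures, respiratory frequency, tidal volume,
#' respiratory evaporative resistance, and the Nusselt number of the
#' cow-as-cylinder forced-convection model.
#'
#' Sub-models (all inputs degC, percent, m/s, W/m^2):
#' \itemize{
#'   \item skin temperature
#'     `Ts = (0.173 Ta - (0.1 - RH/1000) 10^(7.5 Ta/(237.5 + Ta)) +
#'     0.116 U^0.53 Ta + 5 Qsr/1000 + 31.608) / (0.116 U^0.53 + 1)`
#'   \item coat temperature `Tc = 18.76 + 0.908 Ta - 0.011 Ta^2`
#'   \item exhaled air `Tex = 17.0 + 0.3 Ta + exp(0.01611 RH + 0.0387 Ta)`
#'   \item sweating rate, piecewise in Ts:
#'     quadratic `1.1665 Ts^2 - 64.166 Ts + 894.35` below 35 degC,
#'     linear `4.2976 Ts - 71.289` at and above 35 degC
#'   \item saturation vapor pressure `Pe = 0.611 x 10^(7.5 T/(T + 237.3))`
#'     evaluated at Ta (`Pe_a`) and at Tex (`Pe_b`)
#'   \item respiratory frequency `Fr = exp(2.966 + 0.0218 Ta + 0.00069 Ta)`
#'   \item tidal volume `Vt = 0.0189 Fr - 0.463`, floored at
#'     `constants$vt_floor` because the linear form goes negative for
#'     Fr < 24.5
#'   \item respiratory evaporative resistance
#'     `rr = 100 / (2.7e-4 Fr + 5e-3)`
#'   \item Nusselt number from the Hilpert cylinder-crossflow correlation,
#'     `Nu = C Re^m Pr^(1/3)`, `Re = U d / nu_air`, with the usual banded
#'     (C, m); `Nu = 0` at `U = 0` (natural convection out of scope).
#' }
#'
#' @param Ta air temperature, degC.
#' @param RH relative humidity, percent, in (0, 100].
#' @param U wind speed, m/s, non-negative.
#' @param Qsr solar radiation, W/m^2.
#' @param constants a [thermal_constants()] list.
#' @return data frame with columns `Ts`, `Tc`, `Tex`, `Rsw`, `Pe_a`, `Pe_b`,
#'   `Fr`, `Vt`, `rr`, `Nu`, `Trad` (one row per input element). `Trad`, the
#'   mean radiant temperature, is approximated by `Ta`.
#' @export
#' @examples
#' thermal_state(25, 60, 1, 400)
thermal_state <- function(Ta, RH, U, Qsr, constants = thermal_constants()) {
  if (any(U < 0)) stop("U must be non-negative")
  if (any(RH <= 0) || any(RH > 100)) stop("RH must be in (0, 100] percent")
  n <- max(length(Ta), length(RH), length(U), length(Qsr))
  Ta <- rep_len(Ta, n); RH <- rep_len(RH, n)
  U <- rep_len(U, n); Qsr <- rep_len(Qsr, n)

  wind <- 0.116 * U^0.53
  Ts <- (0.173 * Ta - (0.1 - RH / 1000) * 10^(7.5 * Ta / (237.5 + Ta)) +
           wind * Ta + 5 * Qsr / 1000 + 31.608) / (wind + 1)
  Tc <- 18.76 + 0.908 * Ta - 0.011 * Ta^2
  Tex <- 17.0 + 0.3 * Ta + exp(0.01611 * RH + 0.0387 * Ta)
  Rsw <- ifelse(Ts < 35,
                1.1665 * Ts^2 - 64.166 * Ts + 894.35,
                4.2976 * Ts - 71.289)
  Pe_a <- 0.611 * 10^(7.5 * Ta / (Ta + 237.3))
  Pe_b <- 0.611 * 10^(7.5 * Tex / (Tex + 237.3))
  Fr <- exp(2.966 + 0.0218 * Ta + 0.00069 * Ta)
  Vt <- pmax(0.0189 * Fr - 0.463, constants$vt_floor)
  rr <- 100 / (2.7e-4 * Fr + 5e-3)
  Nu <- nusselt(U, constants)

  data.frame(Ts = Ts, Tc = Tc, Tex = Tex, Rsw = Rsw, Pe_a = Pe_a,
             Pe_b = Pe_b, Fr = Fr, Vt = Vt, rr = rr, Nu = Nu, Trad = Ta)
}

# Hilpert correlation for a cylinder in crossflow; Nu = 0 in still air.
nusselt <- function(U, constants = thermal_constants()) {
  Re <- U * constants$d / constants$nu_air
  C <- numeric(length(Re))
  m <- numeric(length(Re))
  bands <- cbind(lo = c(0, 4, 40, 4000, 40000),
                 C = c(0.989, 0.911, 0.683, 0.193, 0.027),
                 m = c(0.330, 0.385, 0.466, 0.618, 0.805))
  idx <- findInterval(Re, bands[, "lo"])
  idx[idx < 1] <- 1
  C <- bands[idx, "C"]
  m <- bands[idx, "m"]
  ifelse(Re <= 0, 0, C * Re^m * constants$Pr^(1 / 3))
}

#' Heat fluxes between the cow and its environment
#'
#' Computes the latent and sensible heat-flux components per unit body
#' surface area from a [thermal_state()] table:
#' \itemize{
#'   \item respiratory latent flux
#'     `Qresp = Fr Vt rho_cp (Tex - Ta) / (60 S)
#'              + rho_cp (Pe_b - Pe_amb) / (gamma rr)` where `Pe_amb` is the
#'     ambient vapor pressure under the convention in
#'     `constants$ambient_vapor` (default: actual ambient pressure
#'     `RH/100 * Pe_a`)
#'   \item cutaneous evaporation `Qevap = Rsw lambda / 3600`
#'   \item convection `Qconv = (Tc - Ta) k_a Nu / d`
#'   \item radiation, linearized in Kelvin:
#'     `Qrad = (Tc - Trad) 4 sigma epsilon Tm^3` with
#'     `Tm = (Tc + Trad)/2 + 273.15`
#'   \item totals `Qlat = Qresp + Qevap`, `Qsens = Qconv + Qrad` (exact
#'     identities by construction).
#' }
#'
#' @param state data frame from [thermal_state()].
#' @param Ta air temperature, degC.
#' @param RH relative humidity, percent.
#' @param constants a [thermal_constants()] list.
#' @return data frame with columns `Qresp`, `Qevap`, `Qconv`, `Qrad`,
#'   `Qlat`, `Qsens`, all W/m^2.
#' @export
heat_fluxes <- function(state, Ta, RH, constants = thermal_constants()) {
  need <- c("Fr", "Vt", "Tex", "Pe_a", "Pe_b", "rr", "Rsw", "Tc", "Nu",
            "Trad")
  miss <- setdiff(need, names(state))
  if (length(miss)) stop("state is missing columns: ",
                         paste(miss, collapse = ", "))
  with(c(state, constants), {
    Pe_amb <- if (constants$ambient_vapor == "actual") {
      (RH / 100) * Pe_a
    } else {
      Pe_a
    }
    Qresp <- Fr * Vt * rho_cp * (Tex - Ta) / (60 * S) +
      rho_cp * (Pe_b - Pe_amb) / (gamma * rr)
    Qevap <- Rsw * lambda / 3600
    Qconv <- (Tc - Ta) * k_a * Nu / d
    Tm <- (Tc + Trad) / 2 + 273.15
    Qrad <- (Tc - Trad) * 4 * sigma * epsilon * Tm^3
    data.frame(Qresp = Qresp, Qevap = Qevap, Qconv = Qconv, Qrad = Qrad,
               Qlat = Qresp + Qevap, Qsens = Qconv + Qrad)
  })
}

#' Append thermal-comfort indices, physiological state and heat fluxes
#'
#' Batch feature engineering: given a cohort table with environment columns
#' (`Ta`, `Tbg`, `RH`, `U`, `Qsr`), appends the seven comfort indices and the
#' six heat-flux variables (and, optionally, the intermediate state).
#'
#' @param table cohort data frame.
#' @param constants a [thermal_constants()] list.
#' @param keep_state if TRUE also append the [thermal_state()] columns.
#' @return the table with feature columns appended.
#' @export
add_thermal_features <- function(table, constants = thermal_constants(),
                                 keep_state = FALSE) {
  idx <- thermal_indices(table)
  st <- thermal_state(table$Ta, table$RH, table$U, table$Qsr, constants)
  fl <- heat_fluxes(st, table$Ta, table$RH, constants)
  out <- cbind(table, idx, fl)
  if (keep_state) out <- cbind(out, st)
  out
}
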