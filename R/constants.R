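#' Physical constants of the cow-environment heat-exchange model
#'
#' Returns the constant set used by [thermal_state()] and [heat_fluxes()].
#' Values are the conventional ones for a lactating Holstein modelled as a
#' horizontal cylinder in crossflow.
#'
#' @param S body surface area, m^2.
#' @param rho_cp volumetric specific heat capacity of air, J m^-3 K^-1.
#' @param gamma psychrometer constant, kPa K^-1.
#' @param lambda latent heat of vaporization of water, J g^-1.
#' @param sigma Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param epsilon emissivity of the coat surface (dimensionless).
#' @param d characteristic diameter of the cow trunk, m.
#' @param k_a thermal conductivity of air, W m^-1 K^-1.
#' @param nu_air kinematic viscosity of air, m^2 s^-1 (used in the Reynolds
#'   number of the convection correlation).
#' @param Pr Prandtl number of air (dimensionless).
#' @param vt_floor lower guard for tidal volume, m^3: the published linear
#'   tidal-volume model goes negative at low respiratory frequency, so Vt is
#'   floored here.
#' @param ambient_vapor convention for the ambient vapor-pressure term of the
#'   respiratory latent flux: `"actual"` uses RH/100 times saturation pressure
#'   at Ta (the physically meaningful deficit), `"saturation"` uses saturation
#'   pressure at Ta (the literal tabulated reading).
#'
#' @return A named list of class `thermal_constants`.
#' @export
#' @examples
#' thermal_constants()$S  # 5.4 m^2
thermal_constants <- function(S = 5.4,
                              rho_cp = 1220,
                              gamma = 0.066,
                              lambda = 2260,
                              sigma = 5.67e-8,
                              epsilon = 0.95,
                              d = 0.8,
                              k_a = 0.025,
                              nu_air = 1.5e-5,
                              Pr = 0.71,
                              vt_floor = 1e-4,
                              ambient_vapor = c("actual", "saturation")) {
  ambient_vapor <- match.arg(ambient_vapor)
  out <- list(S = S, rho_cp = rho_cp, gamma = gamma, lambda = lambda,
              sigma = sigma, epsilon = epsilon, d = d, k_a = k_a,
              nu_air = nu_air, Pr = Pr, vt_floor = vt_floor,
              ambient_vapor = ambient_vapor)
  num <- vapply(out[names(out) != "ambient_vapor"], is.numeric, logical(1))
  if (!all(num) ||
      any(unlist(out[names(out) != "ambient_vapor"]) <= 0)) {
    stop("all thermal constants must be strictly positive numbers")
  }
  class(out) <- "thermal_constants"
  out
}
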