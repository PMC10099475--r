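#' Parameters of the optimality-based LUE simulator
#'
#' Constants of the P-model: the unit-cost ratio of carboxylation vs
#' transpiration capacity, the Jmax-limitation constant, the quadratic
#' temperature dependence of the intrinsic quantum yield, the empirical
#' soil-moisture stress function, and the 25 degC reference kinetics of
#' Rubisco (CO2 compensation point and Michaelis-Menten constants with
#' their activation energies).
#'
#' @param beta_cost Unit cost ratio (default 146).
#' @param c_star Jmax-limitation constant (default 0.41).
#' @param kphio Calibrated maximum intrinsic quantum yield multiplier
#'   (mol C mol-1 photons).
#' @param phi0_coeffs Coefficients (c0, c1, c2) of the quadratic
#'   temperature sensitivity of the intrinsic quantum yield,
#'   `phi0(T) = kphio * (c0 + c1 T + c2 T^2)`.
#' @param soilm_theta_star Soil-moisture threshold below which stress
#'   sets in (fraction of water-holding capacity).
#' @param soilm_a,soilm_b Intercept and slope mapping the climatological
#'   moisture index `mean_alpha` to the stress level at zero soil
#'   moisture.
#' @param gammastar25 CO2 compensation point at 25 degC, sea level (Pa).
#' @param dha_gammastar Activation energy of gammastar (J mol-1).
#' @param kc25,ko25 Michaelis constants of carboxylation/oxygenation at
#'   25 degC (Pa), with activation energies `dha_kc`, `dha_ko`.
#' @param o2_frac Mole fraction of O2 in dry air.
#' @return An object of class `pmodel_params`.
#' @export
pmodel_params <- function(beta_cost = 146,
                          c_star = 0.41,
                          kphio = 0.087,
                          phi0_coeffs = c(0.352, 0.022, -0.00034),
                          soilm_theta_star = 0.6,
                          soilm_a = 0.0,
                          soilm_b = 0.733,
                          gammastar25 = 4.332,
                          dha_gammastar = 37830,
                          kc25 = 39.97,
                          dha_kc = 79430,
                          ko25 = 27480,
                          dha_ko = 36380,
                          o2_frac = 0.20946) {
  p <- list(beta_cost = beta_cost, c_star = c_star, kphio = kphio,
            phi0_coeffs = phi0_coeffs,
            soilm_theta_star = soilm_theta_star,
            soilm_a = soilm_a, soilm_b = soilm_b,
            gammastar25 = gammastar25, dha_gammastar = dha_gammastar,
            kc25 = kc25, dha_kc = dha_kc, ko25 = ko25, dha_ko = dha_ko,
            o2_frac = o2_frac)
  stopifnot(beta_cost > 0, c_star > 0, kphio > 0,
            soilm_theta_star > 0, gammastar25 > 0)
  class(p) <- "pmodel_params"
  p
}

# barometric pressure (Pa) from elevation (m), standard atmosphere
.patm <- function(elevation) {
  101325 * (1 - 0.0065 * elevation / 288.15)^
    (9.80665 * 0.028963 / (8.3145 * 0.0065))
}

# Arrhenius scaling from the 25 degC reference
.arrhenius <- function(dha, temp) {
  tk <- temp + 273.15
  exp(dha * (tk - 298.15) / (298.15 * 8.3145 * tk))
}

#' Temperature- and pressure-dependent photosynthetic kinetics
#'
#' Arrhenius scaling of the photorespiratory CO2 compensation point
#' (gammastar) and the effective Michaelis-Menten coefficient of
#' Rubisco `K = Kc (1 + pO2/Ko)`, plus the viscosity of water relative
#' to 25 degC.
#'
#' @param temp Air temperature (degC), in \[-25, 60\].
#' @param elevation Elevation (m), converted to pressure by the standard
#'   barometric formula.
#' @param params A [pmodel_params()] object.
#' @return List with vectors `gammastar` (Pa), `K` (Pa), `eta_star`
#'   (dimensionless) and `patm` (Pa).
#' @export
photosynthesis_kinetics <- function(temp, elevation = 0,
                                    params = pmodel_params()) {
  if (any(!is.finite(temp)) || any(temp < -25) || any(temp > 60))
    stop("temp must be in [-25, 60] degC")
  patm <- .patm(elevation)
  gammastar <- params$gammastar25 * (patm / 101325) *
    .arrhenius(params$dha_gammastar, temp)
  kc <- params$kc25 * .arrhenius(params$dha_kc, temp)
  ko <- params$ko25 * .arrhenius(params$dha_ko, temp)
  po2 <- params$o2_frac * patm
  # water viscosity relative to 25 degC (Vogel-type correlation)
  visc <- function(tc) 2.414e-5 * 10^(247.8 / (tc + 273.15 - 140))
  list(gammastar = gammastar, K = kc * (1 + po2 / ko),
       eta_star = visc(temp) / visc(25), patm = patm)
}

#' Optimal ratio of leaf-internal to ambient CO2
#'
#' The least-cost optimality solution
#' `chi = gammastar/ca + (1 - gammastar/ca) * xi / (xi + sqrt(D))` with
#' `xi = sqrt(beta (K + gammastar) / (1.6 eta*))`, and the CO2
#' limitation factor of light-limited assimilation
#' `mj = (ci - gammastar) / (ci + 2 gammastar)`.
#'
#' @param temp Air temperature (degC).
#' @param vpd Vapour pressure deficit (Pa), >= 0.
#' @param co2 Ambient CO2 (umol mol-1).
#' @param elevation Elevation (m).
#' @param params A [pmodel_params()] object.
#' @return List with vectors `chi`, `ci` (Pa), `mj`, `xi`.
#' @export
optimal_chi <- function(temp, vpd, co2, elevation = 0,
                        params = pmodel_params()) {
  if (any(vpd < 0, na.rm = TRUE)) stop("vpd must be nonnegative")
  if (any(co2 <= 0, na.rm = TRUE)) stop("co2 must be positive")
  k <- photosynthesis_kinetics(temp, elevation, params)
  ca <- co2 * 1e-6 * k$patm
  xi <- sqrt(params$beta_cost * (k$K + k$gammastar) / (1.6 * k$eta_star))
  chi <- k$gammastar / ca +
    (1 - k$gammastar / ca) * xi / (xi + sqrt(pmax(vpd, 0)))
  ci <- chi * ca
  mj <- (ci - k$gammastar) / (ci + 2 * k$gammastar)
  list(chi = chi, ci = ci, mj = pmax(mj, 0), xi = xi)
}

# empirical soil-moisture stress multiplier in [0, 1]
.soilm_stress <- function(soil_m, mean_alpha, params) {
  beta0 <- params$soilm_a + params$soilm_b * mean_alpha
  q <- (beta0 - 1) / params$soilm_theta_star^2
  out <- ifelse(soil_m >= params$soilm_theta_star, 1,
                q * (soil_m - params$soilm_theta_star)^2 + 1)
  pmin(pmax(out, 0), 1)
}

#' Light use efficiency predicted by the optimality model
#'
#' `LUE = phi0(T) * beta_sm(theta) * mj * sqrt(1 - (c*/mj)^(2/3))`,
#' zero where `mj <= c*`: the intrinsic quantum yield with its
#' quadratic temperature sensitivity, an empirical soil-moisture stress
#' multiplier, the CO2 limitation of light-limited photosynthesis from
#' [optimal_chi()], and the Jmax-limitation factor.
#'
#' @param temp Air temperature (degC).
#' @param vpd Vapour pressure deficit (Pa).
#' @param co2 Ambient CO2 (umol mol-1).
#' @param elevation Elevation (m).
#' @param soil_m Soil moisture as a fraction of holding capacity (0, 1].
#' @param mean_alpha Climatological moisture index scaling the maximum
#'   soil-moisture stress (1 = mild stress at dry soil).
#' @param params A [pmodel_params()] object.
#' @return LUE (mol C mol-1 photons).
#' @examples
#' pmodel_lue(temp = 20, vpd = 800, co2 = 400)
#' @export
pmodel_lue <- function(temp, vpd, co2 = 400, elevation = 0, soil_m = 1,
                       mean_alpha = 1, params = pmodel_params()) {
  if (any(soil_m <= 0 | soil_m > 1, na.rm = TRUE))
    stop("soil_m must be in (0, 1]")
  oc <- optimal_chi(temp, vpd, co2, elevation, params)
  cf <- params$phi0_coeffs
  phi0 <- params$kphio * pmax(cf[1] + cf[2] * temp + cf[3] * temp^2, 0)
  bsm <- .soilm_stress(soil_m, mean_alpha, params)
  jlim <- ifelse(oc$mj > params$c_star,
                 sqrt(pmax(1 - (params$c_star / oc$mj)^(2 / 3), 0)), 0)
  phi0 * bsm * oc$mj * jlim
}

#' One-driver-at-a-time response experiment with the optimality model
#'
#' Evaluates [pmodel_lue()] along a grid of one environmental driver
#' while the other drivers are held at their medians in a composite
#' dataset, mirroring the conditional response curves of the empirical
#' model so the two can be overlaid.
#'
#' @param composites An `lue_composites` data.frame supplying the
#'   medians and observed driver ranges.
#' @param variable One of `"temp"`, `"vpd"`, `"soil_m"`, `"ci"`,
#'   `"co2"`, `"elevation"`.  Cloudiness (`"ci"`) is accepted for
#'   overlay purposes; the simulator has no diffuse-radiation pathway,
#'   so that curve is flat by construction.
#' @param n_grid Grid resolution; the grid spans the observed range.
#' @param mean_alpha Climatological moisture index passed through.
#' @param params A [pmodel_params()] object.
#' @return A data.frame of class `lue_response` (columns `variable`,
#'   `x`, `mu`, `lo`, `hi`; the simulator is deterministic so `lo` and
#'   `hi` equal `mu`).
#' @export
stylized_experiment <- function(composites, variable, n_grid = 100,
                                mean_alpha = 1,
                                params = pmodel_params()) {
  ok_vars <- c("temp", "vpd", "soil_m", "ci", "co2", "elevation")
  if (!variable %in% ok_vars)
    stop("variable must be one of: ", paste(ok_vars, collapse = ", "))
  med <- function(v, default) {
    x <- composites[[v]]
    if (is.null(x) || all(!is.finite(x))) default
    else stats::median(x[is.finite(x)])
  }
  env <- list(temp = med("temp", 15), vpd = med("vpd", 800),
              co2 = med("co2", 400), elevation = med("elevation", 0),
              soil_m = med("soil_m", 0.8), ci = med("ci", 0.3))
  x <- composites[[variable]]
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values of ", variable, " in composites")
  grid <- seq(min(x), max(x), length.out = n_grid)
  env_grid <- env
  env_grid[[variable]] <- grid
  mu <- pmodel_lue(temp = env_grid$temp, vpd = env_grid$vpd,
                   co2 = env_grid$co2, elevation = env_grid$elevation,
                   soil_m = env_grid$soil_m, mean_alpha = mean_alpha,
                   params = params)
  mu <- rep_len(mu, n_grid)   # ci: driver unused, constant response
  out <- data.frame(variable = variable, x = grid, mu = mu, lo = mu,
                    hi = mu, stringsAsFactors = FALSE)
  class(out) <- c("lue_response", "data.frame")
  out
}
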