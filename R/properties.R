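#' Material property set for a fruit-slice drying simulation
#'
#' Bundles the measured regression coefficients and physical constants that
#' define how specific heat, thermal conductivity and the complex relative
#' permittivity of the tissue depend on temperature and wet-basis moisture,
#' together with bulk density, electrical conductivity and the equilibrium
#' moisture content used by the boundary conditions.
#'
#' The default coefficients are the fitted regressions for winter-jujube
#' slices at 27.12 MHz:
#' \itemize{
#'   \item Cp (kJ kg-1 K-1) = 0.043 T + 1.047 W - 1.333
#'   \item k  (W m-1 K-1)   = 0.008 T + 0.675 W - 0.261
#'   \item eps' = 34.519 W + 0.072 T + 46.022
#'   \item eps'' = 319.028 W + 1.150 T + 3.786 W T + 46.952
#' }
#' with T in degrees Celsius and W the wet-basis moisture *fraction* (0-1).
#' The linear Cp and k fits go negative well below the measured range, so
#' evaluated values are clamped at configurable positive floors typical of
#' dry plant solids.
#'
#' @param cp_coeffs numeric(3): coefficients (T, W, intercept) of the
#'   specific-heat regression, result in kJ kg-1 K-1.
#' @param k_coeffs numeric(3): thermal-conductivity regression, W m-1 K-1.
#' @param eps_prime_coeffs numeric(3): dielectric-constant regression
#'   (W, T, intercept), dimensionless.
#' @param eps_loss_coeffs numeric(4): loss-factor regression
#'   (W, T, W*T, intercept), dimensionless.
#' @param rho_s bulk density of the slice, kg/m3.
#' @param sigma ionic electrical conductivity, S/m (0 = pure dielectric).
#' @param Me equilibrium moisture content, kg/kg dry basis.
#' @param cp_floor,k_floor positive clamping floors for Cp (kJ kg-1 K-1)
#'   and k (W m-1 K-1).
#' @param T_range,W_range validity ranges for temperature (degC) and
#'   wet-basis moisture fraction.
#' @return an object of class `material_properties`.
#' @export
material_properties <- function(cp_coeffs = c(0.043, 1.047, -1.333),
                                k_coeffs = c(0.008, 0.675, -0.261),
                                eps_prime_coeffs = c(34.519, 0.072, 46.022),
                                eps_loss_coeffs = c(319.028, 1.150, 3.786, 46.952),
                                rho_s = 1100,
                                sigma = 0,
                                Me = 0.05,
                                cp_floor = 0.85,
                                k_floor = 0.05,
                                T_range = c(15, 100),
                                W_range = c(0, 0.9)) {
  stopifnot(length(cp_coeffs) == 3, length(k_coeffs) == 3,
            length(eps_prime_coeffs) == 3, length(eps_loss_coeffs) == 4)
  if (!is.numeric(rho_s) || rho_s <= 0) stop("rho_s must be > 0")
  if (Me < 0) stop("Me must be >= 0")
  if (cp_floor <= 0 || k_floor <= 0) stop("property floors must be > 0")
  structure(list(
    cp_coeffs = as.numeric(cp_coeffs),
    k_coeffs = as.numeric(k_coeffs),
    eps_prime_coeffs = as.numeric(eps_prime_coeffs),
    eps_loss_coeffs = as.numeric(eps_loss_coeffs),
    rho_s = rho_s, sigma = sigma, Me = Me,
    cp_floor = cp_floor, k_floor = k_floor,
    T_range = as.numeric(T_range), W_range = as.numeric(W_range)
  ), class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Material properties (fruit-slice drying)\n")
  cat(sprintf("  Cp   [kJ/kg/K]: %.3f*T + %.3f*W + (%.3f), floor %.2f\n",
              x$cp_coeffs[1], x$cp_coeffs[2], x$cp_coeffs[3], x$cp_floor))
  cat(sprintf("  k    [W/m/K]  : %.3f*T + %.3f*W + (%.3f), floor %.2f\n",
              x$k_coeffs[1], x$k_coeffs[2], x$k_coeffs[3], x$k_floor))
  cat(sprintf("  eps' [-]      : %.3f*W + %.3f*T + %.3f\n",
              x$eps_prime_coeffs[1], x$eps_prime_coeffs[2], x$eps_prime_coeffs[3]))
  cat(sprintf("  eps''[-]      : %.3f*W + %.3f*T + %.3f*W*T + %.3f\n",
              x$eps_loss_coeffs[1], x$eps_loss_coeffs[2],
              x$eps_loss_coeffs[3], x$eps_loss_coeffs[4]))
  cat(sprintf("  rho_s = %g kg/m3, sigma = %g S/m, Me = %g kg/kg db\n",
              x$rho_s, x$sigma, x$Me))
  invisible(x)
}

# Validate or clamp (T, W) against the configured validity ranges.
# check = TRUE  -> error naming the offending variable;
# check = FALSE -> silently clamp into range (used inside the PDE solver,
#                  where transient excursions past the measured range are
#                  handled by constant extrapolation).
check_TW <- function(mat, T, W, check) {
  if (check) {
    if (any(T < mat$T_range[1] | T > mat$T_range[2]))
      stop(sprintf("temperature T outside validity range [%g, %g] degC",
                   mat$T_range[1], mat$T_range[2]))
    if (any(W < mat$W_range[1] | W > mat$W_range[2]))
      stop(sprintf("moisture W outside validity range [%g, %g] (wet-basis fraction)",
                   mat$W_range[1], mat$W_range[2]))
    list(T = T, W = W)
  } else {
    list(T = pmin(pmax(T, mat$T_range[1]), mat$T_range[2]),
         W = pmin(pmax(W, mat$W_range[1]), mat$W_range[2]))
  }
}

#' Specific heat of the tissue
#'
#' Evaluates the linear regression Cp(T, W) and clamps at the configured
#' positive floor.
#'
#' @param mat a [material_properties()] object.
#' @param T temperature, degC.
#' @param W wet-basis moisture fraction (0-1).
#' @param check if TRUE (default), error on out-of-range inputs; if FALSE,
#'   clamp inputs into the validity range (constant extrapolation).
#' @return specific heat, kJ kg-1 K-1 (vectorised).
#' @export
specific_heat <- function(mat, T, W, check = TRUE) {
  v <- check_TW(mat, T, W, check)
  raw <- mat$cp_coeffs[1] * v$T + mat$cp_coeffs[2] * v$W + mat$cp_coeffs[3]
  pmax(raw, mat$cp_floor)
}

#' Thermal conductivity of the tissue
#'
#' @inheritParams specific_heat
#' @return thermal conductivity, W m-1 K-1 (vectorised, clamped at the floor).
#' @export
thermal_conductivity <- function(mat, T, W, check = TRUE) {
  v <- check_TW(mat, T, W, check)
  raw <- mat$k_coeffs[1] * v$T + mat$k_coeffs[2] * v$W + mat$k_coeffs[3]
  pmax(raw, mat$k_floor)
}

#' Dielectric constant (real part of relative permittivity) at 27.12 MHz
#'
#' @inheritParams specific_heat
#' @return dimensionless eps' (vectorised).
#' @export
dielectric_constant <- function(mat, T, W, check = TRUE) {
  v <- check_TW(mat, T, W, check)
  mat$eps_prime_coeffs[1] * v$W + mat$eps_prime_coeffs[2] * v$T +
    mat$eps_prime_coeffs[3]
}

#' Dielectric loss factor (imaginary part of relative permittivity) at 27.12 MHz
#'
#' @inheritParams specific_heat
#' @return dimensionless eps'' (vectorised).
#' @export
loss_factor <- function(mat, T, W, check = TRUE) {
  v <- check_TW(mat, T, W, check)
  mat$eps_loss_coeffs[1] * v$W + mat$eps_loss_coeffs[2] * v$T +
    mat$eps_loss_coeffs[3] * v$W * v$T + mat$eps_loss_coeffs[4]
}

#' Dry-air properties at a given temperature
#'
#' Standard dry-air correlations at 101.325 kPa: ideal-gas density,
#' Sutherland viscosity, a constant specific heat (1007 J/kg/K, within 0.5%
#' over 0-150 degC) and a power-law thermal conductivity. Used by the
#' flat-plate convective heat-transfer correlation.
#'
#' @param T_air air temperature, degC, in [0, 150].
#' @return object of class `air_properties`: list with `rho_a` (kg/m3),
#'   `mu_a` (Pa s), `cp_a` (J/kg/K), `k_a` (W/m/K), `T_air` (degC).
#' @export
air_properties <- function(T_air = 60) {
  if (T_air < 0 || T_air > 150)
    stop("T_air outside supported range [0, 150] degC")
  TK <- T_air + 273.15
  rho <- 101325 * 0.0289647 / (8.31446 * TK)            # ideal gas
  mu <- 1.716e-5 * (TK / 273.15)^1.5 * (273.15 + 110.4) / (TK + 110.4)
  k <- 0.02624 * (TK / 300)^0.8646
  structure(list(rho_a = rho, mu_a = mu, cp_a = 1007, k_a = k, T_air = T_air),
            class = "air_properties")
}

#' Latent heat of evaporation of water
#'
#' Linear steam-table correlation h_fg(T) = 2.503e6 - 2386 T, valid over the
#' drying temperature range.
#'
#' @param T temperature, degC.
#' @return latent heat, J/kg (vectorised).
#' @export
latent_heat <- function(T) {
  2.503e6 - 2386 * T
}

#' Convert dry-basis moisture content to liquid-water concentration
#'
#' Under the no-shrinkage assumption the dry-matter mass per unit total
#' volume, rho_dm, is constant, so the moisture concentration field of the
#' diffusion equation is simply C = rho_dm * M_db.
#'
#' @param M_db dry-basis moisture content, kg water / kg dry matter.
#' @param rho_dm dry-matter density, kg dry matter / m3 total volume.
#' @return concentration, kg water / m3.
#' @export
concentration_from_moisture <- function(M_db, rho_dm) {
  if (rho_dm <= 0) stop("rho_dm must be > 0")
  if (any(M_db < 0)) stop("M_db must be >= 0")
  rho_dm * M_db
}

#' @rdname concentration_from_moisture
#' @param C concentration, kg water / m3.
#' @export
moisture_from_concentration <- function(C, rho_dm) {
  if (rho_dm <= 0) stop("rho_dm must be > 0")
  C / rho_dm
}
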