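#' Drying curve container
#'
#' A measured (or simulated) drying curve: time versus dry-basis moisture
#' content, with the initial and equilibrium moisture contents needed to form
#' the moisture ratio.
#'
#' @param times time points, s; strictly increasing, first point 0.
#' @param M_db dry-basis moisture contents, kg/kg, same length as `times`.
#' @param M0_db initial dry-basis moisture (defaults to `M_db[1]`).
#' @param Me_db equilibrium dry-basis moisture content.
#' @return object of class `drying_curve`.
#' @export
drying_curve <- function(times, M_db, M0_db = M_db[1], Me_db = 0.05) {
  times <- as.numeric(times); M_db <- as.numeric(M_db)
  if (length(times) < 2 || length(times) != length(M_db))
    stop("need >= 2 (time, M_db) pairs of equal length")
  if (times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(M_db < 0)) stop("M_db must be nonnegative")
  if (M0_db <= Me_db) stop("degenerate curve: M0_db must exceed Me_db")
  structure(list(times = times, M_db = M_db, M0_db = M0_db, Me_db = Me_db),
            class = "drying_curve")
}

#' Moisture ratio
#'
#' Normalised drying progress MR = (Mt - Me) / (M0 - Me).
#'
#' @param Mt_db moisture content at time t, kg/kg dry basis (vectorised).
#' @param Me_db equilibrium moisture content, kg/kg dry basis.
#' @param M0_db initial moisture content, kg/kg dry basis.
#' @return dimensionless moisture ratio.
#' @export
moisture_ratio <- function(Mt_db, Me_db, M0_db) {
  if (M0_db <= Me_db) stop("degenerate curve: M0_db must exceed Me_db")
  (Mt_db - Me_db) / (M0_db - Me_db)
}

#' Dry- and wet-basis moisture content from sample masses
#'
#' Dry basis: water mass per dry-matter mass; wet basis: water mass per total
#' mass. Both returned in percent.
#'
#' @param Wt total sample mass at time t, g.
#' @param Wd dry-matter mass, g.
#' @return moisture content in percent.
#' @export
dry_basis <- function(Wt, Wd) {
  if (any(Wd <= 0)) stop("dry-matter mass Wd must be > 0")
  if (any(Wt < Wd)) stop("total mass Wt must be >= dry mass Wd")
  (Wt - Wd) / Wd * 100
}

#' @rdname dry_basis
#' @export
wet_basis <- function(Wt, Wd) {
  if (any(Wd <= 0)) stop("dry-matter mass Wd must be > 0")
  if (any(Wt < Wd)) stop("total mass Wt must be >= dry mass Wd")
  (Wt - Wd) / Wt * 100
}

#' Fit the exponential lag model MR = Lf * exp(-S t)
#'
#' Log-linear least squares of ln MR on t. Points with MR <= 0 (possible in
#' noisy tails) are dropped with a warning; at least three positive-MR points
#' are required.
#'
#' @param curve a [drying_curve()] object.
#' @return list with `Lf` (lag factor), `S` (drying coefficient, 1/s) and
#'   `r_squared` of the log-linear fit.
#' @export
fit_lag_model <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  MR <- moisture_ratio(curve$M_db, curve$Me_db, curve$M0_db)
  keep <- MR > 0
  if (any(!keep))
    warning(sprintf("%d point(s) with MR <= 0 excluded from the lag-model fit",
                    sum(!keep)))
  if (sum(keep) < 3)
    stop("fewer than 3 points with MR > 0: cannot fit lag model")
  t <- curve$times[keep]; y <- log(MR[keep])
  fit <- stats::lm(y ~ t)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  list(Lf = exp(unname(co[1])), S = -unname(co[2]), r_squared = r2)
}

#' Mass Biot number from the lag factor
#'
#' Closed-form inversion of the Dincer relation
#' Lf = exp(0.2533 Bi / (1.3 + Bi)):  Bi = 1.3 ln Lf / (0.2533 - ln Lf).
#' Lf <= 1 maps to the Bi = 0 boundary (with a warning); Lf >= exp(0.2533)
#' is outside the model (infinite Bi) and errors.
#'
#' @param Lf lag factor (dimensionless).
#' @return mass Biot number (dimensionless).
#' @export
biot_from_lag <- function(Lf) {
  if (Lf >= exp(0.2533))
    stop(sprintf("Lf = %g >= exp(0.2533) = %.6f: outside the lag-factor model",
                 Lf, exp(0.2533)))
  if (Lf <= 1) {
    warning("Lf <= 1: returning the Bi = 0 boundary")
    return(0)
  }
  l <- log(Lf)
  1.3 * l / (0.2533 - l)
}

#' First eigenvalue approximation mu1(Bi)
#'
#' Dincer's explicit approximation for the first root of the slab eigenvalue
#' equation: mu1 = pi/2 for Bi >= 100, else atan(0.640443 Bi + 0.380397).
#'
#' @param Bi mass Biot number.
#' @return mu1 in radians.
#' @export
mu1_from_biot <- function(Bi) {
  ifelse(Bi >= 100, pi / 2, atan(0.640443 * Bi + 0.380397))
}

#' Moisture diffusivity from the drying coefficient (Dincer relation)
#'
#' D = S * L_half^2 / mu1^2.
#'
#' @param S drying coefficient, 1/s.
#' @param L_half characteristic half-thickness, m.
#' @param mu1 first eigenvalue, rad.
#' @return diffusivity, m2/s.
#' @export
diffusivity_dincer <- function(S, L_half, mu1) {
  S * L_half^2 / mu1^2
}

#' Convective mass-transfer coefficient from Biot number and diffusivity
#'
#' hm = Bi * D / L_half.
#'
#' @param Bi mass Biot number.
#' @param D moisture diffusivity, m2/s.
#' @param L_half characteristic half-thickness, m.
#' @return mass-transfer coefficient, m/s.
#' @export
mass_transfer_coeff <- function(Bi, D, L_half) {
  Bi * D / L_half
}

#' Full Dincer-model kinetics fit
#'
#' Chains the lag-model fit, Biot inversion, eigenvalue rule, diffusivity and
#' mass-transfer-coefficient estimators on a drying curve.
#'
#' @param curve a [drying_curve()] object.
#' @param L_half characteristic half-thickness of the slab, m. For one-sided
#'   drying (evaporation from the top surface only) this is the full slice
#'   thickness, since a one-sided slab is equivalent to half of a symmetric
#'   slab of double thickness.
#' @return object of class `dincer_fit`: list with Lf, S, Bi, mu1, D, hm and
#'   r_squared.
#' @export
fit_dincer <- function(curve, L_half = 0.008) {
  lag <- fit_lag_model(curve)
  Bi <- biot_from_lag(lag$Lf)
  mu1 <- mu1_from_biot(Bi)
  D <- diffusivity_dincer(lag$S, L_half, mu1)
  hm <- mass_transfer_coeff(Bi, D, L_half)
  structure(list(Lf = lag$Lf, S = lag$S, Bi = Bi, mu1 = mu1, D = D, hm = hm,
                 r_squared = lag$r_squared, L_half = L_half),
            class = "dincer_fit")
}

#' @export
print.dincer_fit <- function(x, ...) {
  cat("Dincer drying-kinetics fit\n")
  cat(sprintf("  Lf = %.5f, S = %.4g 1/s (log-linear R2 = %.4f)\n",
              x$Lf, x$S, x$r_squared))
  cat(sprintf("  Bi = %.4g, mu1 = %.5f rad (L_half = %g m)\n",
              x$Bi, x$mu1, x$L_half))
  cat(sprintf("  D = %.4g m2/s, hm = %.4g m/s\n", x$D, x$hm))
  invisible(x)
}

#' Effective diffusivity by the slope method
#'
#' First-term slab-series reading of the falling-rate period:
#' MR = (8/pi^2) exp(-pi^2 Deff t / (4 L^2)), so
#' Deff = -slope(ln MR vs t) * 4 L^2 / pi^2.
#'
#' @param curve a [drying_curve()] object.
#' @param L_char characteristic slab length, m (full thickness for one-sided
#'   drying).
#' @param window optional integer index range (e.g. `5:12`) selecting the
#'   falling-rate portion; default uses all points with MR > 0.
#' @return effective diffusivity, m2/s, with the fitted slope and R2 as
#'   attributes.
#' @export
eff_diffusivity_slope <- function(curve, L_char, window = NULL) {
  stopifnot(inherits(curve, "drying_curve"))
  MR <- moisture_ratio(curve$M_db, curve$Me_db, curve$M0_db)
  idx <- if (is.null(window)) seq_along(MR) else window
  idx <- idx[MR[idx] > 0]
  if (length(idx) < 3) stop("need >= 3 points with MR > 0 in the window")
  t <- curve$times[idx]; y <- log(MR[idx])
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("curve not drying: nonnegative ln-MR slope")
  D <- -slope * 4 * L_char^2 / pi^2
  ss_tot <- sum((y - mean(y))^2)
  attr(D, "slope") <- slope
  attr(D, "r_squared") <- if (ss_tot == 0) 1 else
    1 - sum(stats::resid(fit)^2) / ss_tot
  D
}

#' Convective heat-transfer coefficient (laminar flat plate)
#'
#' Re = rho_a v L / mu_a; Pr = cp_a mu_a / k_a; Nu = 0.664 Re^0.5 Pr^0.33;
#' h_T = Nu k_a / L. The Prandtl exponent is 0.33 exactly.
#'
#' @param v air speed over the sample, m/s.
#' @param L_char characteristic length (slice diameter), m.
#' @param air an [air_properties()] object.
#' @return h_T in W m-2 K-1, with Re, Pr and Nu as attributes. Warns when Re
#'   exceeds the laminar flat-plate limit 5e5.
#' @export
heat_transfer_coeff <- function(v, L_char, air = air_properties(60)) {
  stopifnot(inherits(air, "air_properties"))
  if (v < 0) stop("air speed must be >= 0")
  Re <- air$rho_a * v * L_char / air$mu_a
  if (Re > 5e5)
    warning(sprintf("Re = %.3g exceeds the laminar flat-plate range (5e5)", Re))
  Pr <- air$cp_a * air$mu_a / air$k_a
  Nu <- 0.664 * Re^0.5 * Pr^0.33
  hT <- Nu * air$k_a / L_char
  attr(hT, "Re") <- Re; attr(hT, "Pr") <- Pr; attr(hT, "Nu") <- Nu
  hT
}
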