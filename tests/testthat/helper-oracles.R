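# Independent analytic oracles for the PDE solvers: transient 1-D slab with a
# Robin (convective) boundary, computed from the classical eigenfunction
# series. The slab occupies x in [0, L] with zero flux at x = 0 and
# -k dT/dx = h (T - T_inf) at x = L; eigenvalues solve lambda tan lambda = Bi.

slab_eigenvalues <- function(Bi, n_terms = 20) {
  if (!is.finite(Bi)) return((2 * seq_len(n_terms) - 1) * pi / 2)
  vapply(seq_len(n_terms), function(m) {
    lo <- (m - 1) * pi + 1e-9
    hi <- (m - 1) * pi + pi / 2 - 1e-9
    stats::uniroot(function(l) l * tan(l) - Bi, c(lo, hi), tol = 1e-13)$root
  }, numeric(1))
}

# Normalised excess profile theta(x, t) / theta_initial
slab_series_profile <- function(x, t, L, alpha, Bi, n_terms = 20) {
  lam <- slab_eigenvalues(Bi, n_terms)
  Cn <- 2 * sin(lam) / (lam + sin(lam) * cos(lam))
  Fo <- alpha * t / L^2
  sapply(x, function(xx)
    sum(Cn * cos(lam * xx / L) * exp(-lam^2 * Fo)))
}

# Spatially averaged normalised content (moisture ratio for the mass case)
slab_series_mean <- function(t, L, alpha, Bi, n_terms = 20) {
  lam <- slab_eigenvalues(Bi, n_terms)
  Bn <- 2 * sin(lam)^2 / (lam * (lam + sin(lam) * cos(lam)))
  vapply(t, function(tt) sum(Bn * exp(-lam^2 * alpha * tt / L^2)), numeric(1))
}

# Forward Dincer model: exact MR curve for a chosen Biot number and
# diffusivity (used to test the inverse pipeline)
dincer_forward <- function(times, Bi, D, L_half) {
  Lf <- exp(0.2533 * Bi / (1.3 + Bi))
  mu1 <- if (Bi >= 100) pi / 2 else atan(0.640443 * Bi + 0.380397)
  S <- D * mu1^2 / L_half^2
  list(MR = Lf * exp(-S * times), Lf = Lf, S = S, mu1 = mu1)
}

# Small, fast configuration for coupled-run tests (coarse grid, large step,
# short horizon); scientific content identical to the default set-up
tiny_config <- function(t_end = 1800, dt = 5, rf_stage = FALSE) {
  cfg <- default_config()
  cfg$geometry$nr <- 4
  cfg$geometry$nz <- 4
  cfg$solver$dt <- dt
  cfg$solver$record_every <- 60
  if (rf_stage) {
    cfg$schedule$t_end <- t_end
    cfg$schedule$stages <- list(list(start = 0, end = t_end, rf_on = TRUE))
  } else {
    cfg$schedule$t_end <- t_end
    cfg$schedule$stages <- list(list(start = 0, end = t_end, rf_on = FALSE))
  }
  cfg
}
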