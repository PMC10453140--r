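test_that("moisture ratio is the normalised drying progress", {
  expect_equal(moisture_ratio(3.9, 0.1, 3.9), 1)
  expect_equal(moisture_ratio(0.1, 0.1, 3.9), 0)
  expect_equal(moisture_ratio(2.0, 0.1, 3.9), 0.5)
  expect_error(moisture_ratio(1, 2, 2), "degenerate")
})

test_that("dry- and wet-basis moisture are consistent with each other", {
  expect_equal(dry_basis(10, 2), 400)
  expect_equal(wet_basis(10, 2), 80)
  expect_equal(dry_basis(5, 5), 0)
  expect_equal(wet_basis(5, 5), 0)
  for (Wt in c(3, 7, 12)) {
    db <- dry_basis(Wt, 2); wb <- wet_basis(Wt, 2)
    expect_equal(wb, db / (1 + db / 100), tolerance = 1e-12)
  }
  expect_error(dry_basis(1, 0))
  expect_error(wet_basis(1, 2))
})

test_that("lag-model fit recovers exact exponentials to machine precision", {
  t <- seq(0, 9000, length.out = 10)
  Lf <- 1.10; S <- 2e-4; Me <- 0.1; M0 <- 4
  M <- Me + (M0 - Me) * Lf * exp(-S * t)
  cv <- drying_curve(t, M, M0_db = M0, Me_db = Me)
  fit <- fit_lag_model(cv)
  expect_equal(fit$Lf, Lf, tolerance = 1e-10)
  expect_equal(fit$S, S, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("lag-model fit of a constant curve gives S = 0, Lf = 1", {
  t <- seq(0, 1000, 100)
  cv <- drying_curve(t, rep(4, length(t)), M0_db = 4, Me_db = 0.1)
  fit <- fit_lag_model(cv)
  expect_equal(fit$S, 0)
  expect_equal(fit$Lf, 1)
})

test_that("nonpositive-MR points are excluded with a warning", {
  t <- seq(0, 5000, 500)
  M <- 0.1 + 3.9 * exp(-1e-3 * t)
  M[10:11] <- 0.05                       # below Me -> MR < 0
  cv <- drying_curve(t, M, M0_db = 4, Me_db = 0.1)
  expect_warning(fit <- fit_lag_model(cv), "excluded")
  expect_gt(fit$S, 0)
  short <- drying_curve(c(0, 10, 20), c(4, 0.05, 0.04), M0_db = 4, Me_db = 0.1)
  expect_warning(expect_error(fit_lag_model(short), "fewer than 3"))
})

test_that("noisy lag-model recovery stays within 5% (Monte Carlo)", {
  t <- seq(0, 12000, length.out = 25)
  Lf <- 1.15; S <- 1.5e-4
  errs <- matrix(NA_real_, 100, 2)
  set.seed(42)
  for (i in 1:100) {
    MR <- pmax(Lf * exp(-S * t) + rnorm(length(t), 0, 0.01), 1e-6)
    M <- 0.1 + 3.8 * MR
    cv <- drying_curve(t, M, M0_db = 3.9, Me_db = 0.1)
    fit <- fit_lag_model(cv)
    errs[i, ] <- abs(c(fit$Lf - Lf, fit$S - S) / c(Lf, S))
  }
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)
})

test_that("Biot inversion is the exact inverse of the lag-factor relation", {
  expect_equal(biot_from_lag(exp(0.2533 / 2.3)), 1, tolerance = 1e-12)
  for (Bi in c(0.1, 1, 10, 99)) {
    Lf <- exp(0.2533 * Bi / (1.3 + Bi))
    expect_equal(biot_from_lag(Lf), Bi, tolerance = 1e-10)
  }
  expect_lt(biot_from_lag(1 + 1e-9), 1e-6)   # Lf -> 1+ gives Bi -> 0
  expect_warning(expect_equal(biot_from_lag(0.99), 0), "Bi = 0")
  expect_error(biot_from_lag(1.30), "outside")
})

test_that("mu1 rule matches its two branches and is nearly continuous", {
  expect_equal(mu1_from_biot(100), pi / 2)
  expect_equal(mu1_from_biot(1), atan(1.020840), tolerance = 1e-6)
  below <- mu1_from_biot(99.999999)
  expect_lt(abs(below - pi / 2) / (pi / 2), 0.01)
})

test_that("Dincer diffusivity and mass-transfer relations are dimensional", {
  expect_equal(diffusivity_dincer(2e-4, 0.004, 0.79573), 5.0538e-9,
               tolerance = 1e-4)
  expect_equal(diffusivity_dincer(2e-4, 0.008, 0.79573) /
                 diffusivity_dincer(2e-4, 0.004, 0.79573), 4)
  # with mu1 = pi/2 the relation inverts the first-term series rate exactly
  D_true <- 3e-9; L <- 0.005
  S <- pi^2 * D_true / (4 * L^2)
  expect_equal(diffusivity_dincer(S, L, pi / 2), D_true, tolerance = 1e-14)
  expect_equal(mass_transfer_coeff(1, 5.054e-9, 0.004), 1.2635e-6)
  expect_equal(mass_transfer_coeff(0, 5.054e-9, 0.004), 0)
})

test_that("full Dincer pipeline round-trips forward-generated curves", {
  L <- 0.008
  for (Bi in c(0.5, 2, 20)) {
    D <- 5e-9
    t <- seq(0, 20000, length.out = 30)
    fwd <- dincer_forward(t, Bi, D, L)
    M <- 0.05 + 3.85 * fwd$MR
    # M(0) = Me + (M0-Me)*Lf, so pass the true M0 defining MR = 1
    cv <- drying_curve(t, M, M0_db = 0.05 + 3.85, Me_db = 0.05)
    fit <- fit_dincer(cv, L_half = L)
    expect_equal(fit$Bi, Bi, tolerance = 1e-6)
    expect_equal(fit$D, D, tolerance = 1e-6)
    expect_equal(fit$hm, Bi * D / L, tolerance = 1e-6)
  }
})

test_that("noisy Dincer pipeline recovers Bi, D, hm within 10% (median)", {
  L <- 0.008; Bi <- 2; D <- 5e-9
  t <- seq(0, 20000, length.out = 30)
  fwd <- dincer_forward(t, Bi, D, L)
  errs <- matrix(NA_real_, 100, 3)
  set.seed(7)
  for (i in 1:100) {
    MR <- pmax(fwd$MR + rnorm(length(t), 0, 0.01), 1e-6)
    cv <- drying_curve(t, 0.05 + 3.85 * MR, M0_db = 3.9, Me_db = 0.05)
    fit <- try(fit_dincer(cv, L_half = L), silent = TRUE)
    if (inherits(fit, "try-error")) next
    errs[i, ] <- abs(c(fit$Bi - Bi, fit$D - D, fit$hm - Bi * D / L) /
                       c(Bi, D, Bi * D / L))
  }
  med <- apply(errs, 2, stats::median, na.rm = TRUE)
  expect_true(all(med < 0.10))
})

test_that("slope-method diffusivity matches the slab series", {
  L <- 0.008; D <- 1e-9
  # exact first-term curve -> machine-precision recovery
  t <- seq(0, 40000, length.out = 20)
  MR1 <- 8 / pi^2 * exp(-pi^2 * D * t / (4 * L^2))
  cv <- drying_curve(t, 0.05 + 3.85 * MR1, M0_db = 3.9, Me_db = 0.05)
  expect_equal(as.numeric(eff_diffusivity_slope(cv, L)), D, tolerance = 1e-10)
  # 20-term series truth, fitted on late times only
  t2 <- seq(0, 60000, length.out = 60)
  MR20 <- slab_series_mean(t2, L, D, Inf, n_terms = 20)
  cv2 <- drying_curve(t2, 0.05 + 3.85 * MR20, M0_db = 3.9, Me_db = 0.05)
  D_fit <- eff_diffusivity_slope(cv2, L, window = 20:60)
  expect_lt(abs(D_fit - D) / D, 0.03)
  # noisy: median bias < 5% over 100 seeds
  set.seed(11)
  Ds <- replicate(100, {
    MRn <- pmax(MR20 + rnorm(length(t2), 0, 0.01), 1e-6)
    cvn <- drying_curve(t2, 0.05 + 3.85 * MRn, M0_db = 3.9, Me_db = 0.05)
    tryCatch(eff_diffusivity_slope(cvn, L, window = 20:60),
             error = function(e) NA_real_)
  })
  expect_lt(abs(stats::median(Ds, na.rm = TRUE) - D) / D, 0.05)
  # a flat curve is rejected
  flat <- drying_curve(c(0, 10, 20, 30), rep(3.9, 4), M0_db = 3.9, Me_db = 0.05)
  expect_error(eff_diffusivity_slope(flat, L), "not drying")
})

test_that("flat-plate heat-transfer chain reproduces Re, Pr, Nu, h_T", {
  air <- air_properties(60)
  h <- heat_transfer_coeff(2.5, 0.03, air)
  Re <- air$rho_a * 2.5 * 0.03 / air$mu_a
  Pr <- air$cp_a * air$mu_a / air$k_a
  Nu <- 0.664 * sqrt(Re) * Pr^0.33
  expect_equal(attr(h, "Re"), Re)
  expect_equal(as.numeric(h), Nu * air$k_a / 0.03, tolerance = 1e-12)
  expect_equal(Re, 3975, tolerance = 1e-3)
  expect_equal(Pr, 0.700, tolerance = 2e-3)
  expect_equal(as.numeric(h), 35.7, tolerance = 2e-3)
  expect_equal(as.numeric(heat_transfer_coeff(0, 0.03, air)), 0)
  # h_T scales as sqrt(v)
  expect_equal(as.numeric(heat_transfer_coeff(4 * 2.5, 0.03, air)),
               2 * as.numeric(h), tolerance = 1e-12)
  expect_warning(heat_transfer_coeff(5000, 0.03, air), "laminar")
})

test_that("drying_curve validates its invariants", {
  expect_error(drying_curve(c(1, 2), c(1, 1)), "start at 0")
  expect_error(drying_curve(c(0, 0), c(1, 1)), "increasing")
  expect_error(drying_curve(c(0, 1), c(1, -1)), "nonnegative")
  expect_error(drying_curve(c(0, 1), c(0.1, 0.1), M0_db = 0.1, Me_db = 0.2),
               "degenerate")
})
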