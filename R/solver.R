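#' Axisymmetric finite-volume grid for a cylindrical slice
#'
#' Cell-centred grid on the (r, z) cross-section of a cylinder of given
#' radius and thickness. Cell volumes are the axisymmetric ring volumes
#' 2 pi r dr dz; they sum to pi R^2 H exactly.
#'
#' @param radius slice radius, m.
#' @param thickness slice thickness, m.
#' @param nr,nz number of cells radially and vertically (>= 4 each).
#' @return object of class `drying_grid`.
#' @export
drying_grid <- function(radius = 0.015, thickness = 0.008, nr = 9, nz = 8) {
  if (nr < 4 || nz < 4) stop("nr and nz must both be >= 4")
  if (radius <= 0 || thickness <= 0) stop("radius and thickness must be > 0")
  dr <- radius / nr; dz <- thickness / nz
  n <- nr * nz
  i_of <- rep(1:nr, nz); k_of <- rep(1:nz, each = nr)
  r_c <- (i_of - 0.5) * dr
  z_c <- (k_of - 0.5) * dz
  vol <- 2 * pi * r_c * dr * dz

  # Interior faces (p, q, area, distance); radial then vertical
  pr <- qr <- ar <- numeric(0)
  if (nr > 1) {
    i <- rep(1:(nr - 1), nz); k <- rep(1:nz, each = nr - 1)
    pr <- (k - 1) * nr + i; qr <- pr + 1
    ar <- 2 * pi * (i * dr) * dz
  }
  i <- rep(1:nr, nz - 1); k <- rep(1:(nz - 1), each = nr)
  pz <- (k - 1) * nr + i; qz <- pz + nr
  az <- 2 * pi * ((i - 0.5) * dr) * dr

  top_cells <- (nz - 1) * nr + 1:nr
  bottom_cells <- 1:nr
  side_cells <- (1:nz) * nr
  structure(list(
    radius = radius, thickness = thickness, nr = nr, nz = nz,
    dr = dr, dz = dz, n = n, i_of = i_of, k_of = k_of,
    r_c = r_c, z_c = z_c, vol = vol,
    face_p = c(pr, pz), face_q = c(qr, qz),
    face_area = c(ar, az),
    face_d = c(rep(dr, length(pr)), rep(dz, length(pz))),
    top_cells = top_cells, top_area = 2 * pi * r_c[top_cells] * dr,
    bottom_cells = bottom_cells, bottom_area = 2 * pi * r_c[bottom_cells] * dr,
    side_cells = side_cells, side_area = rep(2 * pi * radius * dz, nz),
    center_cell = (ceiling(nz / 2) - 1) * nr + 1
  ), class = "drying_grid")
}

#' Boundary specification for the coupled solver
#'
#' Convective and evaporative boundary settings: which faces exchange heat
#' convectively and which lose moisture evaporatively, with the associated
#' transfer coefficients. Default (one-sided drying on a tray): top face
#' convective + evaporative, lateral face convective only, bottom face
#' adiabatic and impermeable.
#'
#' @param h_T convective heat-transfer coefficient, W m-2 K-1.
#' @param h_m convective mass-transfer coefficient, m/s.
#' @param T_air drying-air temperature, degC.
#' @param C_eq equilibrium surface moisture concentration, kg/m3
#'   (rho_dm * Me).
#' @param faces named list with logical `conv`/`evap` flags for `top`,
#'   `side`, `bottom`.
#' @return object of class `boundary_spec`.
#' @export
boundary_spec <- function(h_T, h_m, T_air = 60, C_eq,
                          faces = list(top = list(conv = TRUE, evap = TRUE),
                                       side = list(conv = TRUE, evap = FALSE),
                                       bottom = list(conv = FALSE,
                                                     evap = FALSE))) {
  if (h_T < 0 || h_m < 0) stop("transfer coefficients must be >= 0")
  structure(list(h_T = h_T, h_m = h_m, T_air = T_air, C_eq = C_eq,
                 faces = faces),
            class = "boundary_spec")
}

# Sum `vals` into bins 1..n given by `idx`
accum <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Boundary face table: cell index, face area, half-distance to the face,
# conv/evap flags -- derived from grid + boundary_spec
boundary_faces <- function(grid, bnd) {
  list(
    cells = c(grid$top_cells, grid$side_cells, grid$bottom_cells),
    area = c(grid$top_area, grid$side_area, grid$bottom_area),
    half = c(rep(grid$dz / 2, length(grid$top_cells)),
             rep(grid$dr / 2, length(grid$side_cells)),
             rep(grid$dz / 2, length(grid$bottom_cells))),
    conv = c(rep(bnd$faces$top[["conv"]], length(grid$top_cells)),
             rep(bnd$faces$side[["conv"]], length(grid$side_cells)),
             rep(bnd$faces$bottom[["conv"]], length(grid$bottom_cells))),
    evap = c(rep(bnd$faces$top[["evap"]], length(grid$top_cells)),
             rep(bnd$faces$side[["evap"]], length(grid$side_cells)),
             rep(bnd$faces$bottom[["evap"]], length(grid$bottom_cells)))
  )
}

#' One backward-Euler step of the axisymmetric heat equation
#'
#' rho_s Cp dT/dt = div(k grad T) + Q_rf, with Robin boundary faces
#' k dT/dn = U_T (T_air - T_s) - h_fg J_evap on convective/evaporative faces
#' (U_T folds the half-cell conduction resistance into the film coefficient)
#' and the evaporative mass flux J_evap = U_m (C_s - C_eq) taken at the
#' supplied concentration iterate.
#'
#' @param grid a [drying_grid()].
#' @param T_old temperature field at time t, degC (length `grid$n`).
#' @param C_used concentration iterate used for the evaporative sink, kg/m3.
#' @param k_node,rhocp_node nodal thermal conductivity (W/m/K) and volumetric
#'   heat capacity rho_s*Cp (J/m3/K).
#' @param D_node nodal moisture diffusivity (m2/s), for the evaporative-flux
#'   surface resistance.
#' @param q_node volumetric source, W/m3.
#' @param bnd a [boundary_spec()].
#' @param dt time step, s.
#' @return list: `T` (new field), and the step's discrete energy-budget terms
#'   `conv_W`, `evap_W`, `q_W`, `stored_W` (watts).
#' @keywords internal
heat_step <- function(grid, T_old, C_used, k_node, rhocp_node, D_node,
                      q_node, bnd, dt) {
  n <- grid$n
  if (all(k_node <= 0)) stop("singular system: all-zero thermal conductivity")
  p <- grid$face_p; q <- grid$face_q
  kf <- 2 * k_node[p] * k_node[q] / (k_node[p] + k_node[q])
  tr <- kf * grid$face_area / grid$face_d
  cap <- rhocp_node * grid$vol / dt

  bf <- boundary_faces(grid, bnd)
  U_T <- ifelse(bf$conv, 1 / (1 / bnd$h_T + bf$half / k_node[bf$cells]), 0)
  U_m <- ifelse(bf$evap & bnd$h_m > 0,
                1 / (1 / bnd$h_m + bf$half / D_node[bf$cells]), 0)
  J_evap <- U_m * (C_used[bf$cells] - bnd$C_eq)      # kg m-2 s-1
  hfg <- latent_heat(T_old[bf$cells])

  A <- matrix(0, n, n)
  A[cbind(p, q)] <- -tr
  A[cbind(q, p)] <- -tr
  dg <- cap + accum(p, tr, n) + accum(q, tr, n) +
    accum(bf$cells, U_T * bf$area, n)
  diag(A) <- dg
  b <- cap * T_old + q_node * grid$vol
  b <- b + accum(bf$cells, U_T * bf$area * bnd$T_air, n) -
    accum(bf$cells, hfg * J_evap * bf$area, n)
  T_new <- solve(A, b)

  conv_W <- sum(U_T * bf$area * (bnd$T_air - T_new[bf$cells]))
  evap_W <- sum(hfg * J_evap * bf$area)
  list(T = as.numeric(T_new),
       conv_W = conv_W, evap_W = evap_W,
       q_W = sum(q_node * grid$vol),
       stored_W = sum(cap * (T_new - T_old)))
}

#' One backward-Euler step of the axisymmetric moisture-diffusion equation
#'
#' dC/dt = div(D_eff grad C), with evaporative faces
#' -D_eff dC/dn = U_m (C_s - C_eq) (implicit in C) and zero flux elsewhere.
#'
#' @inheritParams heat_step
#' @param C_old concentration field at time t, kg/m3.
#' @return list: `C` (new field), `evap_kg_s` (boundary outflux, kg/s) and
#'   `stored_kg_s` (rate of change of stored moisture, kg/s).
#' @keywords internal
mass_step <- function(grid, C_old, D_node, bnd, dt) {
  if (any(D_node < 0)) stop("negative moisture diffusivity")
  n <- grid$n
  p <- grid$face_p; q <- grid$face_q
  Df <- 2 * D_node[p] * D_node[q] / pmax(D_node[p] + D_node[q], 1e-300)
  tr <- Df * grid$face_area / grid$face_d
  cap <- grid$vol / dt

  bf <- boundary_faces(grid, bnd)
  U_m <- ifelse(bf$evap & bnd$h_m > 0,
                1 / (1 / bnd$h_m + bf$half / D_node[bf$cells]), 0)

  A <- matrix(0, n, n)
  A[cbind(p, q)] <- -tr
  A[cbind(q, p)] <- -tr
  diag(A) <- cap + accum(p, tr, n) + accum(q, tr, n) +
    accum(bf$cells, U_m * bf$area, n)
  b <- cap * C_old + accum(bf$cells, U_m * bf$area * bnd$C_eq, n)
  C_new <- as.numeric(solve(A, b))

  evap <- sum(U_m * bf$area * (C_new[bf$cells] - bnd$C_eq))
  list(C = C_new, evap_kg_s = evap,
       stored_kg_s = sum(cap * (C_new - C_old)))
}

# Arrhenius moisture diffusivity (constant when arrhenius = FALSE)
d_eff_node <- function(transport, T) {
  if (!isTRUE(transport$arrhenius)) return(rep(transport$D_ref, length(T)))
  TK <- T + 273.15; TrefK <- transport$T_ref + 273.15
  transport$D_ref * exp(-transport$Ea / 8.31446 * (1 / TK - 1 / TrefK))
}

# RF field magnitude at solver nodes (layered closed form or 2-D Laplace),
# given nodal permittivity fields. Returns a vector of |E| (V/m) per node.
sample_field <- function(sys, eps_p, eps_pp) {
  rfc <- sys$rf
  if (identical(sys$ctrl$field_mode, "2d")) {
    g <- sys$grid
    z0 <- rfc$sample_offset
    emg <- em_grid(r_max = sys$ctrl$em_rmax_factor * g$radius,
                   gap = rfc$gap, nr = sys$ctrl$em_nr, nz = sys$ctrl$em_nz)
    eps_map <- matrix(1 + 0i, emg$nr, emg$nz)
    sig_map <- matrix(0, emg$nr, emg$nz)
    rc <- rep(emg$r_cells, emg$nz); zc <- rep(emg$z_cells, each = emg$nr)
    inside <- rc < g$radius & zc > z0 & zc < z0 + g$thickness
    if (any(inside)) {
      ii <- pmin(pmax(ceiling(rc[inside] / g$dr), 1), g$nr)
      kk <- pmin(pmax(ceiling((zc[inside] - z0) / g$dz), 1), g$nz)
      pidx <- (kk - 1) * g$nr + ii
      eps_map[inside] <- complex(real = eps_p[pidx], imaginary = -eps_pp[pidx])
      sig_map[inside] <- sys$mat$sigma
    }
    sol <- laplace_2d(emg, eps_map, sigma_map = sig_map,
                      f = rfc$f, v_top = rfc$v_top)
    ii <- pmin(pmax(ceiling(g$r_c / emg$dr), 1), emg$nr)
    kk <- pmin(pmax(ceiling((z0 + g$z_c) / emg$dz), 1), emg$nz)
    sol$E_mag[cbind(ii, kk)]
  } else {
    # Layered mode: series-capacitor field with the volume-averaged sample
    # permittivity, applied uniformly over the slice
    wts <- sys$grid$vol / sum(sys$grid$vol)
    eps_s <- complex(real = sum(eps_p * wts), imaginary = -sum(eps_pp * wts))
    lay <- rfc$layers
    lay$eps[lay$role == "sample"] <- eps_s
    lay$sigma[lay$role == "sample"] <- sys$mat$sigma
    fld <- layered_field(rfc$v_top, lay, rfc$f)
    rep(fld$E_mag[which(lay$role == "sample")[1]], sys$grid$n)
  }
}

#' Advance the coupled temperature-moisture state by one time step
#'
#' Picard iteration: material properties (and, on its refresh cadence, the RF
#' field) are evaluated at the current iterate, then one backward-Euler heat
#' step and one mass step are taken; iteration stops when successive iterates
#' change by less than the configured tolerances.
#'
#' @param state list with `t`, `T`, `C`, `rf_on` and the internal field cache.
#' @param sys internal system assembled by [run_drying()] (grid, material,
#'   boundary, transport, rf, control settings).
#' @param dt time step, s.
#' @return updated state, with the step's audit terms attached as
#'   `state$step_audit` and the Picard iteration count as `state$picard_iters`.
#' @keywords internal
step_coupled <- function(state, sys, dt) {
  grid <- sys$grid; mat <- sys$mat; ctrl <- sys$ctrl
  rho_dm <- sys$rho_dm
  T_it <- state$T; C_it <- state$C
  hs <- ms <- NULL; qn <- rep(0, grid$n); q_total <- 0
  converged <- FALSE
  for (iter in seq_len(ctrl$max_picard)) {
    M_it <- C_it / rho_dm
    W_it <- M_it / (1 + M_it)
    cp <- specific_heat(mat, T_it, W_it, check = FALSE) * 1000   # J/kg/K
    kth <- thermal_conductivity(mat, T_it, W_it, check = FALSE)
    D_it <- d_eff_node(sys$transport, T_it)
    if (isTRUE(state$rf_on) && !is.null(sys$rf)) {
      fc <- state$field_cache
      if (is.null(fc) ||
          max(abs(T_it - fc$T_at)) > ctrl$field_dT ||
          max(abs(M_it - fc$M_at)) > ctrl$field_dM) {
        eps_p <- dielectric_constant(mat, T_it, W_it, check = FALSE)
        eps_pp <- loss_factor(mat, T_it, W_it, check = FALSE)
        E_node <- sample_field(sys, eps_p, eps_pp)
        state$field_cache <- fc <- list(E = E_node, T_at = T_it, M_at = M_it)
      }
      eps_pp_loc <- loss_factor(mat, T_it, W_it, check = FALSE)
      qn <- q_rf(fc$E, eps_pp_loc, sys$rf$f) + mat$sigma * fc$E^2
    } else {
      qn <- rep(0, grid$n)
    }
    hs <- heat_step(grid, state$T, C_it, kth, mat$rho_s * cp, D_it, qn,
                    sys$bnd, dt)
    ms <- mass_step(grid, state$C, D_it, sys$bnd, dt)
    dT <- max(abs(hs$T - T_it))
    dC <- max(abs(ms$C - C_it)) / max(mean(abs(C_it)), 1e-12)
    T_it <- hs$T; C_it <- ms$C
    if (dT < ctrl$tol_T && dC < ctrl$tol_C) { converged <- TRUE; break }
  }
  if (!converged && ctrl$max_picard > 1)
    stop(sprintf(paste0("Picard iteration did not converge in %d iterations ",
                        "at t = %g s: reduce the time step"),
                 ctrl$max_picard, state$t))
  state$T <- T_it; state$C <- C_it
  state$t <- state$t + dt
  state$picard_iters <- iter
  state$step_audit <- list(
    conv_J = hs$conv_W * dt, evap_heat_J = hs$evap_W * dt,
    rf_J = hs$q_W * dt, stored_J = hs$stored_W * dt,
    evap_kg = ms$evap_kg_s * dt, stored_kg = ms$stored_kg_s * dt,
    q_total_W = hs$q_W)
  state
}

#' Run a staged drying simulation
#'
#' Integrates the coupled heat and moisture equations over a drying schedule
#' (RF toggled per stage), recording volume-averaged moisture, centre and
#' mean top-surface temperatures at a fixed cadence, and accumulating
#' discrete energy- and moisture-budget audits.
#'
#' @param config a run configuration, see [default_config()]. May be a
#'   partial list; missing entries take their defaults.
#' @param quiet suppress the per-stage progress messages.
#' @return object of class `drying_result`: list with `timeseries`
#'   (data.frame: t_s, T_center_C, T_surface_mean_C, M_db, M_wb, rf_on,
#'   Q_rf_total_W), `audit` (energy and mass budgets with relative
#'   residuals), `schedule`, `final_state` and the expanded `config`.
#' @export
run_drying <- function(config = default_config(), quiet = FALSE) {
  config <- merge_config(config)
  sys <- build_system(config)
  sched <- if (config$schedule$t_end == 0 && is.null(config$schedule$stages))
    data.frame(start = numeric(0), end = numeric(0), rf_on = logical(0))
  else build_schedule(config)
  ctrl <- sys$ctrl

  M0 <- config$initial$wet_basis / (1 - config$initial$wet_basis)
  C0 <- sys$rho_dm * M0
  state <- list(t = 0, T = rep(config$initial$temperature, sys$grid$n),
                C = rep(C0, sys$grid$n), rf_on = FALSE, field_cache = NULL)

  audit <- list(conv_J = 0, evap_heat_J = 0, rf_J = 0, stored_J = 0,
                evap_kg = 0, stored_kg = 0)
  rec <- list(); q_now <- 0
  snap <- function(st, q_total) {
    Mbar <- sum(st$C * sys$grid$vol) / sum(sys$grid$vol) / sys$rho_dm
    data.frame(t_s = st$t,
               T_center_C = st$T[sys$grid$center_cell],
               T_surface_mean_C = sum(st$T[sys$grid$top_cells] *
                                        sys$grid$top_area) /
                 sum(sys$grid$top_area),
               M_db = Mbar, M_wb = Mbar / (1 + Mbar),
               rf_on = st$rf_on, Q_rf_total_W = q_total)
  }
  rec[[1]] <- snap(state, 0)
  next_rec <- ctrl$record_every

  if (!quiet) {
    chars <- utf8ToInt(yaml::as.yaml(config))
    cfg_hash <- sum(chars * (seq_along(chars) %% 97 + 1)) %% 1e9
    message(sprintf("rfdry %s | config hash %09.0f | seed %s",
                    as.character(utils::packageVersion("rfdry")), cfg_hash,
                    format(config$seed)))
  }
  for (s in seq_len(nrow(sched))) {
    state$rf_on <- sched$rf_on[s]
    state$field_cache <- NULL
    wall0 <- Sys.time()
    if (!quiet)
      message(sprintf("stage %d: [%g, %g] s, RF %s", s, sched$start[s],
                      sched$end[s], if (sched$rf_on[s]) "on" else "off"))
    while (state$t < sched$end[s] - 1e-9) {
      dt <- min(ctrl$dt, sched$end[s] - state$t)
      state <- step_coupled(state, sys, dt)
      sa <- state$step_audit
      audit$conv_J <- audit$conv_J + sa$conv_J
      audit$evap_heat_J <- audit$evap_heat_J + sa$evap_heat_J
      audit$rf_J <- audit$rf_J + sa$rf_J
      audit$stored_J <- audit$stored_J + sa$stored_J
      audit$evap_kg <- audit$evap_kg + sa$evap_kg
      audit$stored_kg <- audit$stored_kg + sa$stored_kg
      q_now <- sa$q_total_W
      if (state$t >= next_rec - 1e-9 || state$t >= sched$end[s] - 1e-9) {
        rec[[length(rec) + 1]] <- snap(state, q_now)
        if (state$t >= next_rec - 1e-9)
          next_rec <- next_rec + ctrl$record_every
      }
    }
    if (!quiet)
      message(sprintf("  stage %d done in %.1f s wall clock", s,
                      as.numeric(Sys.time() - wall0, units = "secs")))
  }
  ts <- do.call(rbind, rec)
  ts <- ts[!duplicated(ts$t_s), , drop = FALSE]
  rownames(ts) <- NULL

  ein <- audit$conv_J - audit$evap_heat_J + audit$rf_J
  escale <- abs(audit$conv_J) + abs(audit$evap_heat_J) + abs(audit$rf_J)
  audit$energy_residual_rel <- abs(audit$stored_J - ein) / max(escale, 1e-300)
  audit$mass_residual_rel <- abs(audit$stored_kg + audit$evap_kg) /
    max(abs(audit$evap_kg), 1e-300)

  structure(list(timeseries = ts, audit = audit, schedule = sched,
                 final_state = state, config = config),
            class = "drying_result")
}

#' @export
print.drying_result <- function(x, ...) {
  ts <- x$timeseries
  cat(sprintf("Drying simulation: %s, %g s, %d records\n",
              x$config$schedule$scenario, max(ts$t_s), nrow(ts)))
  cat(sprintf("  M_db: %.3f -> %.3f kg/kg db; T_center: %.1f -> %.1f degC\n",
              ts$M_db[1], ts$M_db[nrow(ts)], ts$T_center_C[1],
              ts$T_center_C[nrow(ts)]))
  cat(sprintf("  budget residuals: energy %.2e, moisture %.2e (relative)\n",
              x$audit$energy_residual_rel, x$audit$mass_residual_rel))
  invisible(x)
}

#' Time at which the mean moisture content first reaches a target
#'
#' Linear interpolation of the recorded volume-averaged dry-basis moisture;
#' `Inf` if the target is never reached within the simulated window.
#'
#' @param result a [run_drying()] result.
#' @param target target mean moisture content, kg/kg dry basis.
#' @return time in seconds (possibly `Inf`).
#' @export
time_to_moisture <- function(result, target = 1.0) {
  ts <- result$timeseries
  below <- which(ts$M_db <= target)
  if (length(below) == 0) return(Inf)
  j <- below[1]
  if (j == 1) return(ts$t_s[1])
  t0 <- ts$t_s[j - 1]; t1 <- ts$t_s[j]
  m0 <- ts$M_db[j - 1]; m1 <- ts$M_db[j]
  t0 + (m0 - target) / (m0 - m1) * (t1 - t0)
}
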