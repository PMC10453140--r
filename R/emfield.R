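#' Radio-frequency applicator configuration
#'
#' Geometry and electrical settings of the parallel-plate RF applicator: the
#' operating frequency, plate spacing, top-electrode potential (the bottom
#' plate is grounded) and the vertical stack of dielectric layers between the
#' plates. The default stack is: 20 mm air below the sample (tray offset),
#' 8 mm sample, 82 mm air above, summing to the 110 mm gap.
#'
#' @param f frequency, Hz.
#' @param gap plate spacing, m.
#' @param v_top top-electrode potential (RMS), V.
#' @param layers data.frame with columns `thickness` (m, bottom to top),
#'   `eps` (complex relative permittivity eps' - i eps'') and optionally
#'   `sigma` (S/m, default 0). Thicknesses must sum to `gap`.
#' @param plate_area opposing plate area, m2.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(f = 27.12e6,
                      gap = 0.110,
                      v_top = 11000,
                      layers = NULL,
                      plate_area = 0.80 * 0.43) {
  if (f <= 0) stop("frequency must be > 0")
  if (is.null(layers)) {
    layers <- data.frame(thickness = c(0.020, 0.008, 0.082),
                         eps = c(1 + 0i, 77 - 550i, 1 + 0i),
                         sigma = 0)
    layers$role <- c("air", "sample", "air")
  }
  if (is.null(layers$sigma)) layers$sigma <- 0
  if (any(layers$thickness <= 0)) stop("all layer thicknesses must be > 0")
  if (abs(sum(layers$thickness) - gap) > 1e-9 * gap)
    stop("rf.layers: layer thicknesses must sum to the plate gap")
  structure(list(f = f, eps0 = 8.854e-12, gap = gap, v_top = v_top,
                 layers = layers, plate_area = plate_area),
            class = "rf_config")
}

#' Electric field in a stack of dielectric layers between parallel plates
#'
#' One-dimensional series-capacitor solution of the quasi-static field: the
#' normal component of the total current density J = kappa E, with admittivity
#' kappa = sigma + i omega eps0 eps*, is continuous across layer interfaces,
#' and the layer voltages sum to the applied potential. Hence
#' J = V / sum(d_j / kappa_j) and E_i = J / kappa_i.
#'
#' @param v_top applied potential (RMS), V.
#' @param layers data.frame as in [rf_config()].
#' @param f frequency, Hz.
#' @return list with complex per-layer field `E` (V/m), current density `J`
#'   (A/m2), and `E_mag = Mod(E)`.
#' @export
layered_field <- function(v_top, layers, f = 27.12e6) {
  if (nrow(layers) < 1) stop("need at least one layer")
  if (any(layers$thickness <= 0)) stop("zero-thickness layer")
  if (any(Mod(layers$eps) == 0)) stop("zero-permittivity layer")
  sig <- if (is.null(layers$sigma)) rep(0, nrow(layers)) else layers$sigma
  w <- 2 * pi * f
  kappa <- sig + 1i * w * 8.854e-12 * layers$eps
  J <- v_top / sum(layers$thickness / kappa)
  E <- J / kappa
  list(E = E, J = J, E_mag = Mod(E))
}

#' Volumetric RF heat source
#'
#' Power density deposited by the RF field: Q = 2 pi f eps0 eps'' |E|^2
#' (RMS field convention).
#'
#' @param E_mag electric field magnitude, V/m (vectorised).
#' @param eps_loss dielectric loss factor eps'' (vectorised).
#' @param f frequency, Hz.
#' @return power density, W/m3.
#' @export
q_rf <- function(E_mag, eps_loss, f = 27.12e6) {
  2 * pi * f * 8.854e-12 * eps_loss * E_mag^2
}

#' Rectangular axisymmetric grid for the 2-D field solver
#'
#' Node-based grid spanning the electrode gap vertically (0 = grounded lower
#' plate, `gap` = energised upper plate) and `r_max` radially. Material
#' properties live on cells; the potential on nodes.
#'
#' @param r_max radial extent of the computational domain, m.
#' @param gap plate spacing, m.
#' @param nr,nz number of cells radially and vertically.
#' @return list with node/cell coordinates and spacings.
#' @export
em_grid <- function(r_max, gap, nr, nz) {
  if (nr < 2 || nz < 2) stop("nr, nz must be >= 2")
  dr <- r_max / nr; dz <- gap / nz
  list(r_max = r_max, gap = gap, nr = nr, nz = nz, dr = dr, dz = dz,
       r_nodes = (0:nr) * dr, z_nodes = (0:nz) * dz,
       r_cells = ((1:nr) - 0.5) * dr, z_cells = ((1:nz) - 0.5) * dz)
}

# Solve a complex sparse linear system A x = b via the equivalent real
# 2n x 2n block system using Matrix's sparse LU.
solve_complex_sparse <- function(i, j, x, b, n) {
  ii <- c(i, i + n, i, i + n)
  jj <- c(j, j + n, j + n, j)
  xx <- c(Re(x), Re(x), -Im(x), Im(x))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * n, 2 * n))
  rhs <- c(Re(b), Im(b))
  sol <- as.numeric(Matrix::solve(A, rhs))
  complex(real = sol[1:n], imaginary = sol[(n + 1):(2 * n)])
}

#' 2-D quasi-static complex Laplace field solver
#'
#' Solves -div((sigma + i omega eps0 eps*) grad V) = 0 on an axisymmetric
#' node-based finite-volume grid with V = `v_top` on the upper plate, V = 0 on
#' the grounded lower plate, and insulating (zero normal current) boundaries
#' on the axis and the open radial edge. Cell admittivities are area-weighted
#' on control-volume faces, which reproduces the layered-capacitor solution
#' exactly for horizontally stratified media.
#'
#' @param grid an [em_grid()] object.
#' @param eps_map complex nr x nz matrix (or scalar) of relative permittivity
#'   eps' - i eps'' per cell.
#' @param sigma_map nr x nz matrix (or scalar) of electrical conductivity, S/m.
#' @param f frequency, Hz.
#' @param v_top top-plate potential (RMS), V.
#' @return object of class `field_solution`: complex nodal potential `V`
#'   ((nr+1) x (nz+1)), cell fields `Er`, `Ez`, `E_mag`, `Q` (W/m3, from the
#'   loss factor), cell volumes, dissipated power `P_diss` (W), top-plate
#'   current `I_top` (A) and complex power `P_circuit` = v_top * Conj(I_top).
#' @export
laplace_2d <- function(grid, eps_map, sigma_map = 0, f = 27.12e6, v_top) {
  nr <- grid$nr; nz <- grid$nz
  if (length(eps_map) == 1) eps_map <- matrix(eps_map, nr, nz)
  if (length(sigma_map) == 1) sigma_map <- matrix(sigma_map, nr, nz)
  stopifnot(all(dim(eps_map) == c(nr, nz)), all(dim(sigma_map) == c(nr, nz)))
  w <- 2 * pi * f
  kappa <- sigma_map + 1i * w * 8.854e-12 * eps_map   # cell admittivity, S/m
  nrn <- nr + 1; nzn <- nz + 1; n <- nrn * nzn
  pid <- function(i, j) (j - 1) * nrn + i
  dr <- grid$dr; dz <- grid$dz
  rn <- grid$r_nodes

  # Half-annulus areas of the node control volumes (for vertical faces)
  a_left <- pi * (rn^2 - pmax(rn - dr / 2, 0)^2)   # 0 on the axis node
  a_right <- pi * (pmin(rn + dr / 2, grid$r_max)^2 - rn^2)  # 0 on outer node

  # Face lists: fp -- fq node pairs with complex admittance ft (S)
  fp <- integer(0); fq <- integer(0); ft <- complex(0)
  iidx <- 1:nrn
  # Vertical faces: node (i,j) -- (i,j+1), through cell layer j; admittivity
  # area-weighted over the cells left (i-1) and right (i) of the node column.
  for (j in 1:nz) {
    kl <- kappa[pmax(iidx - 1, 1), j]            # cell i-1 (guarded by area 0)
    kr <- kappa[pmin(iidx, nr), j]               # cell i   (guarded by area 0)
    tt <- (kl * a_left + kr * a_right) / dz
    fp <- c(fp, pid(iidx, j)); fq <- c(fq, pid(iidx, j + 1)); ft <- c(ft, tt)
  }
  # Radial faces: node (i,j) -- (i+1,j), through cell column i; admittivity
  # weighted over the half-cells below (j-1) and above (j) the node level.
  rface <- (rn[1:nr] + rn[2:nrn]) / 2
  for (j in 1:nzn) {
    tb <- if (j > 1) kappa[, j - 1] * (dz / 2) else complex(nr)
    tt2 <- if (j <= nz) kappa[, j] * (dz / 2) else complex(nr)
    tt <- 2 * pi * rface * (tb + tt2) / dr
    fp <- c(fp, pid(1:nr, j)); fq <- c(fq, pid(2:nrn, j)); ft <- c(ft, tt)
  }

  # Symmetric Laplacian triplets from the face list
  ti <- c(fp, fq, fp, fq); tj <- c(fp, fq, fq, fp); tx <- c(ft, ft, -ft, -ft)

  # Dirichlet: bottom row grounded, top row at v_top
  dir_top <- pid(1:nrn, nzn)
  is_dir <- logical(n); is_dir[c(pid(1:nrn, 1), dir_top)] <- TRUE
  vdir <- numeric(n); vdir[dir_top] <- v_top

  b <- complex(n)
  move <- !is_dir[ti] & is_dir[tj]      # free row, known column -> RHS
  for (k in which(move)) b[ti[k]] <- b[ti[k]] - tx[k] * vdir[tj[k]]
  keep <- !is_dir[ti] & !is_dir[tj]
  dir_idx <- which(is_dir)
  ti2 <- c(ti[keep], dir_idx); tj2 <- c(tj[keep], dir_idx)
  tx2 <- c(tx[keep], rep(1 + 0i, length(dir_idx)))
  b[is_dir] <- vdir[is_dir]

  Vv <- solve_complex_sparse(ti2, tj2, tx2, b, n)
  V <- matrix(Vv, nrn, nzn)

  # Cell-centred field components from nodal potentials
  Ez <- -((V[1:nr, 2:nzn] + V[2:nrn, 2:nzn]) -
          (V[1:nr, 1:nz] + V[2:nrn, 1:nz])) / (2 * dz)
  Er <- -((V[2:nrn, 1:nz] + V[2:nrn, 2:nzn]) -
          (V[1:nr, 1:nz] + V[1:nr, 2:nzn])) / (2 * dr)
  E2 <- Mod(Er)^2 + Mod(Ez)^2
  eps_loss <- -Im(eps_map)
  Q <- q_rf(sqrt(E2), eps_loss, f) + sigma_map * E2
  vol <- outer(2 * pi * grid$r_cells * dr * dz, rep(1, nz))
  P_diss <- sum(Q * vol)

  # Top-plate current from the vertical-face admittances below the top row
  tt_top <- (kappa[pmax(iidx - 1, 1), nz] * a_left +
             kappa[pmin(iidx, nr), nz] * a_right) / dz
  I_top <- sum(tt_top * (v_top - Vv[pid(iidx, nz)]))
  structure(list(V = V, Er = Er, Ez = Ez, E_mag = sqrt(E2), Q = Q,
                 cell_volumes = vol, P_diss = P_diss, I_top = I_top,
                 P_circuit = v_top * Conj(I_top), grid = grid, f = f,
                 v_top = v_top),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Quasi-static field solution: %d x %d cells, V_top = %g V\n",
              x$grid$nr, x$grid$nz, x$v_top))
  cat(sprintf("  |E| range: %.4g - %.4g V/m\n", min(x$E_mag), max(x$E_mag)))
  cat(sprintf("  dissipated power %.4g W; Re(V conj(I)) = %.4g W\n",
              x$P_diss, Re(x$P_circuit)))
  invisible(x)
}

#' Write a field solution to delimited grid files
#'
#' Dumps the field magnitude and volumetric power of a [laplace_2d()]
#' solution as tab-delimited matrices whose header row and first column name
#' the cell-centre r and z coordinates in metres (`<path>_Emag.tsv`,
#' `<path>_Qrf.tsv`).
#'
#' @param sol a `field_solution`.
#' @param path output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_field_snapshot <- function(sol, path) {
  stopifnot(inherits(sol, "field_solution"))
  g <- sol$grid
  dump1 <- function(M, suffix) {
    f <- paste0(path, "_", suffix, ".tsv")
    df <- data.frame(r_m = g$r_cells, M)
    names(df) <- c("r_m", sprintf("z_%g", g$z_cells))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    f
  }
  invisible(c(dump1(sol$E_mag, "Emag"), dump1(sol$Q, "Qrf")))
}

#' Calibrate the top-electrode voltage against a reference drying record
#'
#' Emulates the trial-and-error electrode-voltage adjustment: a bracketed
#' scalar search over `v_top` minimising the (range-normalised) sum of
#' squared residuals between simulated and reference moisture and/or
#' centre-temperature series.
#'
#' @param reference data.frame with column `t_s` and one or both of `M_db`
#'   and `T_center_C`.
#' @param config a run configuration (see [default_config()]); its schedule
#'   must include at least one RF-on stage.
#' @param bounds numeric(2) search bracket for v_top, V.
#' @param weights named numeric weights for the `moisture` and `temperature`
#'   residual terms.
#' @param tol absolute search tolerance on v_top (default: 1e-4 of the
#'   bracket width).
#' @return list with `v_top`, the final `objective`, and the number of
#'   simulator `evaluations`.
#' @export
calibrate_voltage <- function(reference, config,
                              bounds = c(2000, 30000),
                              weights = c(moisture = 1, temperature = 1),
                              tol = NULL) {
  stopifnot(is.data.frame(reference), "t_s" %in% names(reference))
  cols <- intersect(c("M_db", "T_center_C"), names(reference))
  if (length(cols) == 0)
    stop("reference must contain an M_db and/or T_center_C column")
  sched <- build_schedule(config)
  if (!any(sched$rf_on))
    stop("objective independent of v_top: schedule has no RF-on stage")
  if (is.null(tol)) tol <- diff(bounds) * 1e-4
  n_eval <- 0L
  objective <- function(v) {
    n_eval <<- n_eval + 1L
    cfg <- config; cfg$rf$v_top <- v
    res <- run_drying(cfg, quiet = TRUE)
    ts <- res$timeseries
    ss <- 0
    for (col in cols) {
      simv <- stats::approx(ts$t_s, ts[[col]], xout = reference$t_s,
                            rule = 2)$y
      rng <- diff(range(reference[[col]]))
      if (rng == 0) rng <- 1
      wgt <- if (col == "M_db") weights[["moisture"]] else weights[["temperature"]]
      ss <- ss + wgt * sum(((simv - reference[[col]]) / rng)^2)
    }
    ss
  }
  opt <- stats::optimize(objective, interval = bounds, tol = tol)
  edge <- 0.02 * diff(bounds)
  if (opt$minimum < bounds[1] + edge || opt$minimum > bounds[2] - edge)
    stop("minimum at the bracket edge: widen the v_top search bounds")
  list(v_top = opt$minimum, objective = opt$objective, evaluations = n_eval)
}
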