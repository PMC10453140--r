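#' Default run configuration
#'
#' The canonical configuration of a drying run: a single 8 mm x 30 mm
#' cylindrical slice at 79.6% initial wet-basis moisture, dried by 60 degC /
#' 2.5 m/s air for 4.5 h, with an optional 27.12 MHz parallel-plate RF field
#' (110 mm gap, slice sitting 20 mm above the grounded lower plate).
#' All lengths are SI metres, temperatures degC, times seconds.
#'
#' Blocks:
#' \describe{
#'   \item{material}{regression coefficients and constants, see
#'     [material_properties()].}
#'   \item{air}{`temperature` (degC), `velocity` (m/s), `char_length` (m,
#'     slice diameter used in the Reynolds number).}
#'   \item{rf}{`f` (Hz), `gap` (m), `v_top` (V), `field_mode`
#'     ("layered" or "2d"), `sample_offset` (m, height of the slice base
#'     above the lower plate), `plate_area` (m2).}
#'   \item{geometry}{`radius`, `thickness` (m), `nr`, `nz` cells.}
#'   \item{boundary}{`h_T` (W/m2/K; NULL = computed from the flat-plate
#'     correlation), `h_m` (m/s), face flags.}
#'   \item{transport}{`D_ref` (m2/s at `T_ref` degC), `Ea` (J/mol),
#'     `arrhenius` (logical).}
#'   \item{solver}{`dt` (s), `max_picard`, `tol_T` (degC), `tol_C`
#'     (relative), `record_every` (s), field refresh thresholds `field_dT`
#'     (degC) and `field_dM` (kg/kg), 2-D field grid sizes.}
#'   \item{schedule}{`scenario` name or explicit `stages`; `t_end` (s).}
#'   \item{initial}{`temperature` (degC), `wet_basis` (fraction).}
#' }
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    material = list(
      cp_coeffs = c(0.043, 1.047, -1.333),
      k_coeffs = c(0.008, 0.675, -0.261),
      eps_prime_coeffs = c(34.519, 0.072, 46.022),
      eps_loss_coeffs = c(319.028, 1.150, 3.786, 46.952),
      rho_s = 1100, sigma = 0, Me = 0.05,
      cp_floor = 0.85, k_floor = 0.05,
      T_range = c(15, 100), W_range = c(0, 0.9)
    ),
    air = list(temperature = 60, velocity = 2.5, char_length = 0.03),
    rf = list(
      f = 27.12e6, gap = 0.110, v_top = 11000,
      field_mode = "layered", sample_offset = 0.020,
      plate_area = 0.80 * 0.43,
      layers = NULL   # NULL = air below / sample / air above from geometry
    ),
    geometry = list(radius = 0.015, thickness = 0.008, nr = 9, nz = 8),
    boundary = list(
      h_T = NULL, h_m = 3e-6,
      faces = list(top = list(conv = TRUE, evap = TRUE),
                   side = list(conv = TRUE, evap = FALSE),
                   bottom = list(conv = FALSE, evap = FALSE))
    ),
    transport = list(D_ref = 6.5e-9, T_ref = 60, Ea = 30000, arrhenius = TRUE),
    solver = list(dt = 1, max_picard = 8, tol_T = 1e-3, tol_C = 1e-6,
                  record_every = 60, field_dT = 0.5, field_dM = 0.05,
                  em_nr = 30, em_nz = 110, em_rmax_factor = 2),
    schedule = list(scenario = "HA", t_end = 16200, stages = NULL),
    initial = list(temperature = 22, wet_basis = 0.796),
    seed = 1
  )
}

# Recursively overlay user values onto the defaults, rejecting unknown keys
# with a path-qualified message. Leaves (non-list defaults) are replaced
# wholesale.
overlay <- function(def, usr, path = "") {
  if (!is.list(usr)) return(usr)
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key: %s%s", path, unknown[1]))
  for (nm in names(usr)) {
    if (is.null(usr[[nm]])) next       # explicit null = keep the default
    sub <- paste0(path, nm, ".")
    # schedule$stages, rf$layers and boundary$faces are free-form lists
    if (is.list(def[[nm]]) && !is.null(def[[nm]]) &&
        !nm %in% c("stages", "layers", "faces")) {
      def[[nm]] <- overlay(def[[nm]], usr[[nm]], sub)
    } else {
      def[[nm]] <- usr[[nm]]
    }
  }
  def
}

#' Complete a partial configuration with defaults and validate it
#'
#' @param config partial nested configuration list (possibly empty).
#' @return the completed configuration.
#' @export
merge_config <- function(config = list()) {
  if (isTRUE(attr(config, "merged"))) return(config)
  cfg <- overlay(default_config(), config)
  validate_config(cfg)
  attr(cfg, "merged") <- TRUE
  cfg
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$nr < 4 || g$nz < 4) stop("geometry.nr and geometry.nz must be >= 4")
  if (g$radius <= 0 || g$thickness <= 0)
    stop("geometry.radius and geometry.thickness must be > 0")
  if (cfg$solver$dt <= 0) stop("solver.dt must be > 0")
  if (cfg$solver$tol_T <= 0 || cfg$solver$tol_C <= 0)
    stop("solver tolerances must be > 0")
  if (!is.null(cfg$rf$layers)) {
    th <- vapply(cfg$rf$layers, function(l) l$thickness, numeric(1))
    if (any(th <= 0)) stop("rf.layers: thicknesses must be > 0")
    if (abs(sum(th) - cfg$rf$gap) > 1e-9 * cfg$rf$gap)
      stop("rf.layers: layer thicknesses must sum to rf.gap")
  } else {
    if (cfg$rf$sample_offset + g$thickness >= cfg$rf$gap)
      stop("rf.gap too small for rf.sample_offset + geometry.thickness")
  }
  if (cfg$initial$wet_basis <= 0 || cfg$initial$wet_basis >= 1)
    stop("initial.wet_basis must be in (0, 1)")
  if (!cfg$rf$field_mode %in% c("layered", "2d"))
    stop("rf.field_mode must be 'layered' or '2d'")
  invisible(cfg)
}

# Assemble the internal system objects (grid, material, boundary, transport,
# RF stack, control settings) from a completed configuration.
build_system <- function(config) {
  m <- config$material
  mat <- material_properties(
    cp_coeffs = m$cp_coeffs, k_coeffs = m$k_coeffs,
    eps_prime_coeffs = m$eps_prime_coeffs,
    eps_loss_coeffs = m$eps_loss_coeffs,
    rho_s = m$rho_s, sigma = m$sigma, Me = m$Me,
    cp_floor = m$cp_floor, k_floor = m$k_floor,
    T_range = m$T_range, W_range = m$W_range)
  g <- config$geometry
  grid <- drying_grid(g$radius, g$thickness, g$nr, g$nz)
  air <- air_properties(config$air$temperature)
  h_T <- config$boundary$h_T
  if (is.null(h_T))
    h_T <- as.numeric(heat_transfer_coeff(config$air$velocity,
                                          config$air$char_length, air))
  rho_dm <- m$rho_s * (1 - config$initial$wet_basis)
  bnd <- boundary_spec(h_T = h_T, h_m = config$boundary$h_m,
                       T_air = config$air$temperature,
                       C_eq = rho_dm * m$Me,
                       faces = config$boundary$faces)

  layers <- config$rf$layers
  if (is.null(layers)) {
    above <- config$rf$gap - config$rf$sample_offset - g$thickness
    layers <- data.frame(thickness = c(config$rf$sample_offset, g$thickness,
                                       above),
                         eps = c(1 + 0i, NA_complex_, 1 + 0i),
                         sigma = 0)
    layers$role <- c("air", "sample", "air")
  } else {
    layers <- do.call(rbind, lapply(layers, function(l) {
      data.frame(thickness = l$thickness,
                 eps = complex(real = if (is.null(l$eps_real)) 1 else l$eps_real,
                               imaginary = -(if (is.null(l$eps_loss)) 0 else l$eps_loss)),
                 sigma = if (is.null(l$sigma)) 0 else l$sigma,
                 role = if (is.null(l$role)) "dielectric" else l$role)
    }))
    if (!any(layers$role == "sample"))
      stop("rf.layers: one layer must have role 'sample'")
  }
  rf <- list(f = config$rf$f, gap = config$rf$gap, v_top = config$rf$v_top,
             layers = layers, sample_offset = config$rf$sample_offset,
             plate_area = config$rf$plate_area)

  ctrl <- config$solver
  ctrl$field_mode <- config$rf$field_mode
  list(grid = grid, mat = mat, air = air, bnd = bnd,
       transport = config$transport, rf = rf, rho_dm = rho_dm, ctrl = ctrl)
}

#' Load a run configuration from a YAML file
#'
#' Parses a human-editable YAML document, overlays it on the defaults
#' (unknown keys are rejected with the offending path) and validates the
#' result. An empty document yields the canonical hot-air run.
#'
#' @param path path to a YAML configuration file.
#' @return completed configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  usr <- yaml::read_yaml(path)
  if (is.null(usr)) usr <- list()
  merge_config(usr)
}

#' Write a configuration to a YAML file
#'
#' @param config configuration list (completed or partial).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- merge_config(config)
  attr(cfg, "merged") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
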