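#' Canonical drying schedules
#'
#' The 4.5 h drying process is divided into three equal stages; RF is either
#' never applied (HA) or applied during exactly one stage: early (E-HA+RF),
#' middle (M-HA+RF) or late (L-HA+RF).
#'
#' @param name one of "HA", "E-HA+RF", "M-HA+RF", "L-HA+RF".
#' @param t_end total drying time, s (default 16200 = 4.5 h).
#' @return data.frame with columns `start`, `end` (s) and `rf_on` (logical),
#'   of class `drying_schedule`.
#' @export
make_schedule <- function(name = c("HA", "E-HA+RF", "M-HA+RF", "L-HA+RF"),
                          t_end = 16200) {
  valid <- c("HA", "E-HA+RF", "M-HA+RF", "L-HA+RF")
  if (!name[1] %in% valid)
    stop(sprintf("unknown scenario '%s'; valid names: %s", name[1],
                 paste(valid, collapse = ", ")))
  name <- name[1]
  edges <- seq(0, t_end, length.out = 4)
  rf <- switch(name,
               "HA" = c(FALSE, FALSE, FALSE),
               "E-HA+RF" = c(TRUE, FALSE, FALSE),
               "M-HA+RF" = c(FALSE, TRUE, FALSE),
               "L-HA+RF" = c(FALSE, FALSE, TRUE))
  sched <- data.frame(start = edges[1:3], end = edges[2:4], rf_on = rf)
  class(sched) <- c("drying_schedule", "data.frame")
  attr(sched, "scenario") <- name
  sched
}

# Schedule from a configuration: canonical scenario name or explicit stages.
# Validates that the stages tile [0, t_end] without gaps or overlaps.
build_schedule <- function(config) {
  config <- merge_config(config)
  sc <- config$schedule
  if (is.null(sc$stages)) return(make_schedule(sc$scenario, sc$t_end))
  st <- do.call(rbind, lapply(sc$stages, function(s)
    data.frame(start = s$start, end = s$end, rf_on = isTRUE(s$rf_on))))
  st <- st[order(st$start), , drop = FALSE]
  if (st$start[1] != 0 || abs(st$end[nrow(st)] - sc$t_end) > 1e-9 ||
      any(abs(st$start[-1] - st$end[-nrow(st)]) > 1e-9))
    stop("schedule.stages must tile [0, t_end] without gaps or overlaps")
  if (any(st$end <= st$start)) stop("schedule stages must have end > start")
  class(st) <- c("drying_schedule", "data.frame")
  st
}

#' Compare a simulated series against a reference series
#'
#' The simulated series is linearly interpolated onto the reference time
#' points; the report gives the determination coefficient R^2 = 1 -
#' SS_res/SS_tot (SS_tot about the reference mean), the maximum and minimum
#' absolute differences and the RMSE. Note R^2 is asymmetric under exchange
#' of the two series (the reference defines SS_tot); max/min/RMSE are
#' symmetric.
#'
#' @param sim data.frame with columns `t_s` and `column` (the simulation).
#' @param ref data.frame with columns `t_s` and `column` (the reference).
#' @param column name of the value column to compare (default "M_db").
#' @return object of class `comparison_report`: list with `r_squared`,
#'   `max_abs_diff`, `min_abs_diff`, `rmse`, `n` and `column`.
#' @export
compare_series <- function(sim, ref, column = "M_db") {
  stopifnot(is.data.frame(sim), is.data.frame(ref))
  for (d in list(sim, ref))
    if (!all(c("t_s", column) %in% names(d)))
      stop(sprintf("both series need columns 't_s' and '%s'", column))
  tt <- ref$t_s[ref$t_s >= min(sim$t_s) & ref$t_s <= max(sim$t_s)]
  if (length(tt) < 3) stop("need >= 3 shared time points")
  rv <- ref[[column]][match(tt, ref$t_s)]
  sv <- stats::approx(sim$t_s, sim[[column]], xout = tt)$y
  ss_tot <- sum((rv - mean(rv))^2)
  if (ss_tot == 0) stop("constant reference series: R^2 undefined")
  d <- sv - rv
  structure(list(r_squared = 1 - sum(d^2) / ss_tot,
                 max_abs_diff = max(abs(d)), min_abs_diff = min(abs(d)),
                 rmse = sqrt(mean(d^2)), n = length(tt), column = column),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison on '%s' (%d shared points)\n", x$column, x$n))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g, |diff| in [%.4g, %.4g]\n",
              x$r_squared, x$rmse, x$min_abs_diff, x$max_abs_diff))
  invisible(x)
}

#' Generate a pseudo-experimental reference curve
#'
#' Runs the simulator for a scenario, resamples the record at the
#' experimental cadence and adds seeded Gaussian noise, standing in for a
#' measured drying record (synthetic: there is no real data behind it). The
#' noise standard deviation is `sigma` times the range of each series, so
#' `sigma = 0` reproduces the simulation exactly. Deterministic per seed.
#'
#' @param scenario canonical scenario name, see [make_schedule()].
#' @param sigma relative noise level (fraction of each series' range).
#' @param seed integer RNG seed.
#' @param config base configuration (scenario is overridden).
#' @param sample_every sampling interval of the pseudo-experiment, s
#'   (default 1800 = 30 min).
#' @return data.frame with columns t_s, M_db, T_center_C, T_surface_mean_C.
#' @export
make_fixture <- function(scenario = "HA", sigma = 0.01, seed = 1,
                         config = default_config(), sample_every = 1800) {
  config <- merge_config(config)
  config$schedule$scenario <- scenario
  config$schedule$stages <- NULL
  res <- run_drying(config, quiet = TRUE)
  ts <- res$timeseries
  tt <- seq(0, max(ts$t_s), by = sample_every)
  out <- data.frame(t_s = tt)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (col in c("M_db", "T_center_C", "T_surface_mean_C")) {
    v <- stats::approx(ts$t_s, ts[[col]], xout = tt)$y
    out[[col]] <- v + stats::rnorm(length(v), 0, sigma * diff(range(v)))
  }
  attr(out, "scenario") <- scenario
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  out
}
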