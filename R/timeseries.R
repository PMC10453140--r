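#' Write a simulation time series to CSV
#'
#' Fixed header: t_s, T_center_C, T_surface_mean_C, M_db, M_wb, rf_on,
#' Q_rf_total_W. Accepts a `drying_result` or its `timeseries` data.frame.
#'
#' @param result a [run_drying()] result or a time-series data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  ts <- if (inherits(result, "drying_result")) result$timeseries else result
  cols <- c("t_s", "T_center_C", "T_surface_mean_C", "M_db", "M_wb",
            "rf_on", "Q_rf_total_W")
  if (nrow(ts) == 0) {
    ts <- stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols))),
                          cols)
  } else {
    for (mc in setdiff(cols, names(ts))) ts[[mc]] <- NA
  }
  utils::write.csv(ts[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a simulation time series from CSV
#'
#' Validates the header and that every row parses to numbers; malformed
#' lines are reported with their line number.
#'
#' @param path path to a CSV written by [write_timeseries()].
#' @return data.frame with the standard time-series columns.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop(sprintf("time-series file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty time-series file")
  cols <- c("t_s", "T_center_C", "T_surface_mean_C", "M_db", "M_wb",
            "rf_on", "Q_rf_total_W")
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(hdr, cols))
    stop(sprintf("unexpected header at line 1: got '%s'", lines[1]))
  if (length(lines) == 1)
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols))),
                           cols))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop(sprintf("malformed CSV at line %d: expected %d fields, found %d",
                 which(nf != length(cols))[1] + 1L, length(cols),
                 nf[nf != length(cols)][1]))
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  for (cc in setdiff(cols, "rf_on")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop(sprintf("malformed CSV at line %d: non-numeric value in '%s'",
                   which(is.na(v))[1] + 1L, cc))
    df[[cc]] <- v
  }
  df$rf_on <- as.logical(df$rf_on)
  df
}
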