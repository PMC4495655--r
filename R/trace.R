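#' Uniformly sampled time series
#'
#' A `trace` is the universal currency of the package: a uniformly sampled
#' time series (light stimulus or neural response) with a sampling interval,
#' a start time and a units label.
#'
#' @param values Numeric vector of samples (finite, length >= 1).
#' @param dt Sampling interval in seconds (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param units Units label, e.g. `"contrast"`, `"R*/s"`, `"a.u."`.
#'
#' @return An object of class `"trace"`: a list with fields `values`, `dt`,
#'   `start_time` and `units`.
#' @examples
#' tr <- trace(sin(seq(0, 1, by = 0.001) * 2 * pi), dt = 0.001)
#' tr
#' head(trace_times(tr))
#' @export
trace <- function(values, dt, start_time = 0, units = "a.u.") {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(start_time, "start_time")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must have length >= 1", call. = FALSE)
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  structure(
    list(values = values, dt = dt, start_time = start_time,
         units = as.character(units)[1L]),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<trace> %d samples, dt = %g s (%.4g s), units = %s\n",
    n, x$dt, n * x$dt, x$units
  ))
  cat(sprintf("  range: [%.4g, %.4g], start = %g s\n",
              min(x$values), max(x$values), x$start_time))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param x A [trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time + (seq_along(x$values) - 1L) * x$dt
}

#' @export
length.trace <- function(x) length(x$values)

#' @export
plot.trace <- function(x, ..., xlab = "time (s)", ylab = x$units, type = "l") {
  graphics::plot(trace_times(x), x$values, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Mean of trace values over a closed time window [from, to].
trace_window_mean <- function(x, from, to) {
  t <- trace_times(x)
  sel <- t >= from & t <= to
  if (!any(sel)) stop("window contains no samples", call. = FALSE)
  mean(x$values[sel])
}

# Integral (rectangle rule) of trace values over [from, to).
trace_integral <- function(x, from, to) {
  t <- trace_times(x)
  sel <- t >= from & t < to
  sum(x$values[sel]) * x$dt
}

check_same_grid <- function(a, b) {
  if (abs(a$dt - b$dt) > 1e-12 * max(a$dt, b$dt)) {
    stop("traces have mismatched dt", call. = FALSE)
  }
  if (length(a$values) != length(b$values)) {
    stop("traces have mismatched lengths", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a raw-intensity stimulus to contrast drive
#'
#' The LN analysis operates on mean-relative fluctuations. This helper maps a
#' raw-intensity trace with background (mean) level `mean_level` to
#' dimensionless contrast drive `(x - mean_level) / mean_level`. Negative
#' drive values are retained: clipping would distort the Gaussianity that
#' reverse correlation relies on.
#'
#' @param x A [trace()] in raw stimulus units.
#' @param mean_level Background level; defaults to the sample mean.
#' @return A [trace()] in `"contrast"` units.
#' @export
contrast_drive <- function(x, mean_level = mean(x$values)) {
  stopifnot(inherits(x, "trace"))
  stopifnot_scalar(mean_level, "mean_level")
  if (mean_level == 0) stop("`mean_level` must be nonzero", call. = FALSE)
  trace((x$values - mean_level) / mean_level, dt = x$dt,
        start_time = x$start_time, units = "contrast")
}

#' Write a trace to CSV (with JSON metadata sidecar)
#'
#' Traces are stored as a two-column CSV with header `time_s,value`, plus a
#' `<path>.json` sidecar recording units, dt and any extra metadata, so a
#' written trace round-trips losslessly through [read_trace()].
#'
#' @param x A [trace()].
#' @param path Output CSV path.
#' @param metadata Optional named list of extra metadata (seed, generator
#'   parameters, ...) stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, metadata = list()) {
  stopifnot(inherits(x, "trace"))
  df <- data.frame(time_s = trace_times(x), value = x$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(units = x$units, dt = x$dt, start_time = x$start_time,
                 n = length(x$values)), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Reads a `time_s,value` CSV written by [write_trace()] (or by any other
#' tool using the same layout) and validates that the time grid is uniform to
#' within a relative tolerance of 1e-9. If a `<path>.json` sidecar exists its
#' units label is restored.
#'
#' @param path CSV path.
#' @return A [trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  if (length(raw) < 2L) stop("empty trace file: ", path, call. = FALSE)
  nfield <- lengths(strsplit(raw, ",", fixed = TRUE))
  bad <- which(nfield != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("ragged row %d in %s: expected 2 fields, found %d",
                 bad[1L], path, nfield[bad[1L]]), call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace CSV must have header `time_s,value`", call. = FALSE)
  }
  tt <- df$time_s
  if (length(tt) < 2L) {
    stop("trace must contain at least 2 samples to define dt", call. = FALSE)
  }
  dts <- diff(tt)
  dt <- stats::median(dts)
  off <- which(abs(dts - dt) > 1e-9 * max(abs(dt), 1e-12))
  if (length(off) > 0L) {
    stop(sprintf("non-uniform time grid in %s at row %d (dt %.12g vs %.12g)",
                 path, off[1L] + 1L, dts[off[1L]], dt), call. = FALSE)
  }
  units <- "a.u."
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$units)) units <- meta$units
  }
  trace(df$value, dt = dt, start_time = tt[1L], units = units)
}
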