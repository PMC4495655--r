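#' Static nonlinearities of the cone bipolar to ganglion cell synapse
#'
#' The LN cascade passes the summed, filtered pathway signals (the generator
#' signal) through a memoryless non-decreasing input-output function. Two
#' closed-form families are provided: threshold-linear (hard rectifier,
#' `baseline + gain * max(x - threshold, 0)`) and softplus (smooth
#' rectifier, `baseline + gain * s * log(1 + exp((x - threshold)/s))`).
#' Estimated nonlinearities from data are represented as knot sequences, see
#' [estimate_nonlinearity()].
#'
#' @param threshold Generator-signal value at which the output turns on.
#'   Positive thresholds produce the rectification that suppresses
#'   sub-threshold inputs.
#' @param gain Output units per generator unit above threshold (> 0).
#' @param baseline Output at strongly negative generator values.
#' @param sharpness Softplus smoothing scale in generator units (> 0);
#'   smaller values approach the hard threshold.
#'
#' @return An object of class `c("nl_threshold_linear", "nonlinearity")` or
#'   `c("nl_softplus", "nonlinearity")`.
#' @examples
#' N <- threshold_linear(threshold = 0.3, gain = 2)
#' nl_eval(N, c(-1, 0.3, 0.8))
#' @export
threshold_linear <- function(threshold = 0, gain = 1, baseline = 0) {
  stopifnot_scalar(threshold, "threshold")
  stopifnot_scalar(gain, "gain", positive = TRUE)
  stopifnot_scalar(baseline, "baseline")
  structure(list(threshold = threshold, gain = gain, baseline = baseline),
            class = c("nl_threshold_linear", "nonlinearity"))
}

#' @rdname threshold_linear
#' @export
softplus_nl <- function(threshold = 0, gain = 1, baseline = 0,
                        sharpness = 0.1) {
  stopifnot_scalar(threshold, "threshold")
  stopifnot_scalar(gain, "gain", positive = TRUE)
  stopifnot_scalar(baseline, "baseline")
  stopifnot_scalar(sharpness, "sharpness", positive = TRUE)
  structure(list(threshold = threshold, gain = gain, baseline = baseline,
                 sharpness = sharpness),
            class = c("nl_softplus", "nonlinearity"))
}

#' Identity nonlinearity
#'
#' Passes the generator signal through unchanged. Under an identity
#' nonlinearity the LN cascade is fully linear, so paired-flash responses
#' equal the sum of the single-flash responses and every interaction index
#' is 0 -- the linearity null used throughout the tests.
#'
#' @return An object of class `c("nl_identity", "nonlinearity")`.
#' @export
identity_nl <- function() {
  structure(list(), class = c("nl_identity", "nonlinearity"))
}

#' Knot-based nonlinearity
#'
#' A monotone piecewise-linear input-output function defined by knots,
#' linearly extrapolated beyond the knot range using the end-segment slopes
#' and floored at `floor_output` (by default the smallest knot output).
#' This is the representation produced by [estimate_nonlinearity()]; the
#' extrapolation rule matters because flash predictions evaluate the
#' nonlinearity outside the range sampled by the noise stimulus.
#'
#' @param x Strictly increasing generator-signal knot positions.
#' @param y Non-decreasing output values at the knots.
#' @param counts Optional per-knot sample counts (from estimation).
#' @param floor_output Lower bound applied after extrapolation; defaults to
#'   `min(y)`.
#' @return An object of class `c("nl_knots", "nonlinearity")`.
#' @export
knot_nl <- function(x, y, counts = NULL, floor_output = min(y)) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need >= 2 knots with matching x and y", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("knot positions must be strictly increasing", call. = FALSE)
  }
  if (any(diff(y) < -1e-12 * max(abs(y), 1))) {
    stop("knot outputs must be non-decreasing", call. = FALSE)
  }
  structure(list(x = x, y = y, counts = counts, floor_output = floor_output),
            class = c("nl_knots", "nonlinearity"))
}

#' Evaluate a nonlinearity
#'
#' @param nl A `"nonlinearity"` object.
#' @param x Numeric vector of generator-signal values.
#' @return Numeric vector of outputs, same length as `x`.
#' @export
nl_eval <- function(nl, x) {
  UseMethod("nl_eval")
}

#' @export
nl_eval.nl_identity <- function(nl, x) as.numeric(x)

#' @export
nl_eval.nl_threshold_linear <- function(nl, x) {
  nl$baseline + nl$gain * pmax(x - nl$threshold, 0)
}

#' @export
nl_eval.nl_softplus <- function(nl, x) {
  z <- (x - nl$threshold) / nl$sharpness
  # numerically stable softplus
  sp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  nl$baseline + nl$gain * nl$sharpness * sp
}

#' @export
nl_eval.nl_knots <- function(nl, x) {
  xs <- nl$x; ys <- nl$y
  n <- length(xs)
  out <- stats::approx(xs, ys, xout = x, rule = 2)$y
  lo_slope <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
  hi_slope <- (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
  below <- x < xs[1L]
  above <- x > xs[n]
  out[below] <- ys[1L] + lo_slope * (x[below] - xs[1L])
  out[above] <- ys[n] + hi_slope * (x[above] - xs[n])
  pmax(out, nl$floor_output)
}

#' @export
print.nonlinearity <- function(x, ...) {
  cls <- class(x)[1L]
  switch(cls,
    nl_identity = cat("<nonlinearity> identity\n"),
    nl_threshold_linear = cat(sprintf(
      "<nonlinearity> threshold-linear: threshold %.4g, gain %.4g, baseline %.4g\n",
      x$threshold, x$gain, x$baseline)),
    nl_softplus = cat(sprintf(
      "<nonlinearity> softplus: threshold %.4g, gain %.4g, baseline %.4g, sharpness %.4g\n",
      x$threshold, x$gain, x$baseline, x$sharpness)),
    nl_knots = cat(sprintf(
      "<nonlinearity> %d knots on [%.4g, %.4g], outputs [%.4g, %.4g]\n",
      length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)))
  )
  invisible(x)
}

#' @export
plot.nonlinearity <- function(x, ..., from = NULL, to = NULL,
                              xlab = "generator signal", ylab = "output") {
  if (is.null(from) || is.null(to)) {
    if (inherits(x, "nl_knots")) {
      rng <- range(x$x)
    } else {
      rng <- c(-1, 1)
    }
    pad <- 0.1 * diff(rng)
    if (is.null(from)) from <- rng[1L] - pad
    if (is.null(to)) to <- rng[2L] + pad
  }
  g <- seq(from, to, length.out = 400L)
  graphics::plot(g, nl_eval(x, g), type = "l", xlab = xlab, ylab = ylab, ...)
  if (inherits(x, "nl_knots")) graphics::points(x$x, x$y, pch = 16, cex = 0.5)
  invisible(x)
}
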