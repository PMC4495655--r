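#' Biphasic temporal filters for rod and cone pathways
#'
#' Constructs the impulse response of a retinal pathway as the difference of
#' two gamma-shaped lobes of shape order 4: a positive lobe peaking at
#' `peak_time` minus a weighted negative lobe peaking at `undershoot_time`.
#' The weight of the negative lobe is solved (by bisection) so that the depth
#' of the composite filter's undershoot relative to its positive peak equals
#' `undershoot_ratio` exactly. The result is peak-normalized to a maximum
#' of 1.
#'
#' Because the two order-4 lobes overlap in time, the extrema of the
#' *composite* filter sit slightly off the lobe peaks: the maximum lands a
#' little before `peak_time` and the minimum a little after
#' `undershoot_time`. The lobe anchors, not the composite extrema, are the
#' construction parameters; the composite undershoot depth is exact.
#'
#' The rod pathway of the mesopic retina is slower and strongly biphasic
#' (the undershoot reflects inhibition in the rod bipolar circuit); the cone
#' pathway is faster and only weakly biphasic. [rod_filter()] and
#' [cone_filter()] encode these presets.
#'
#' @param peak_time Peak time of the positive lobe in seconds.
#' @param undershoot_time Peak time of the negative lobe in seconds
#'   (`peak_time < undershoot_time < duration`).
#' @param undershoot_ratio Depth of the composite undershoot relative to the
#'   composite positive peak, in `[0, 1)`. `0` yields a monophasic
#'   (non-negative) filter.
#' @param dt Sampling interval in seconds.
#' @param duration Filter support in seconds (lags `0 .. duration`).
#' @param pathway Pathway label, `"rod"` or `"cone"`.
#'
#' @return An object of class `"linear_filter"`: list with `taps` (impulse
#'   response over the lag axis starting at lag 0), `dt`, `pathway` and the
#'   generating parameters.
#' @examples
#' f <- rod_filter()
#' f
#' max(f$taps)                      # peak-normalized
#' -min(f$taps) / max(f$taps)       # = undershoot_ratio
#' @export
make_biphasic_filter <- function(peak_time, undershoot_time, undershoot_ratio,
                                 dt = 0.001, duration = 0.5,
                                 pathway = c("rod", "cone")) {
  pathway <- match.arg(pathway)
  stopifnot_scalar(peak_time, "peak_time", positive = TRUE)
  stopifnot_scalar(undershoot_time, "undershoot_time", positive = TRUE)
  stopifnot_scalar(undershoot_ratio, "undershoot_ratio")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (!(peak_time < undershoot_time && undershoot_time < duration)) {
    stop("require 0 < peak_time < undershoot_time < duration", call. = FALSE)
  }
  if (undershoot_ratio < 0 || undershoot_ratio >= 1) {
    stop("`undershoot_ratio` must be in [0, 1)", call. = FALSE)
  }

  lags <- seq(0, duration, by = dt)
  if (undershoot_ratio == 0) {
    taps <- gamma_lobe(lags, peak_time)
  } else {
    r <- solve_undershoot_weight(peak_time, undershoot_time, undershoot_ratio,
                                 duration)
    taps <- gamma_lobe(lags, peak_time) - r * gamma_lobe(lags, undershoot_time)
  }
  taps <- taps / max(taps)

  structure(
    list(taps = taps, dt = dt, pathway = pathway,
         peak_time = peak_time, undershoot_time = undershoot_time,
         undershoot_ratio = undershoot_ratio, duration = duration),
    class = "linear_filter"
  )
}

# Gamma lobe of shape order 4, unit peak at t = tp:
# g(t) = (t/tp)^3 exp(3 (1 - t/tp)), zero for t <= 0.
gamma_lobe <- function(t, tp) {
  s <- t / tp
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- exp(3 * (log(s[pos]) + 1 - s[pos]))
  out
}

# Bisect the negative-lobe weight r so that the composite
# g(t, peak) - r g(t, undershoot) has |min|/max == ratio.
solve_undershoot_weight <- function(peak_time, undershoot_time, ratio,
                                    duration) {
  tg <- seq(0, duration, length.out = 4096L)
  l1 <- gamma_lobe(tg, peak_time)
  l2 <- gamma_lobe(tg, undershoot_time)
  realized <- function(r) {
    v <- l1 - r * l2
    vmax <- max(v)
    if (vmax <= 0) return(Inf)
    max(0, -min(v)) / vmax
  }
  hi <- 1
  while (realized(hi) < ratio && hi < 1e6) hi <- hi * 2
  if (realized(hi) < ratio) {
    stop("cannot reach requested undershoot_ratio", call. = FALSE)
  }
  stats::uniroot(function(r) realized(r) - ratio, c(0, hi),
                 tol = 1e-12)$root
}

#' @rdname make_biphasic_filter
#' @export
rod_filter <- function(dt = 0.001, duration = 0.5) {
  make_biphasic_filter(0.10, 0.20, 0.5, dt = dt, duration = duration,
                       pathway = "rod")
}

#' @rdname make_biphasic_filter
#' @export
cone_filter <- function(dt = 0.001, duration = 0.5) {
  make_biphasic_filter(0.05, 0.12, 0.1, dt = dt, duration = duration,
                       pathway = "cone")
}

#' Construct a linear filter from raw taps
#'
#' Lower-level constructor used when taps come from estimation or from a
#' serialized model rather than from the gamma-lobe family.
#'
#' @param taps Numeric impulse response over the lag axis starting at lag 0.
#' @param dt Sampling interval in seconds.
#' @param pathway Pathway label.
#' @return A `"linear_filter"` object.
#' @export
linear_filter <- function(taps, dt, pathway = "rod") {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  taps <- as.numeric(taps)
  if (length(taps) < 1L) stop("`taps` must be non-empty", call. = FALSE)
  if (!all(is.finite(taps))) stop("`taps` must be finite", call. = FALSE)
  structure(list(taps = taps, dt = dt, pathway = pathway,
                 duration = length(taps) * dt),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("<linear_filter> pathway = %s, %d taps, dt = %g s (%.3g s)\n",
              x$pathway, length(x$taps), x$dt, length(x$taps) * x$dt))
  ip <- which.max(x$taps); im <- which.min(x$taps)
  cat(sprintf("  peak %.3g at %.3g s; min %.3g at %.3g s\n",
              x$taps[ip], (ip - 1L) * x$dt, x$taps[im], (im - 1L) * x$dt))
  invisible(x)
}

#' @export
plot.linear_filter <- function(x, ..., xlab = "lag (s)", ylab = "weight") {
  graphics::plot((seq_along(x$taps) - 1L) * x$dt, x$taps, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Peak-normalize a linear filter
#'
#' Divides the taps by the maximum absolute tap and flips the sign if the
#' dominant excursion is negative, so that every normalized filter has a
#' positive peak of 1 (ON-pathway sign convention).
#'
#' @param filter A `"linear_filter"`.
#' @return A `"linear_filter"` with `max(abs(taps)) == 1` and positive peak.
#' @export
normalize_filter <- function(filter) {
  stopifnot(inherits(filter, "linear_filter"))
  m <- max(abs(filter$taps))
  if (m == 0) stop("cannot normalize an all-zero filter", call. = FALSE)
  taps <- filter$taps / m
  if (max(taps) < -min(taps)) taps <- -taps
  out <- filter
  out$taps <- taps
  out
}
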