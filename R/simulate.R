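#' Simulate retinal output from summed rod and cone pathway signals
#'
#' The mechanistic ground-truth model: rod and cone stimuli (as contrast
#' drive, i.e. deviation from background) are convolved with their pathway
#' filters, the two generator signals are summed, the sum passes through the
#' shared synaptic nonlinearity, and Gaussian noise is added. The
#' convolution is causal (lags >= 0) and approximates the continuous
#' integral, so a unit-area impulse reproduces the filter shape.
#'
#' @param rod_filter,cone_filter `"linear_filter"` objects for the two
#'   pathways (same `dt`).
#' @param nonlinearity A `"nonlinearity"`: the shared synapse.
#' @param rod_stim,cone_stim [trace()] inputs in contrast-drive units (see
#'   [contrast_drive()]); must share `dt` and length. Either may be omitted
#'   (`NULL`) to drive one pathway alone.
#' @param noise_sd Standard deviation of additive Gaussian response noise,
#'   in output units (0 for noise-free).
#' @param seed Integer seed for the response noise.
#' @return A [trace()] of the response, in arbitrary output units.
#' @examples
#' s <- contrast_drive(noise_stimulus(20, duration = 5, seed = 1))
#' z <- trace(numeric(length(s)), dt = s$dt, units = "contrast")
#' r <- simulate_response(rod_filter(), cone_filter(),
#'                        threshold_linear(0.1), s, z)
#' r
#' @export
simulate_response <- function(rod_filter, cone_filter, nonlinearity,
                              rod_stim = NULL, cone_stim = NULL,
                              noise_sd = 0, seed = 1) {
  stopifnot(inherits(nonlinearity, "nonlinearity"))
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(rod_stim) && is.null(cone_stim)) {
    stop("at least one of `rod_stim`, `cone_stim` is required", call. = FALSE)
  }
  ref <- if (!is.null(rod_stim)) rod_stim else cone_stim
  if (!is.null(rod_stim) && !is.null(cone_stim)) {
    check_same_grid(rod_stim, cone_stim)
  }
  dt <- ref$dt
  n <- length(ref$values)

  gen <- numeric(n)
  if (!is.null(rod_stim)) {
    stopifnot(inherits(rod_filter, "linear_filter"))
    if (abs(rod_filter$dt - dt) > 1e-12 * dt) {
      stop("rod filter dt does not match stimulus dt", call. = FALSE)
    }
    gen <- gen + convolve_causal(rod_stim$values, rod_filter$taps, dt)
  }
  if (!is.null(cone_stim)) {
    stopifnot(inherits(cone_filter, "linear_filter"))
    if (abs(cone_filter$dt - dt) > 1e-12 * dt) {
      stop("cone filter dt does not match stimulus dt", call. = FALSE)
    }
    gen <- gen + convolve_causal(cone_stim$values, cone_filter$taps, dt)
  }

  out <- nl_eval(nonlinearity, gen)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  trace(out, dt = dt, start_time = ref$start_time, units = "a.u.")
}

#' Generator signal of one pathway
#'
#' Convolves a contrast-drive stimulus with a pathway filter (causal,
#' integral-scaled). This is the filter-output stage of the LN cascade.
#'
#' @param filter A `"linear_filter"`.
#' @param stimulus A [trace()] in contrast-drive units.
#' @return A [trace()] of the generator signal.
#' @export
generator_signal <- function(filter, stimulus) {
  stopifnot(inherits(filter, "linear_filter"), inherits(stimulus, "trace"))
  if (abs(filter$dt - stimulus$dt) > 1e-12 * stimulus$dt) {
    stop("filter dt does not match stimulus dt", call. = FALSE)
  }
  trace(convolve_causal(stimulus$values, filter$taps, stimulus$dt),
        dt = stimulus$dt, start_time = stimulus$start_time,
        units = "generator")
}

#' Default shared synaptic nonlinearity for a filter pair
#'
#' The rectification threshold that produces clearly nonlinear interactions
#' while keeping responses in range is tied to the operating point of the
#' synapse: the threshold is placed at 0.3 times the standard deviation of
#' the generator signal produced by the standard noise stimulus (50%
#' contrast, 0-60 Hz) summed across the two pathways.
#'
#' @param rod_filter,cone_filter Pathway filters (same `dt`).
#' @param contrast,bandwidth,duration,seed Noise-stimulus parameters used to
#'   probe the generator operating point.
#' @return A [threshold_linear()] nonlinearity with unit gain and zero
#'   baseline.
#' @export
default_nonlinearity <- function(rod_filter, cone_filter,
                                 contrast = 0.5, bandwidth = c(0, 60),
                                 duration = 60, seed = 9120) {
  s1 <- contrast_drive(noise_stimulus(1, contrast = contrast,
                                      bandwidth = bandwidth,
                                      duration = duration,
                                      dt = rod_filter$dt, seed = seed))
  s2 <- contrast_drive(noise_stimulus(1, contrast = contrast,
                                      bandwidth = bandwidth,
                                      duration = duration,
                                      dt = rod_filter$dt, seed = seed + 1))
  g <- generator_signal(rod_filter, s1)$values +
    generator_signal(cone_filter, s2)$values
  threshold_linear(threshold = 0.3 * stats::sd(g), gain = 1, baseline = 0)
}
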