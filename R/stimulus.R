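#' Band-limited Gaussian noise stimulus
#'
#' Generates the noise stimulus used to characterize the LN cascade: a
#' Gaussian sequence with mean `mean_level`, standard deviation
#' `contrast * mean_level`, and power confined to the `bandwidth` frequency
#' band. Band-limiting is a frequency-domain brick wall applied to a white
#' Gaussian sequence, after which the sequence is rescaled to the target
#' standard deviation, so the realized sample SD matches the contrast spec
#' exactly up to the sample-mean correction. The defaults reproduce the
#' standard characterization stimulus: 50% contrast, 0-60 Hz.
#'
#' @param mean_level Mean stimulus intensity (background), in stimulus units.
#' @param contrast Dimensionless contrast (SD / mean), >= 0.
#' @param bandwidth Length-2 numeric, low and high cutoffs in Hz
#'   (`0 <= low < high <= Nyquist`).
#' @param duration Stimulus duration in seconds.
#' @param dt Sampling interval in seconds.
#' @param seed Integer seed; the same seed reproduces the same trace, and no
#'   global RNG state is disturbed.
#'
#' @return A [trace()] in raw intensity units.
#' @examples
#' s <- noise_stimulus(mean_level = 20, duration = 10, seed = 1)
#' c(mean(s$values), stats::sd(s$values))  # ~20 and ~10
#' @export
noise_stimulus <- function(mean_level, contrast = 0.5, bandwidth = c(0, 60),
                           duration = 100, dt = 0.001, seed = 1) {
  stopifnot_scalar(mean_level, "mean_level")
  stopifnot_scalar(contrast, "contrast")
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (contrast < 0) stop("`contrast` must be >= 0", call. = FALSE)
  if (length(bandwidth) != 2L || bandwidth[1L] < 0 ||
      bandwidth[1L] >= bandwidth[2L]) {
    stop("`bandwidth` must be c(low, high) with 0 <= low < high", call. = FALSE)
  }
  nyquist <- 1 / (2 * dt)
  if (bandwidth[2L] > nyquist) {
    stop(sprintf("high cutoff %g Hz exceeds Nyquist %g Hz", bandwidth[2L],
                 nyquist), call. = FALSE)
  }
  n <- round(duration / dt)
  if (n < 2L) stop("`duration` must cover at least 2 samples", call. = FALSE)
  low_res <- if (bandwidth[1L] > 0) 1 / bandwidth[1L] else 1 / bandwidth[2L]
  if (duration < 10 * low_res) {
    warning("duration is short relative to the stimulus bandwidth; ",
            "sample statistics will be imprecise", call. = FALSE)
  }

  if (contrast == 0) {
    return(trace(rep(mean_level, n), dt = dt, units = "intensity"))
  }

  x <- with_seed(seed, stats::rnorm(n))
  xf <- stats::fft(x)
  freq <- seq(0L, n - 1L)
  freq <- pmin(freq, n - freq) / (n * dt)     # two-sided frequency axis
  keep <- freq >= bandwidth[1L] & freq <= bandwidth[2L]
  keep[1L] <- FALSE                           # DC handled via mean_level
  xf[!keep] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  x <- x / stats::sd(x) * (contrast * abs(mean_level))
  trace(mean_level + x, dt = dt, units = "intensity")
}

#' Flash event descriptor
#'
#' Describes one brief full-field flash riding on the background: onset,
#' duration (10 ms by default, the standard brief-flash duration), strength
#' above background, and which pathway-preferring wavelength delivers it.
#'
#' @param onset Flash onset in seconds.
#' @param strength Intensity above background, in stimulus units (>= 0).
#' @param duration Flash duration in seconds (> 0; default 0.01).
#' @param pathway `"rod"` or `"cone"`.
#' @return An object of class `"flash"`.
#' @export
flash <- function(onset, strength, duration = 0.01,
                  pathway = c("rod", "cone")) {
  pathway <- match.arg(pathway)
  stopifnot_scalar(onset, "onset")
  stopifnot_scalar(strength, "strength")
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (strength < 0) stop("`strength` must be >= 0", call. = FALSE)
  if (onset < 0) stop("`onset` must be >= 0", call. = FALSE)
  structure(list(onset = onset, strength = strength, duration = duration,
                 pathway = pathway), class = "flash")
}

#' Flash-sequence stimulus
#'
#' Builds a raw-intensity trace equal to `background` everywhere except for
#' rectangular pulses at the given flash onsets. Flashes of the same pathway
#' must not overlap in time.
#'
#' @param background Background intensity, in stimulus units.
#' @param flashes A list of [flash()] objects (possibly empty).
#' @param duration Total trace duration in seconds.
#' @param dt Sampling interval in seconds.
#' @return A [trace()] in raw intensity units.
#' @examples
#' st <- flash_stimulus(20, list(flash(0.5, 40)), duration = 2)
#' sum(st$values - 20) * st$dt   # pulse area = 0.01 * 40
#' @export
flash_stimulus <- function(background, flashes, duration, dt = 0.001) {
  stopifnot_scalar(background, "background")
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (!is.list(flashes) || (length(flashes) > 0L &&
      !all(vapply(flashes, inherits, TRUE, "flash")))) {
    stop("`flashes` must be a list of flash() objects", call. = FALSE)
  }
  n <- round(duration / dt)
  values <- rep(background, n)
  tt <- (seq_len(n) - 1L) * dt

  for (pw in c("rod", "cone")) {
    fl <- Filter(function(f) f$pathway == pw, flashes)
    if (length(fl) > 1L) {
      on <- vapply(fl, `[[`, 0, "onset")
      off <- on + vapply(fl, `[[`, 0, "duration")
      ord <- order(on)
      if (any(on[ord][-1L] < off[ord][-length(off)])) {
        stop(sprintf("overlapping %s flashes", pw), call. = FALSE)
      }
    }
  }
  for (f in flashes) {
    if (f$onset + f$duration > duration + 1e-12) {
      stop("flash extends past stimulus duration", call. = FALSE)
    }
    sel <- tt >= f$onset & tt < f$onset + f$duration
    values[sel] <- values[sel] + f$strength
  }
  trace(values, dt = dt, units = "intensity")
}
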