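#' Estimate a linear filter by regularized reverse correlation
#'
#' Recovers the temporal filter of an LN cascade from a Gaussian-noise
#' stimulus and the measured response. The estimate is the Wiener solution
#' computed in the frequency domain: the stimulus-response cross-spectrum
#' divided by the stimulus power spectrum plus a ridge (a fraction of the
#' mean power), inverse-transformed and truncated to lags `[0, max_lag]`.
#' The ridge regularizes the division where the band-limited stimulus has
#' no power; frequency components outside `passband` are zeroed. A naive
#' cross-correlation would instead return the filter convolved with the
#' stimulus autocorrelation.
#'
#' Both traces are mean-centered before estimation, so the filter describes
#' responses to stimulus fluctuations about the operating point.
#'
#' @param stimulus A [trace()], typically contrast drive from
#'   [contrast_drive()].
#' @param response A [trace()] aligned with `stimulus` (same dt and length).
#' @param max_lag Filter support in seconds.
#' @param passband Length-2 Hz vector; components outside are suppressed.
#' @param ridge Ridge fraction of mean stimulus power (>= 0, default 0.01).
#' @return A `"linear_filter"` with `length(taps) = max_lag/dt + 1`.
#' @seealso [estimate_nonlinearity()], [ln_fit()]
#' @export
estimate_filter <- function(stimulus, response, max_lag = 0.5,
                            passband = c(0, 60), ridge = 0.01) {
  stopifnot(inherits(stimulus, "trace"), inherits(response, "trace"))
  check_same_grid(stimulus, response)
  stopifnot_scalar(max_lag, "max_lag", positive = TRUE)
  stopifnot_scalar(ridge, "ridge")
  if (ridge < 0) stop("`ridge` must be >= 0", call. = FALSE)
  dt <- stimulus$dt
  s <- stimulus$values - mean(stimulus$values)
  r <- response$values - mean(response$values)
  if (stats::sd(s) == 0) {
    stop("stimulus has zero variance; cannot estimate a filter", call. = FALSE)
  }
  n <- length(s)
  sf <- stats::fft(s)
  rf <- stats::fft(r)
  cross <- Conj(sf) * rf / n
  power <- Mod(sf)^2 / n
  h <- cross / (power + ridge * mean(power))

  freq <- seq(0L, n - 1L)
  freq <- pmin(freq, n - freq) / (n * dt)
  h[freq < passband[1L] | freq > passband[2L]] <- 0

  taps <- Re(stats::fft(h, inverse = TRUE)) / n / dt
  nlag <- min(n, round(max_lag / dt) + 1L)
  linear_filter(taps[seq_len(nlag)], dt = dt, pathway = stimulus$units)
}

#' Estimate the static nonlinearity of an LN cascade
#'
#' Bins the generator signal (stimulus convolved with the filter) into
#' quantile bins and takes the mean generator value and mean response in
#' each bin as a knot. Adjacent bins that violate monotonicity are pooled
#' (weighted by their counts) until the knot outputs are non-decreasing, as
#' for an isotonic fit. The initial filter-length samples are discarded so
#' that only fully-driven generator values enter the fit.
#'
#' @param stimulus,response Aligned [trace()]s (the training data).
#' @param filter The `"linear_filter"` whose output defines the generator
#'   signal.
#' @param n_bins Number of quantile bins (>= 5, default 40).
#' @param min_count Minimum samples per bin (default 50); `n_bins` is
#'   reduced if needed, and an error is raised if even 5 bins cannot be
#'   filled.
#' @return A [knot_nl()] nonlinearity carrying per-knot counts.
#' @export
estimate_nonlinearity <- function(stimulus, response, filter, n_bins = 40,
                                  min_count = 50) {
  stopifnot(inherits(stimulus, "trace"), inherits(response, "trace"),
            inherits(filter, "linear_filter"))
  check_same_grid(stimulus, response)
  if (n_bins < 5) stop("`n_bins` must be >= 5", call. = FALSE)
  g <- generator_signal(filter, stimulus)$values
  r <- response$values
  warm <- length(filter$taps)
  if (length(g) <= warm + n_bins) {
    stop("trace too short to fill the requested bins", call. = FALSE)
  }
  g <- g[-seq_len(warm)]
  r <- r[-seq_len(warm)]

  n_bins <- min(n_bins, floor(length(g) / min_count))
  if (n_bins < 5) {
    stop("too few samples for the minimum bin occupancy", call. = FALSE)
  }
  if (length(unique(g)) < n_bins) {
    stop("fewer distinct generator values than bins", call. = FALSE)
  }
  qs <- stats::quantile(g, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 6L) {
    stop("generator signal too discrete for quantile binning", call. = FALSE)
  }
  bin <- cut(g, breaks = qs, include.lowest = TRUE, labels = FALSE)
  gx <- tapply(g, bin, mean)
  gy <- tapply(r, bin, mean)
  cnt <- tabulate(bin)

  pooled <- pool_monotone(as.numeric(gx), as.numeric(gy), cnt)
  knot_nl(pooled$x, pooled$y, counts = pooled$w)
}

# Pool adjacent bins whose mean responses violate monotonicity
# (weighted PAVA); x knots are pooled alongside.
pool_monotone <- function(x, y, w) {
  i <- 1L
  while (i < length(y)) {
    if (y[i + 1L] < y[i]) {
      wt <- w[i] + w[i + 1L]
      x[i] <- (x[i] * w[i] + x[i + 1L] * w[i + 1L]) / wt
      y[i] <- (y[i] * w[i] + y[i + 1L] * w[i + 1L]) / wt
      w[i] <- wt
      x <- x[-(i + 1L)]; y <- y[-(i + 1L)]; w <- w[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  list(x = x, y = y, w = w)
}

#' Fit a linear-nonlinear cascade model
#'
#' The main fitting entry point: estimates the linear filter by regularized
#' reverse correlation ([estimate_filter()]), peak-normalizes it (the
#' filter/nonlinearity amplitude ambiguity is resolved by putting all gain
#' into the nonlinearity), and estimates the static nonlinearity against the
#' normalized filter's generator signal ([estimate_nonlinearity()]).
#'
#' @param stimulus A [trace()] in contrast-drive units (see
#'   [contrast_drive()]); raw-intensity traces should be converted first.
#' @param response The measured response [trace()], aligned with `stimulus`.
#' @param max_lag Filter support in seconds (default 0.5).
#' @param passband Estimation passband in Hz (default 0-60, the stimulus
#'   band).
#' @param ridge Ridge fraction for the spectral division (default 0.01).
#' @param n_bins Quantile bins for the nonlinearity (default 40).
#' @param min_count Minimum samples per bin (default 50).
#' @param pathway Optional pathway label stored on the filter.
#'
#' @return An object of class `"ln_model"`: a list with components
#'   `filter` (normalized `"linear_filter"`), `nonlinearity` (a
#'   `"nonlinearity"`), `dt`, and -- for fitted models -- the training data
#'   and fitted values. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `plot()`, `residuals()`, `fitted()` and `simulate()`.
#' @examples
#' stim <- contrast_drive(noise_stimulus(20, duration = 30, seed = 1))
#' resp <- simulate_response(rod_filter(), cone_filter(),
#'                           threshold_linear(0.1),
#'                           rod_stim = stim, noise_sd = 0.01, seed = 2)
#' fit <- ln_fit(stim, resp)
#' fit
#' cor(fitted(fit), resp$values)
#' @export
ln_fit <- function(stimulus, response, max_lag = 0.5, passband = c(0, 60),
                   ridge = 0.01, n_bins = 40, min_count = 50,
                   pathway = NULL) {
  filt <- estimate_filter(stimulus, response, max_lag = max_lag,
                          passband = passband, ridge = ridge)
  filt <- normalize_filter(filt)
  if (!is.null(pathway)) filt$pathway <- pathway
  nl <- estimate_nonlinearity(stimulus, response, filt, n_bins = n_bins,
                              min_count = min_count)
  obj <- ln_model(filt, nl)
  obj$call <- match.call()
  obj$stimulus <- stimulus
  obj$response <- response
  obj$fitted_trace <- predict(obj, stimulus)
  obj
}

#' Construct an LN model from known components
#'
#' Builds an `"ln_model"` directly from a filter and a nonlinearity, e.g.
#' for ground-truth models in simulation studies or models read back from
#' JSON.
#'
#' @param filter A `"linear_filter"`.
#' @param nonlinearity A `"nonlinearity"`.
#' @return An `"ln_model"` object (without training data).
#' @export
ln_model <- function(filter, nonlinearity) {
  stopifnot(inherits(filter, "linear_filter"),
            inherits(nonlinearity, "nonlinearity"))
  structure(list(filter = filter, nonlinearity = nonlinearity,
                 dt = filter$dt),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("Linear-nonlinear cascade model\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  print(x$filter)
  print(x$nonlinearity)
  if (!is.null(x$fitted_trace)) {
    cat(sprintf("  training correlation: %.4f\n",
                stats::cor(x$fitted_trace$values, x$response$values)))
  }
  invisible(x)
}

#' @export
summary.ln_model <- function(object, ...) {
  f <- object$filter
  lags <- (seq_along(f$taps) - 1L) * f$dt
  out <- list(
    n_taps = length(f$taps),
    dt = f$dt,
    peak_lag = lags[which.max(f$taps)],
    trough_lag = lags[which.min(f$taps)],
    biphasic_depth = max(0, -min(f$taps)) / max(f$taps),
    nonlinearity = class(object$nonlinearity)[1L]
  )
  if (!is.null(object$fitted_trace)) {
    out$train_cor <- stats::cor(object$fitted_trace$values,
                                object$response$values)
    out$train_n <- length(object$response$values)
  }
  structure(out, class = "summary.ln_model")
}

#' @export
print.summary.ln_model <- function(x, ...) {
  cat("LN model summary\n")
  cat(sprintf("  filter: %d taps at dt = %g s; peak lag %.3f s, trough lag %.3f s\n",
              x$n_taps, x$dt, x$peak_lag, x$trough_lag))
  cat(sprintf("  undershoot depth (|min|/max): %.3f\n", x$biphasic_depth))
  cat(sprintf("  nonlinearity: %s\n", x$nonlinearity))
  if (!is.null(x$train_cor)) {
    cat(sprintf("  training correlation: %.4f over %d samples\n",
                x$train_cor, x$train_n))
  }
  invisible(x)
}

#' @export
coef.ln_model <- function(object, ...) {
  object$filter$taps
}

#' Predict the LN response to a stimulus
#'
#' Applies the cascade: causal convolution of the stimulus with the model
#' filter, then the static nonlinearity (with its extrapolation rule beyond
#' the fitted knot range).
#'
#' @param object An `"ln_model"`.
#' @param stimulus A [trace()] in the same drive units used for fitting.
#' @param ... Unused.
#' @return A [trace()] of the predicted response.
#' @export
predict.ln_model <- function(object, stimulus, ...) {
  stopifnot(inherits(stimulus, "trace"))
  g <- generator_signal(object$filter, stimulus)
  trace(nl_eval(object$nonlinearity, g$values), dt = g$dt,
        start_time = g$start_time, units = "a.u.")
}

#' @export
fitted.ln_model <- function(object, ...) {
  if (is.null(object$fitted_trace)) {
    stop("model carries no training data", call. = FALSE)
  }
  object$fitted_trace$values
}

#' @export
residuals.ln_model <- function(object, ...) {
  if (is.null(object$fitted_trace)) {
    stop("model carries no training data", call. = FALSE)
  }
  object$response$values - object$fitted_trace$values
}

#' Simulate responses from a fitted LN model
#'
#' Draws `nsim` response traces to a stimulus by adding Gaussian noise to
#' the LN prediction. The noise SD defaults to the SD of the training
#' residuals.
#'
#' @param object An `"ln_model"`.
#' @param nsim Number of simulated traces.
#' @param seed Integer seed.
#' @param stimulus Stimulus [trace()]; defaults to the training stimulus.
#' @param noise_sd Noise SD; defaults to the residual SD.
#' @param ... Unused.
#' @return A list of `nsim` [trace()]s.
#' @export
simulate.ln_model <- function(object, nsim = 1, seed = 1, stimulus = NULL,
                              noise_sd = NULL, ...) {
  if (is.null(stimulus)) {
    if (is.null(object$stimulus)) {
      stop("supply `stimulus`: the model carries no training data",
           call. = FALSE)
    }
    stimulus <- object$stimulus
  }
  if (is.null(noise_sd)) {
    noise_sd <- stats::sd(residuals(object))
  }
  mu <- predict(object, stimulus)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    trace(mu$values + stats::rnorm(length(mu$values), sd = noise_sd),
          dt = mu$dt, start_time = mu$start_time, units = mu$units)
  }))
}

#' @export
plot.ln_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$filter, main = "linear filter")
  plot(x$nonlinearity, main = "nonlinearity")
  invisible(x)
}
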