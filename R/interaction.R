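#' Scale a filter so its LN flash response matches a target peak
#'
#' Flash responses are predicted by scaling the (normalized) linear filter
#' and passing it through the nonlinearity; the scale alpha is chosen so
#' that the predicted peak response above baseline, `max_t N(alpha L(t)) -
#' N(0)`, equals the measured flash-response amplitude. "Amplitude" is the
#' peak above baseline (not the integral). Since the peak is non-decreasing
#' in alpha for a non-decreasing nonlinearity, alpha is found by bisection
#' to a relative tolerance of 1e-6.
#'
#' @param model An `"ln_model"` (filter plus nonlinearity).
#' @param target_peak Measured flash-response amplitude above baseline
#'   (> 0).
#' @return An object of class `"flash_scaling"`: list with `alpha`,
#'   `target_peak` and `pathway`.
#' @export
scale_filter_to_flash <- function(model, target_peak) {
  stopifnot(inherits(model, "ln_model"))
  stopifnot_scalar(target_peak, "target_peak", positive = TRUE)
  taps <- model$filter$taps
  nl <- model$nonlinearity
  if (inherits(nl, "nl_knots") && any(diff(nl$y) < 0)) {
    stop("nonlinearity is not non-decreasing", call. = FALSE)
  }
  n0 <- nl_eval(nl, 0)
  peak_above <- function(alpha) max(nl_eval(nl, alpha * taps)) - n0

  hi <- 1
  it <- 0L
  while (peak_above(hi) < target_peak) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L) {
      stop("target peak unreachable: nonlinearity appears bounded above",
           call. = FALSE)
    }
  }
  alpha <- stats::uniroot(function(a) peak_above(a) - target_peak,
                          c(0, hi), tol = 1e-10 * hi)$root
  if (abs(peak_above(alpha) - target_peak) > 1e-6 * target_peak) {
    # flat segment of N: refine by bisection on the achieved peak
    lo <- 0
    for (k in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (peak_above(mid) < target_peak) lo <- mid else hi <- mid
    }
    alpha <- hi
  }
  structure(list(alpha = alpha, target_peak = target_peak,
                 pathway = model$filter$pathway),
            class = "flash_scaling")
}

#' @export
print.flash_scaling <- function(x, ...) {
  cat(sprintf("<flash_scaling> pathway %s: alpha = %.6g for peak %.4g\n",
              x$pathway, x$alpha, x$target_peak))
  invisible(x)
}

#' Predict the response to a single flash
#'
#' The model flash response: baseline `N(0)` before `onset`, then
#' `N(alpha L(t - onset))` -- the scaled filter through the nonlinearity.
#'
#' @param model An `"ln_model"`.
#' @param scaling A `"flash_scaling"` from [scale_filter_to_flash()] (or a
#'   bare number used directly as alpha).
#' @param onset Flash onset in seconds.
#' @param duration Length of the returned trace in seconds; defaults to
#'   `onset` plus the filter support plus 0.1 s.
#' @return A [trace()] of the predicted response.
#' @export
predict_flash_response <- function(model, scaling, onset = 0,
                                   duration = NULL) {
  stopifnot(inherits(model, "ln_model"))
  alpha <- if (inherits(scaling, "flash_scaling")) scaling$alpha
           else as.numeric(scaling)
  dt <- model$dt
  taps <- model$filter$taps
  if (is.null(duration)) duration <- onset + length(taps) * dt + 0.1
  n <- round(duration / dt)
  gen <- numeric(n)
  i0 <- round(onset / dt)
  idx <- seq_along(taps) + i0
  ok <- idx <= n
  gen[idx[ok]] <- alpha * taps[ok]
  trace(nl_eval(model$nonlinearity, gen), dt = dt, units = "a.u.")
}

#' Predict the response to a pair of temporally offset flashes
#'
#' The mechanistic prediction for paired flashes: the scaled adapt and test
#' filters, offset in time by `delta_t`, are summed linearly and the sum is
#' passed through the single shared nonlinearity:
#' `N(alpha_a L_a(t) + alpha_t L_t(t - delta_t))`.
#'
#' @param adapt_model,test_model `"ln_model"`s for the adapt (first) and
#'   test (second) flash pathways; filters must share dt.
#' @param adapt_scaling,test_scaling `"flash_scaling"`s (or bare alphas).
#' @param delta_t Offset of the test flash after the adapt flash (>= 0).
#' @param shared_nl The common synaptic nonlinearity; defaults to the test
#'   model's.
#' @param duration Trace length in seconds; default covers both filters
#'   plus 0.1 s.
#' @return A [trace()] of the predicted paired response (adapt onset at
#'   time 0).
#' @export
predict_paired_response <- function(adapt_model, adapt_scaling,
                                    test_model, test_scaling,
                                    delta_t, shared_nl = NULL,
                                    duration = NULL) {
  stopifnot(inherits(adapt_model, "ln_model"),
            inherits(test_model, "ln_model"))
  stopifnot_scalar(delta_t, "delta_t")
  if (delta_t < 0) stop("`delta_t` must be >= 0", call. = FALSE)
  dt <- adapt_model$dt
  if (abs(test_model$dt - dt) > 1e-12 * dt) {
    stop("adapt and test filters have mismatched dt", call. = FALSE)
  }
  if (is.null(shared_nl)) shared_nl <- test_model$nonlinearity
  a_a <- if (inherits(adapt_scaling, "flash_scaling")) adapt_scaling$alpha
         else as.numeric(adapt_scaling)
  a_t <- if (inherits(test_scaling, "flash_scaling")) test_scaling$alpha
         else as.numeric(test_scaling)
  ta <- adapt_model$filter$taps
  tt <- test_model$filter$taps
  if (is.null(duration)) {
    duration <- delta_t + max(length(ta), length(tt)) * dt + 0.1
  }
  n <- round(duration / dt)
  gen <- numeric(n)
  ok <- seq_along(ta) <= n
  gen[seq_along(ta)[ok]] <- gen[seq_along(ta)[ok]] + a_a * ta[ok]
  i0 <- round(delta_t / dt)
  idx <- seq_along(tt) + i0
  ok <- idx <= n
  gen[idx[ok]] <- gen[idx[ok]] + a_t * tt[ok]
  trace(nl_eval(shared_nl, gen), dt = dt, units = "a.u.")
}

#' Interaction index of a paired-flash protocol
#'
#' Quantifies how much the adapt flash changes the response to the test
#' flash: `II = 1 - R_pair / R_single`, where `R_single` is the integral of
#' the baseline-corrected test-alone response over the test window and
#' `R_pair` is the integral of the paired response minus the adapt-alone
#' response over the same window. `II = 0` corresponds to linear summation;
#' `II = 1` means the adapt flash completely suppressed the test response.
#' Values outside `[0, 1]` (facilitation, or overshoot-driven negative
#' `R_pair`) are reported as computed and flagged, not clipped.
#'
#' @param test_alone,paired,adapt_alone Aligned response [trace()]s.
#' @param test_onset Onset of the test flash in seconds.
#' @param window Integration window length after `test_onset` (default
#'   0.6 s).
#' @param baseline Scalar baseline subtracted from all traces (e.g. `N(0)`
#'   for model predictions). If `NULL`, each trace's baseline is its mean
#'   over `baseline_window`.
#' @param baseline_window Length-2 window (s) for per-trace baselines;
#'   defaults to the 0.5 s at the start of the trace, which should precede
#'   the adapt flash.
#' @return An object of class `"interaction_result"`: list with `R_single`,
#'   `R_pair`, `II`, `window` and `outside_unit` flag.
#' @examples
#' dt <- 0.001
#' t <- seq(0, 2, by = dt)
#' bump <- function(on) ifelse(t > on, (t - on) * exp(-(t - on) / 0.05), 0)
#' adapt <- trace(bump(0.6), dt); test <- trace(bump(0.8), dt)
#' lin <- trace(adapt$values + test$values, dt)
#' interaction_index(test, lin, adapt, test_onset = 0.8)$II  # 0
#' @export
interaction_index <- function(test_alone, paired, adapt_alone, test_onset,
                              window = 0.6, baseline = NULL,
                              baseline_window = NULL) {
  stopifnot(inherits(test_alone, "trace"), inherits(paired, "trace"),
            inherits(adapt_alone, "trace"))
  check_same_grid(test_alone, paired)
  check_same_grid(test_alone, adapt_alone)
  stopifnot_scalar(test_onset, "test_onset")
  stopifnot_scalar(window, "window", positive = TRUE)

  if (is.null(baseline)) {
    if (is.null(baseline_window)) {
      t0 <- test_alone$start_time
      baseline_window <- c(t0, t0 + 0.5)
    }
    b_test <- trace_window_mean(test_alone, baseline_window[1L],
                                baseline_window[2L])
    b_pair <- trace_window_mean(paired, baseline_window[1L],
                                baseline_window[2L])
    b_adapt <- trace_window_mean(adapt_alone, baseline_window[1L],
                                 baseline_window[2L])
  } else {
    stopifnot_scalar(baseline, "baseline")
    b_test <- b_pair <- b_adapt <- baseline
  }

  from <- test_onset
  to <- test_onset + window
  r_single <- trace_integral(test_alone, from, to) -
    b_test * (to - from)
  r_pair <- trace_integral(paired, from, to) -
    trace_integral(adapt_alone, from, to) -
    (b_pair - b_adapt) * (to - from)

  scale <- trace_integral(trace(abs(test_alone$values - b_test),
                                dt = test_alone$dt,
                                start_time = test_alone$start_time),
                          from, to)
  if (abs(r_single) <= 1e-9 * max(scale, .Machine$double.eps)) {
    stop("interaction index undefined: test-alone response integrates to zero",
         call. = FALSE)
  }
  ii <- 1 - r_pair / r_single
  structure(list(R_single = r_single, R_pair = r_pair, II = ii,
                 window = c(from, to),
                 outside_unit = (ii < 0 || ii > 1)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> II = %.4f (R_single = %.4g, R_pair = %.4g, window %.3g-%.3g s)%s\n",
    x$II, x$R_single, x$R_pair, x$window[1L], x$window[2L],
    if (x$outside_unit) " [outside [0,1]]" else ""))
  invisible(x)
}

#' Sweep the adapt-test offset and compute interaction indices
#'
#' For each offset, predicts the adapt-alone, test-alone, and paired
#' responses from the scaled filters and the shared nonlinearity, and
#' computes the interaction index with the exact model baseline `N(0)`.
#' Ties in the argmax are broken toward the smaller offset.
#'
#' @param rod_model,cone_model `"ln_model"`s for the two pathways (their
#'   own nonlinearities are ignored in favour of `shared_nl`).
#' @param shared_nl The shared synaptic nonlinearity; defaults to the cone
#'   model's (the cone-derived estimate).
#' @param offsets Sorted non-negative offsets in seconds (default 0 to
#'   0.8 s in 25 ms steps).
#' @param direction `"rod_to_cone"` (rod adapt, cone test) or
#'   `"cone_to_rod"`.
#' @param target_peak Flash-response amplitude both pathways are scaled to
#'   match (equal-amplitude flashes; default 1).
#' @param window Integration window for the indices (default 0.6 s).
#' @return A `data.frame` of class `"offset_sweep"` with columns `offset`,
#'   `R_single`, `R_pair`, `II`, and attributes `peak_offset` (offset of
#'   maximal II) and `direction`.
#' @export
offset_sweep <- function(rod_model, cone_model, shared_nl = NULL,
                         offsets = seq(0, 0.8, by = 0.025),
                         direction = c("rod_to_cone", "cone_to_rod"),
                         target_peak = 1, window = 0.6) {
  direction <- match.arg(direction)
  stopifnot(inherits(rod_model, "ln_model"), inherits(cone_model, "ln_model"))
  if (is.unsorted(offsets) || any(offsets < 0)) {
    stop("`offsets` must be sorted and >= 0", call. = FALSE)
  }
  if (is.null(shared_nl)) shared_nl <- cone_model$nonlinearity

  rod <- ln_model(rod_model$filter, shared_nl)
  cone <- ln_model(cone_model$filter, shared_nl)
  s_rod <- scale_filter_to_flash(rod, target_peak)
  s_cone <- scale_filter_to_flash(cone, target_peak)
  if (direction == "rod_to_cone") {
    adapt <- rod; a_sc <- s_rod; test <- cone; t_sc <- s_cone
  } else {
    adapt <- cone; a_sc <- s_cone; test <- rod; t_sc <- s_rod
  }
  n0 <- nl_eval(shared_nl, 0)
  filt_support <- max(length(adapt$filter$taps), length(test$filter$taps)) *
    adapt$dt

  rows <- lapply(offsets, function(dt_off) {
    t_end <- dt_off + max(filt_support, window) + 0.05
    adapt_alone <- predict_flash_response(adapt, a_sc, onset = 0,
                                          duration = t_end)
    test_alone <- predict_flash_response(test, t_sc, onset = dt_off,
                                         duration = t_end)
    paired <- predict_paired_response(adapt, a_sc, test, t_sc, dt_off,
                                      shared_nl = shared_nl,
                                      duration = t_end)
    res <- interaction_index(test_alone, paired, adapt_alone,
                             test_onset = dt_off, window = window,
                             baseline = n0)
    data.frame(offset = dt_off, R_single = res$R_single,
               R_pair = res$R_pair, II = res$II)
  })
  out <- do.call(rbind, rows)
  peak <- out$offset[which.max(out$II)]   # which.max takes the first maximum
  structure(out, class = c("offset_sweep", "data.frame"),
            peak_offset = peak, direction = direction)
}

#' @export
print.offset_sweep <- function(x, ...) {
  cat(sprintf("Offset sweep (%s): %d offsets, II max %.4f at %.3f s\n",
              attr(x, "direction"), nrow(x), max(x$II),
              attr(x, "peak_offset")))
  NextMethod()
}

#' @export
plot.offset_sweep <- function(x, ..., xlab = "adapt-test offset (s)",
                              ylab = "interaction index") {
  graphics::plot(x$offset, x$II, type = "b", pch = 16, xlab = xlab,
                 ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = attr(x, "peak_offset"), lty = 2, col = "grey40")
  invisible(x)
}

#' Biphasic index of a flash response
#'
#' `BI = A_H / (A_H + A_D)`, where `A_D` is the maximum depolarization and
#' `A_H` the maximum hyperpolarization magnitude within the first 400 ms of
#' the baseline-corrected response after flash onset. `BI = 0` for a purely
#' monophasic (depolarizing) response, 0.5 for a symmetric biphasic one.
#'
#' @param response A response [trace()] covering
#'   `[flash_onset, flash_onset + 0.4]`.
#' @param flash_onset Flash onset in seconds.
#' @param baseline Scalar baseline; if `NULL`, the pre-flash mean
#'   (`[start, flash_onset)`) is used.
#' @param window Analysis window after onset (default 0.4 s).
#' @return An object of class `"biphasic_result"`: list with `A_D`, `A_H`,
#'   `BI`.
#' @export
biphasic_index <- function(response, flash_onset, baseline = NULL,
                           window = 0.4) {
  stopifnot(inherits(response, "trace"))
  stopifnot_scalar(flash_onset, "flash_onset")
  tt <- trace_times(response)
  if (max(tt) + response$dt < flash_onset + window) {
    stop(sprintf("trace must cover [%g, %g] s after the flash",
                 flash_onset, flash_onset + window), call. = FALSE)
  }
  if (is.null(baseline)) {
    pre <- tt < flash_onset
    if (!any(pre)) {
      stop("no pre-flash samples to estimate the baseline; supply `baseline`",
           call. = FALSE)
    }
    baseline <- mean(response$values[pre])
  } else {
    stopifnot_scalar(baseline, "baseline")
  }
  sel <- tt >= flash_onset & tt <= flash_onset + window
  v <- response$values[sel] - baseline
  a_d <- max(0, max(v))
  a_h <- max(0, -min(v))
  if (a_d + a_h == 0) {
    stop("biphasic index undefined: flat response", call. = FALSE)
  }
  structure(list(A_D = a_d, A_H = a_h, BI = a_h / (a_h + a_d)),
            class = "biphasic_result")
}

#' @export
print.biphasic_result <- function(x, ...) {
  cat(sprintf("<biphasic_result> BI = %.4f (A_D = %.4g, A_H = %.4g)\n",
              x$BI, x$A_D, x$A_H))
  invisible(x)
}
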