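# Brute-force least-squares filter fit: regress the response on lagged
# copies of the stimulus. Independent oracle for the spectral estimator.
ls_filter_oracle <- function(stimulus, response, n_taps) {
  s <- stimulus$values - mean(stimulus$values)
  r <- response$values - mean(response$values)
  n <- length(s)
  X <- sapply(seq_len(n_taps) - 1L, function(lag) {
    c(numeric(lag), s[seq_len(n - lag)])
  }) * stimulus$dt
  as.numeric(stats::coef(stats::lm.fit(X, r)))
}

test_that("reverse correlation recovers a known filter from white noise", {
  f <- rod_filter()
  stim <- contrast_drive(noise_stimulus(20, contrast = 0.5,
                                        bandwidth = c(0, 500),
                                        duration = 60, dt = 0.001,
                                        seed = 14))
  resp <- simulate_response(f, cone_filter(), identity_nl(),
                            rod_stim = stim, noise_sd = 0)
  est <- estimate_filter(stim, resp, max_lag = 0.5,
                         passband = c(0, 500), ridge = 1e-4)
  k <- seq_along(f$taps)
  expect_gt(cor(est$taps[k], f$taps), 0.99)
})

test_that("a response independent of the stimulus gives a near-zero filter", {
  stim <- quick_drive(duration = 40, seed = 15)
  matched <- simulate_response(rod_filter(), cone_filter(), identity_nl(),
                               rod_stim = stim, noise_sd = 0)
  # a shuffled response with the same marginal scale carries no filter
  indep <- trace(rodcone:::with_seed(99, sample(matched$values)),
                 dt = stim$dt, units = "a.u.")
  est <- estimate_filter(stim, indep, max_lag = 0.5)
  ref <- estimate_filter(stim, matched, max_lag = 0.5)
  # the no-signal estimate is sampling noise: an order of magnitude below
  # the matched filter's peak even at its largest excursion
  expect_lt(max(abs(est$taps)) / max(abs(ref$taps)), 0.15)
  expect_lt(mean(abs(est$taps)) / mean(abs(ref$taps)), 0.15)
})

test_that("rectification biases filter amplitude but not shape", {
  sys <- truth_system()
  stim <- quick_drive(duration = 120, seed = 16)
  resp <- simulate_response(sys$rod, sys$cone, sys$nl, rod_stim = stim,
                            noise_sd = 0.002, seed = 17)
  est <- normalize_filter(estimate_filter(stim, resp))
  k <- seq_along(sys$rod$taps)
  expect_gt(cor(est$taps[k], sys$rod$taps), 0.95)
})

test_that("the spectral estimate agrees with brute-force least squares", {
  dt <- 0.01
  true_taps <- c(0, 0.4, 1, 0.6, 0.1, -0.2, -0.35, -0.15)
  f <- linear_filter(true_taps, dt = dt)
  stim <- contrast_drive(noise_stimulus(10, contrast = 0.5,
                                        bandwidth = c(0, 50),
                                        duration = 40, dt = dt, seed = 18))
  resp <- simulate_response(f, f, identity_nl(), rod_stim = stim,
                            noise_sd = 0)
  wiener <- estimate_filter(stim, resp, max_lag = length(true_taps) * dt,
                            passband = c(0, 50), ridge = 0)
  ls <- ls_filter_oracle(stim, resp, length(true_taps))
  expect_gt(cor(wiener$taps[seq_along(ls)], ls), 0.999)
  expect_lt(max(abs(wiener$taps[seq_along(ls)] - ls)), 0.05)
  # and both recover the truth
  expect_lt(max(abs(ls - true_taps)), 0.05)
})

test_that("constant stimuli are rejected", {
  flat <- trace(rep(1, 1000), dt = 0.001)
  resp <- trace(rnorm(1000), dt = 0.001)
  expect_error(estimate_filter(flat, resp), "zero variance")
})

test_that("nonlinearity estimation recovers identity and threshold shapes", {
  dt <- 0.001
  stim <- quick_drive(duration = 60, seed = 20)
  delta <- linear_filter(1 / dt, dt = dt)

  # identity system: knots on the identity line
  est_id <- estimate_nonlinearity(stim, stim, delta, n_bins = 20)
  expect_lt(max(abs(est_id$y - est_id$x)), 1e-9)

  # threshold-linear system through the rod filter
  sys <- truth_system()
  resp <- simulate_response(sys$rod, sys$cone, sys$nl, rod_stim = stim,
                            noise_sd = 0.001, seed = 21)
  est <- estimate_nonlinearity(stim, resp, sys$rod, n_bins = 40)
  truth_y <- nl_eval(sys$nl, est$x)
  rng <- diff(range(truth_y))
  expect_lt(max(abs(est$y - truth_y)), 0.05 * rng)
})

test_that("nonlinearity estimation pools monotone violations", {
  pooled <- rodcone:::pool_monotone(x = c(1, 2, 3, 4),
                                    y = c(0, 2, 1, 3),
                                    w = c(10, 10, 30, 10))
  expect_true(all(diff(pooled$y) >= 0))
  # bins 2 and 3 merge with count weighting
  expect_equal(pooled$y, c(0, (2 * 10 + 1 * 30) / 40, 3))
  expect_equal(pooled$x, c(1, (2 * 10 + 3 * 30) / 40, 4))
})

test_that("occupancy and bin-count preconditions are enforced", {
  dt <- 0.001
  short <- trace(rnorm(10), dt = dt)
  delta <- linear_filter(1 / dt, dt = dt)
  expect_error(estimate_nonlinearity(short, short, delta, n_bins = 5),
               "occupancy|too short")
  stim <- quick_drive(duration = 1, seed = 22)
  expect_error(estimate_nonlinearity(stim, stim, delta, n_bins = 4),
               "n_bins")
})

test_that("ln_fit resolves the amplitude ambiguity into the nonlinearity", {
  sys <- truth_system()
  stim <- quick_drive(duration = 60, seed = 23)
  resp <- simulate_response(sys$rod, sys$cone, sys$nl, rod_stim = stim,
                            noise_sd = 0.001, seed = 24)
  fit <- ln_fit(stim, resp)
  expect_equal(max(abs(fit$filter$taps)), 1)

  # doubling the response doubles the nonlinearity, not the filter
  resp2 <- trace(2 * resp$values, dt = resp$dt, units = resp$units)
  fit2 <- ln_fit(stim, resp2)
  expect_equal(fit2$filter$taps, fit$filter$taps, tolerance = 1e-8)
  g <- seq(min(fit$nonlinearity$x), max(fit$nonlinearity$x),
           length.out = 50)
  expect_equal(nl_eval(fit2$nonlinearity, g), 2 * nl_eval(fit$nonlinearity, g),
               tolerance = 1e-6)
})

test_that("the fitted cascade predicts its own training response", {
  sys <- truth_system()
  stim <- quick_drive(duration = 120, seed = 25)
  clean <- simulate_response(sys$rod, sys$cone, sys$nl, rod_stim = stim,
                             noise_sd = 0)
  fit <- ln_fit(stim, clean)
  pred <- predict(fit, stim)
  warm <- length(fit$filter$taps)
  expect_gt(cor(pred$values[-seq_len(warm)], clean$values[-seq_len(warm)]),
            0.95)
})

test_that("ln_model methods behave like a classical fitted model", {
  sys <- truth_system()
  stim <- quick_drive(duration = 30, seed = 26)
  resp <- simulate_response(sys$rod, sys$cone, sys$nl, rod_stim = stim,
                            noise_sd = 0.002, seed = 27)
  fit <- ln_fit(stim, resp)

  expect_s3_class(fit, "ln_model")
  expect_identical(coef(fit), fit$filter$taps)
  expect_equal(length(fitted(fit)), length(resp$values))
  expect_equal(residuals(fit), resp$values - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.ln_model")
  expect_gt(s$train_cor, 0.9)
  expect_output(print(fit), "Linear-nonlinear")

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_identical(simulate(fit, nsim = 2, seed = 5)[[1]]$values,
                   sims[[1]]$values)

  # evaluating on a zero stimulus returns N(0); doubling a stimulus under
  # an identity nonlinearity doubles the output
  z <- zero_like(stim)
  expect_equal(unique(predict(fit, z)$values),
               nl_eval(fit$nonlinearity, 0))
  lin <- ln_model(fit$filter, identity_nl())
  twice <- trace(2 * stim$values, dt = stim$dt, units = stim$units)
  expect_equal(predict(lin, twice)$values, 2 * predict(lin, stim)$values,
               tolerance = 1e-10)
})
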