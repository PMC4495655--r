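test_that("flash scaling inverts the nonlinearity exactly", {
  rod <- ln_model(rod_filter(), identity_nl())
  sc <- scale_filter_to_flash(rod, target_peak = 3)
  expect_equal(sc$alpha, 3, tolerance = 1e-6)

  # threshold-linear closed form: alpha = theta + p / g for a unit-peak
  # filter
  theta <- 0.4; g <- 2.5; p <- 1.7
  m <- ln_model(rod_filter(), threshold_linear(theta, g))
  sc2 <- scale_filter_to_flash(m, p)
  expect_equal(sc2$alpha, theta + p / g, tolerance = 1e-6)

  # round trip: the predicted peak equals the target
  pred <- predict_flash_response(m, sc2, onset = 0)
  expect_equal(max(pred$values) - nl_eval(m$nonlinearity, 0), p,
               tolerance = 1e-6 * p)

  expect_error(scale_filter_to_flash(m, -1), "target_peak")
})

test_that("single-flash predictions follow the scaled filter", {
  m <- ln_model(rod_filter(), identity_nl())
  flat <- predict_flash_response(m, 0, onset = 0.2, duration = 1)
  expect_equal(unique(flat$values), 0)

  pr <- predict_flash_response(m, 2, onset = 0.1, duration = 0.8)
  i0 <- round(0.1 / m$dt)
  expect_equal(pr$values[seq_len(i0)], numeric(i0))
  expect_equal(pr$values[i0 + seq_along(m$filter$taps)],
               2 * m$filter$taps, tolerance = 1e-12)
})

test_that("paired predictions respect linearity and temporal separation", {
  rod <- ln_model(rod_filter(), identity_nl())
  cone <- ln_model(cone_filter(), identity_nl())

  # identity N: paired = sum of singles at any offset
  for (off in c(0, 0.15, 0.4)) {
    paired <- predict_paired_response(rod, 1.2, cone, 0.8, off,
                                      shared_nl = identity_nl(),
                                      duration = 2)
    s_a <- predict_flash_response(rod, 1.2, onset = 0, duration = 2)
    s_t <- predict_flash_response(cone, 0.8, onset = off, duration = 2)
    expect_equal(paired$values, s_a$values + s_t$values, tolerance = 1e-12)
  }

  # rectifying N with no temporal overlap: the paired trace is the
  # concatenation of the two single-flash responses
  nl <- threshold_linear(0.2)
  rodn <- ln_model(rod_filter(), nl)
  conen <- ln_model(cone_filter(), nl)
  off <- 0.6   # beyond the 0.5 s filter support
  paired <- predict_paired_response(rodn, 1.5, conen, 1.5, off,
                                    shared_nl = nl, duration = 1.5)
  s_a <- predict_flash_response(rodn, 1.5, onset = 0, duration = 1.5)
  s_t <- predict_flash_response(conen, 1.5, onset = off, duration = 1.5)
  expect_equal(paired$values, pmax(s_a$values, s_t$values) +
                 pmin(s_a$values, s_t$values) - nl_eval(nl, 0),
               tolerance = 1e-12)

  # suppression at 0.2 s: the test-epoch response is smaller with the
  # rod adapt flash present
  sys <- truth_system()
  rodm <- ln_model(sys$rod, sys$nl)
  conem <- ln_model(sys$cone, sys$nl)
  sc_r <- scale_filter_to_flash(rodm, 1)
  sc_c <- scale_filter_to_flash(conem, 1)
  paired <- predict_paired_response(rodm, sc_r, conem, sc_c, 0.2,
                                    shared_nl = sys$nl, duration = 1.2)
  alone <- predict_flash_response(conem, sc_c, onset = 0.2, duration = 1.2)
  adapt <- predict_flash_response(rodm, sc_r, onset = 0, duration = 1.2)
  tt <- trace_times(alone)
  ep <- tt >= 0.2 & tt < 0.8
  expect_lt(sum(paired$values[ep] - adapt$values[ep]),
            sum(alone$values[ep]))

  expect_error(predict_paired_response(
    ln_model(rod_filter(dt = 0.002), identity_nl()), 1,
    ln_model(cone_filter(dt = 0.001), identity_nl()), 1, 0.2), "dt")
})

test_that("interaction index reproduces its analytic limits", {
  dt <- 0.001
  t <- seq(0, 2, by = dt)
  bump <- function(on, tau = 0.05) {
    ifelse(t > on, (t - on) / tau * exp(1 - (t - on) / tau), 0)
  }
  adapt <- trace(bump(0.6), dt)
  test <- trace(bump(0.8), dt)

  lin <- trace(adapt$values + test$values, dt)
  ii0 <- interaction_index(test, lin, adapt, test_onset = 0.8, baseline = 0)
  expect_equal(ii0$II, 0, tolerance = 1e-12)

  full <- adapt  # paired identical to adapt-alone: total suppression
  ii1 <- interaction_index(test, full, adapt, test_onset = 0.8, baseline = 0)
  expect_equal(ii1$II, 1, tolerance = 1e-12)
})

test_that("interaction index evaluates the ratio of windowed integrals", {
  dt <- 0.001
  n <- 2000
  tt <- (seq_len(n) - 1) * dt
  # rectangles with known integrals inside the [1, 1.6] window
  test <- trace(ifelse(tt >= 1 & tt < 1.5, 4, 0), dt)       # R_single = 2.0
  adapt <- trace(ifelse(tt >= 0.6 & tt < 0.9, 1, 0), dt)
  paired <- trace(adapt$values + ifelse(tt >= 1 & tt < 1.5, 3, 0), dt)
  res <- interaction_index(test, paired, adapt, test_onset = 1,
                           window = 0.6, baseline = 0)
  expect_equal(res$R_single, 2.0)
  expect_equal(res$R_pair, 1.5)
  expect_equal(res$II, 0.25)
  expect_false(res$outside_unit)

  # facilitation is reported, flagged, not clipped
  boosted <- trace(adapt$values + ifelse(tt >= 1 & tt < 1.5, 5, 0), dt)
  resb <- interaction_index(test, boosted, adapt, test_onset = 1,
                            window = 0.6, baseline = 0)
  expect_equal(resb$II, -0.25)
  expect_true(resb$outside_unit)

  flatt <- trace(numeric(n), dt)
  expect_error(interaction_index(flatt, paired, adapt, test_onset = 1,
                                 baseline = 0), "undefined")
})

test_that("interaction index is invariant to uniform trace rescaling", {
  dt <- 0.001
  t <- seq(0, 2, by = dt)
  bump <- function(on) ifelse(t > on, (t - on) * exp(-(t - on) / 0.06), 0)
  test <- trace(bump(0.9), dt)
  adapt <- trace(bump(0.5), dt)
  paired <- trace(adapt$values + 0.4 * test$values, dt)
  base <- interaction_index(test, paired, adapt, 0.9, baseline = 0)$II
  for (k in c(0.2, 5, 40)) {
    sc <- function(x) trace(k * x$values, dt)
    expect_equal(interaction_index(sc(test), sc(paired), sc(adapt), 0.9,
                                   baseline = 0)$II, base,
                 tolerance = 1e-12)
  }
})

test_that("offset sweep localizes suppression and respects the nulls", {
  sys <- truth_system()
  rodm <- ln_model(sys$rod, sys$nl)
  conem <- ln_model(sys$cone, sys$nl)

  sw <- offset_sweep(rodm, conem, shared_nl = sys$nl)
  expect_gte(attr(sw, "peak_offset"), 0.1)
  expect_lte(attr(sw, "peak_offset"), 0.3)
  expect_lt(abs(sw$II[sw$offset == 0.8]), 0.02)

  # linearity null: identity N kills the interaction at every offset
  swid <- offset_sweep(rodm, conem, shared_nl = identity_nl())
  expect_lt(max(abs(swid$II)), 1e-9)

  # swap symmetry: identical filters make both directions equal
  twin <- ln_model(sys$rod, sys$nl)
  sw_ab <- offset_sweep(twin, twin, shared_nl = sys$nl)
  sw_ba <- offset_sweep(twin, twin, shared_nl = sys$nl,
                        direction = "cone_to_rod")
  expect_equal(sw_ab$II, sw_ba$II, tolerance = 1e-12)
})

test_that("rod-to-cone suppression exceeds cone-to-rod and grows with the undershoot", {
  sys <- truth_system()
  rodm <- ln_model(sys$rod, sys$nl)
  conem <- ln_model(sys$cone, sys$nl)
  at02 <- function(sw) sw$II[abs(sw$offset - 0.2) < 1e-9]

  fwd <- offset_sweep(rodm, conem, shared_nl = sys$nl, offsets = c(0, 0.2))
  rev <- offset_sweep(rodm, conem, shared_nl = sys$nl, offsets = c(0, 0.2),
                      direction = "cone_to_rod")
  expect_gt(at02(fwd), at02(rev))

  # II at 0.2 s is non-decreasing in the rod undershoot depth
  iis <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(rho) {
    rf <- make_biphasic_filter(0.10, 0.20, rho, pathway = "rod")
    at02(offset_sweep(ln_model(rf, sys$nl), conem, shared_nl = sys$nl,
                      offsets = c(0, 0.2)))
  }, 0)
  expect_true(all(diff(iis) >= -1e-9))
})

test_that("biphasic index separates mono- and biphasic responses", {
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  mono <- trace(ifelse(t > 0.3, exp(-(t - 0.3) / 0.05), 0), dt)
  expect_equal(biphasic_index(mono, 0.3)$BI, 0)

  sym <- trace(ifelse(t > 0.3, sin(2 * pi * (t - 0.3) / 0.3), 0) *
                 (t <= 0.6), dt)
  expect_equal(biphasic_index(sym, 0.3)$BI, 0.5, tolerance = 1e-6)

  # rod preset through an identity nonlinearity: extrema are the filter's,
  # so BI = rho / (1 + rho) with rho the undershoot ratio
  rodm <- ln_model(rod_filter(), identity_nl())
  resp <- predict_flash_response(rodm, 1, onset = 0.1, duration = 0.8)
  expect_equal(biphasic_index(resp, 0.1)$BI, 0.5 / 1.5, tolerance = 1e-4)

  expect_true(biphasic_index(resp, 0.1)$BI >= 0)
  expect_true(biphasic_index(resp, 0.1)$BI <= 1)

  expect_error(biphasic_index(trace(numeric(500), dt), 0.05), "flat|undefined")
  expect_error(biphasic_index(mono, 0.9), "cover")
})
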