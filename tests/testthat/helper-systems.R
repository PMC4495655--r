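# Shared fixture builders: small LN systems and stimuli generated in code.

# A quick contrast-drive noise stimulus.
quick_drive <- function(duration = 30, dt = 0.001, seed = 1,
                        bandwidth = c(0, 60)) {
  contrast_drive(noise_stimulus(20, contrast = 0.5, bandwidth = bandwidth,
                                duration = duration, dt = dt, seed = seed))
}

# Ground-truth rod/cone system with a shared threshold-linear synapse.
truth_system <- function(dt = 0.001) {
  rodf <- rod_filter(dt = dt)
  conef <- cone_filter(dt = dt)
  list(rod = rodf, cone = conef,
       nl = default_nonlinearity(rodf, conef))
}

# Zero-valued contrast-drive trace matching another trace's grid.
zero_like <- function(x) {
  trace(numeric(length(x$values)), dt = x$dt, start_time = x$start_time,
        units = "contrast")
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
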