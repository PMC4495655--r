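# internal helpers shared across the package

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a named sub-stream seed from a root seed; stays below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(
    stimulus = 101L, response_noise = 211L, observer = 307L,
    draws = 401L, session = 503L
  )
  off <- offsets[[stream]]
  (as.integer(seed) * 7919L + off) %% 2147483587L
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Causal discrete convolution approximating the continuous integral
# (f * x)(t) = sum_j taps[j] x[t - j] * dt, zero initial conditions.
# FFT-based, zero-padded to a 2-3-5-smooth length so the transform stays fast
# for arbitrary trace lengths.
convolve_causal <- function(x, taps, dt) {
  n <- length(x)
  m <- length(taps)
  len <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, numeric(len - n)))
  hf <- stats::fft(c(taps, numeric(len - m)))
  y <- Re(stats::fft(xf * hf, inverse = TRUE)) / len
  y[seq_len(n)] * dt
}
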