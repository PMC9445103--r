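# small internal helpers

# evaluate expr with a local RNG state seeded at `seed`; the caller's RNG
# stream is left untouched
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# derive a stage seed from a global seed and a stage name, kept within
# 32-bit integer range
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Hann taper over [w1, w2] evaluated at times t (ms); zero outside
.hannWindow <- function(t, window) {
  env <- numeric(length(t))
  inw <- t >= window[1] & t <= window[2]
  span <- window[2] - window[1]
  env[inw] <- 0.5 - 0.5 * cos(2 * pi * (t[inw] - window[1]) / span)
  env
}

# zero-phase band-pass of a vector via hard FFT mask (used for synthetic
# band-limited noise, not for data analysis)
.fftBandpass <- function(x, sfreq, band) {
  n <- length(x)
  f <- c(0, seq_len(n - 1)) / n * sfreq
  f <- pmin(f, sfreq - f)  # two-sided frequency magnitude
  keep <- f >= band[1] & f <= band[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

.assertWindow <- function(window, times, what = "window") {
  if (length(window) != 2L || window[2] < window[1])
    stop(what, " must be c(start, end) with end >= start")
  if (window[1] < min(times) || window[2] > max(times))
    stop(what, " [", window[1], ", ", window[2],
         "] ms lies outside the time axis [", min(times), ", ", max(times),
         "] ms")
  invisible(TRUE)
}
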