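# Independent oracle for the JZS Bayes factor: dense log-space trapezoid
# quadrature over the Cauchy mixture parameter, at 10x the resolution any
# adaptive scheme would need.
bfTrapezoidOracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  lg <- seq(log(1e-7), log(1e5), length.out = 200000)
  g <- exp(lg)
  logf <- -0.5 * log1p(n * g * r^2) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g * r^2) * nu)) -
    0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) + lg  # + lg: du = g dlg
  m <- max(logf)
  num <- sum(exp(logf - m)) * diff(lg)[1] * exp(m)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

test_that("interval averages behave like means", {
  tms <- seq(0, 1000, by = 50)
  curve <- matrix(2.5, 3, length(tms))
  expect_equal(intervalAverage(curve, tms, c(200, 700)), rep(2.5, 3))
  expect_equal(intervalAverage(curve, tms, c(300, 300)), rep(2.5, 3))
  ramp <- matrix(seq(0, 1, length.out = length(tms)), 1)
  expect_equal(intervalAverage(ramp, tms, c(0, 1000)), 0.5)
  expect_error(intervalAverage(curve, tms, c(2000, 3000)), "no samples")
})

test_that("Cohen's d and adjusted partial eta squared reproduce printed
          statistics to two decimals", {
  d <- function(t) t / sqrt(28)
  expect_equal(round(d(5.42), 2), 1.02)
  expect_equal(round(d(5.01), 2), 0.95)
  expect_equal(round(d(60.26), 2), 11.39)
  expect_equal(round(adjustedPartialEtaSq(5.42, 27), 2), 0.50)
  expect_equal(round(adjustedPartialEtaSq(5.01, 27), 2), 0.46)
  expect_equal(round(adjustedPartialEtaSq(3.80, 27), 2), 0.32)
  expect_equal(adjustedPartialEtaSq(1, 27), 0)  # F = 1 -> 0
  expect_equal(adjustedPartialEtaSq(0, 5) * 0, 0)
})

test_that("the JZS Bayes factor matches the fine-grid quadrature oracle", {
  for (t in c(0, 0.5, 2.2, 6.07)) {
    bf <- jzsBayesFactor(t, 28)
    expect_equal(unname(bf["bf10"]), bfTrapezoidOracle(t, 28),
                 tolerance = 1e-4)
  }
  bf0 <- jzsBayesFactor(0, 28)
  expect_gt(bf0["bf01"], 1)
})

test_that("Bayes factors are reciprocal, monotone in |t|, and stable at the
          largest printed t", {
  prev <- 0
  for (t in c(0, 0.5, 1, 2, 4, 8, 20, 60.26)) {
    bf <- jzsBayesFactor(t, 28)
    expect_equal(unname(bf["bf10"] * bf["bf01"]), 1, tolerance = 1e-10)
    expect_gt(bf["bf10"], prev)
    expect_true(is.finite(log(bf["bf10"])))
    prev <- bf["bf10"]
  }
})

test_that("inferenceTest combines t, d, eta and BF consistently for
          one-sample and paired designs", {
  set.seed(81)
  x <- rnorm(28, 0.3)
  y <- rnorm(28, 0.1)
  paired <- inferenceTest(x, y)
  onesample <- inferenceTest(x - y, mu = 0)
  expect_equal(paired@t, onesample@t)
  expect_equal(paired@p, onesample@p)
  expect_equal(paired@bf10, onesample@bf10)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(paired@t, unname(ref$statistic))
  expect_equal(paired@df, 27)
  expect_equal(paired@d, paired@t / sqrt(28))
  expect_equal(paired@etaAdj, adjustedPartialEtaSq(paired@t, 27))
  expect_true(validObject(paired))
  expect_error(inferenceTest(rep(1, 10)), "zero variance")
  expect_error(inferenceTest(1), "at least 2")
})
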