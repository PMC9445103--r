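test_that("the default bank spans 2-20 Hz in 19 steps with reciprocal FWHM", {
  bank <- buildWavelets(200)
  expect_equal(bank@freqs, 2:20)
  expect_equal(bank@fwhmHz, seq(0.75, 4.25, length.out = 19))
  expect_equal(bank@fwhmMs / 1000 * bank@fwhmHz,
               rep(4 * log(2) / pi, 19))
  expect_true(validObject(bank))
  expect_error(buildWavelets(30), "Nyquist")
})

test_that("empirical temporal and spectral FWHM match the bank within 5%", {
  bank <- buildWavelets(200)
  for (k in c(1, 10, 19)) {
    ker <- waveletKernel(bank, k)
    aw <- Mod(ker$w)
    idx <- range(which(aw >= max(aw) / 2))
    empT <- (ker$t[idx[2]] - ker$t[idx[1]]) * 1000
    expect_lt(abs(empT - bank@fwhmMs[k]) / bank@fwhmMs[k], 0.05)
    nf <- 2^15
    sp <- Mod(stats::fft(c(ker$w, complex(real = rep(0, nf -
                                                       length(ker$w))))))
    fax <- (0:(nf - 1)) / nf * 200
    idx <- range(which(sp >= max(sp) / 2 & fax < 100))
    empF <- fax[idx[2]] - fax[idx[1]]
    expect_lt(abs(empF - bank@fwhmHz[k]) / bank@fwhmHz[k], 0.05)
  }
})

test_that("a pure sinusoid is resolved at the matching wavelet and power
          scales with amplitude squared", {
  sched <- makeSchedule(1, 4, seed = 1)[1, , drop = FALSE]
  bank <- buildWavelets(200)
  sinEpochs <- function(amp) {
    tms <- seq(-3700, 13700, by = 5)
    arr <- array(amp * sin(2 * pi * 10 * tms / 1000), c(1, 1, length(tms)))
    new("EpochSet", data = arr, sfreq = 200, times = tms, channels = "Cz",
        trialInfo = sched)
  }
  tfr1 <- tfrDecompose(sinEpochs(1), bank, decimate = 10L)
  prof <- apply(tfrPower(tfr1)[1, 1, , ], 1, mean)
  expect_equal(bank@freqs[which.max(prof)], 10)
  tfr2 <- tfrDecompose(sinEpochs(2), bank, decimate = 10L)
  expect_equal(sum(tfrPower(tfr2)), 4 * sum(tfrPower(tfr1)), tolerance = 1e-9)
  # zero signal -> zero power; determinism
  tfr0 <- tfrDecompose(sinEpochs(0), bank, decimate = 10L)
  expect_true(all(tfrPower(tfr0) == 0))
  expect_identical(tfrPower(tfr1),
                   tfrPower(tfrDecompose(sinEpochs(1), bank,
                                         decimate = 10L)))
})

test_that("edges are trimmed by 700 ms per side and short epochs error", {
  ep <- nullEpochsSmall()
  bank <- buildWavelets(200)
  tfr <- tfrDecompose(ep, bank, freqs = 10, decimate = 1L)
  expect_equal(min(sampleTimes(tfr)), min(sampleTimes(ep)) + 700)
  expect_equal(max(sampleTimes(tfr)), max(sampleTimes(ep)) - 700)
  short <- new("EpochSet",
               data = epochData(ep)[, , 1:200, drop = FALSE], sfreq = 200,
               times = sampleTimes(ep)[1:200], channels = channelNames(ep),
               trialInfo = trialInfo(ep))
  expect_error(tfrDecompose(short, bank, freqs = 10, trimMs = 700),
               "too short")
})

test_that("decibel conversion has the textbook fixed points and inverts
          exactly", {
  # constant power equal to the baseline -> 0 dB; tenfold power -> +10 dB
  tms <- seq(-1000, 1000, by = 50)
  pw <- array(2, c(3, 1, 2, length(tms)))
  pw[, , , tms > 0] <- 20
  tfr <- makeToyTfr(pw, freqs = c(5, 10), times = tms, channels = "Cz")
  db <- dbBaseline(tfr, window = c(-700, -200))
  expect_true(isDb(db))
  expect_equal(unique(as.numeric(tfrPower(db)[, , , tms < -800])), 0)
  expect_equal(unique(as.numeric(tfrPower(db)[, , , tms > 0])), 10)
  back <- dbToRaw(db)
  expect_equal(tfrPower(back), tfrPower(tfr), tolerance = 1e-12)
  expect_error(dbBaseline(db), "already")
})

test_that("condition contrasts in dB do not depend on the shared baseline", {
  # with a condition-general baseline, the dB difference between condition
  # averages equals 10*log10(Pa/Pb) whatever the baseline values are
  set.seed(11)
  tms <- seq(-1000, 1000, by = 100)
  mk <- function() array(stats::rexp(8 * 2 * 2 * length(tms)) + 0.5,
                         c(8, 2, 2, length(tms)))
  pooled <- makeToyTfr(abind2(mk(), mk()), freqs = c(5, 10), times = tms,
                       channels = c("C3", "C4"))
  avgA <- tfrAverage(pooled, trials = 1:8)
  avgB <- tfrAverage(pooled, trials = 9:16)
  dbA <- dbBaseline(avgA, baselineFrom = pooled, window = c(-700, -200))
  dbB <- dbBaseline(avgB, baselineFrom = pooled, window = c(-700, -200))
  expect_equal(tfrPower(dbA) - tfrPower(dbB),
               10 * log10(tfrPower(avgA) / tfrPower(avgB)),
               tolerance = 1e-12)
})

test_that("zero baseline power is reported per channel and frequency", {
  tms <- seq(-1000, 1000, by = 100)
  pw <- array(1, c(2, 2, 1, length(tms)))
  pw[, 2, 1, ] <- 0
  tfr <- makeToyTfr(pw, freqs = 5, times = tms, channels = c("C3", "C4"))
  expect_error(dbBaseline(tfr, window = c(-700, -200)), "C4/5 Hz")
})
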