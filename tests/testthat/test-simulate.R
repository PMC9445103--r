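test_that("identical seed and spec give bit-identical epochs", {
  sched <- makeSchedule(1, 8, seed = 1)
  a <- simulateEpochs(sched, effectSpec(), channels = c("C3", "C4", "O1",
                                                        "O2"), seed = 9)
  b <- simulateEpochs(sched, effectSpec(), channels = c("C3", "C4", "O1",
                                                        "O2"), seed = 9)
  expect_identical(epochData(a), epochData(b))
  c <- simulateEpochs(sched, effectSpec(), channels = c("C3", "C4", "O1",
                                                        "O2"), seed = 10)
  expect_false(identical(epochData(a), epochData(c)))
})

test_that("the epoch container matches the paradigm geometry", {
  ep <- nullEpochsSmall()
  expect_s4_class(ep, "EpochSet")
  expect_true(validObject(ep))
  tms <- sampleTimes(ep)
  expect_equal(range(tms), c(-3700, 13700))
  expect_equal(unique(round(diff(tms), 9)), 5)  # 200 Hz
  expect_equal(nrow(trialInfo(ep)), dim(epochData(ep))[1])
})

test_that("unknown channel labels in the effect spec raise a montage error", {
  sched <- makeSchedule(1, 8, seed = 1)
  spec <- effectSpec(bandEffects = list(
    list(freq = 5, window = c(0, 500), channels = c("XX9"),
         condition = "NCT", amplitude = 1)))
  expect_error(simulateEpochs(sched, spec, channels = c("C3", "C4"),
                              seed = 1),
               "unknown channel")
})

test_that("windows outside the epoch are rejected", {
  sched <- makeSchedule(1, 8, seed = 1)
  spec <- effectSpec(bandEffects = list(
    list(freq = 5, window = c(13000, 14500), channels = "all",
         condition = "NCT", amplitude = 1)))
  expect_error(simulateEpochs(sched, spec, channels = c("C3", "C4"),
                              seed = 1),
               "outside the time axis")
  expect_error(effectSpec(noise = list(pinkSd = -1, whiteSd = 0,
                                       exponent = 1)),
               "non-negative")
})

test_that("a planted oscillatory burst raises band power inside its window
          only", {
  sched <- makeSchedule(1, 16, seed = 2)
  spec <- effectSpec(
    noise = list(pinkSd = 2, whiteSd = 0.5, exponent = 1),
    bandEffects = list(list(freq = 5, window = c(3000, 5600),
                            channels = "all", condition = "all",
                            amplitude = 4)),
    lateralization = list(), decoding = list())
  ep <- simulateEpochs(sched, spec, channels = c("Pz", "P3"), seed = 3)
  bank <- buildWavelets(200)
  tfr <- tfrDecompose(ep, bank, freqs = 5, decimate = 10L)
  pw <- apply(tfrPower(tfr), 4, mean)
  tms <- sampleTimes(tfr)
  inWin <- mean(pw[tms > 3500 & tms < 5100])
  outWin <- mean(pw[tms > 7000 & tms < 12000])
  expect_gt(inWin, 3 * outWin)
})
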