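# Small decoding problems: features restricted to a short window keep the
# number of SVM fits low.

# amplitudes scaled up for the reduced test design (few channels, group
# size ~2), so the planted window is unambiguously decodable
plantedFeatureSet <- function() {
  fixture("plantedFeatureSet", function() {
    sched <- makeSchedule(4, 40, seed = 601)
    spec <- effectSpec(bandEffects = list(), lateralization = list(),
                       decoding = list(window = c(5600, 8000),
                                       erpAmplitude = 10, erpFreq = 2,
                                       alphaAmplitude = 10, alphaFreq = 10))
    ep <- simulateEpochs(sched, spec, channels = smallMontage(8)$channel,
                         seed = 602)
    list(ep = ep, md = trialInfo(ep))
  })
}

test_that("feature tensors have the documented dimensionality", {
  ep <- nullEpochsSmall()  # 4 channels
  f <- prepareFeatures(ep, "broadband_erp", timeRange = c(0, 2000))
  expect_equal(dim(f$features)[2], length(channelNames(ep)))
  expect_equal(diff(f$times)[1], 50)  # 20 Hz
  tfr <- tfrDecompose(ep, buildWavelets(200), freqs = 8:12, decimate = 10L)
  fa <- prepareFeatures(tfr, "alpha_power", timeRange = c(0, 2000))
  expect_equal(dim(fa$features)[2], length(channelNames(ep)) * 5)
  # constant input -> constant features
  cep <- ep
  cep@data[] <- 3
  fc <- prepareFeatures(cep, "broadband_erp", timeRange = c(0, 2000))
  expect_true(all(fc$features == 3))
  expect_error(prepareFeatures(tfr, "alpha_power", alphaFreqs = 30:34),
               "alpha frequencies")
})

test_that("decoding needs two classes with at least nGroups trials each", {
  px <- plantedFeatureSet()
  f <- prepareFeatures(px$ep, "broadband_erp", timeRange = c(6000, 6400))
  expect_error(decodeTimecourse(f, rep("a", nrow(px$md))),
               "two classes")
  expect_error(decodeTimecourse(f, px$md$classification_type, nGroups = 200),
               "insufficient data")
})

test_that("strong planted patterns decode above chance inside their window
          and at chance outside; seeds reproduce", {
  px <- plantedFeatureSet()
  f <- prepareFeatures(px$ep, "broadband_erp", timeRange = c(1000, 8000))
  res <- decodeTimecourse(f, px$md$classification_type, seed = 11)
  expect_s4_class(res, "DecodingResult")
  expect_true(validObject(res))
  expect_equal(res@nPredictions, res@nIter * res@nGroups * 2)
  tms <- sampleTimes(res)
  inWin <- mean(accuracyCurve(res)[tms > 6000 & tms < 7600])
  outWin <- mean(accuracyCurve(res)[tms < 4500])
  expect_gt(inWin, 0.65)
  expect_gt(inWin, outWin + 0.15)
  expect_lt(abs(outWin - 0.5), 0.1)
  res2 <- decodeTimecourse(f, px$md$classification_type, seed = 11)
  expect_identical(accuracyCurve(res), accuracyCurve(res2))
  res3 <- decodeTimecourse(f, px$md$classification_type, seed = 12)
  expect_false(identical(accuracyCurve(res), accuracyCurve(res3)))
})

test_that("identically distributed classes decode at chance", {
  # class labels carry no signal on pure-noise data, so the two class
  # distributions coincide and accuracy fluctuates around 0.5
  sched <- makeSchedule(2, 40, seed = 621)
  ep <- simulateEpochs(sched, nullEffectSpec(),
                       channels = smallMontage(8)$channel, seed = 622)
  f <- prepareFeatures(ep, "broadband_erp", timeRange = c(5600, 8000))
  res <- decodeTimecourse(f, trialInfo(ep)$classification_type, seed = 13)
  expect_lt(abs(mean(accuracyCurve(res, smoothed = FALSE)) - 0.5), 0.08)
})

test_that("group averaging outperforms single-trial decoding on the same
          folds", {
  sched <- makeSchedule(4, 40, seed = 611)
  spec <- effectSpec(bandEffects = list(), lateralization = list(),
                     decoding = list(window = c(5600, 8000),
                                     erpAmplitude = 6, erpFreq = 2,
                                     alphaAmplitude = 0, alphaFreq = 10))
  ep <- simulateEpochs(sched, spec, channels = smallMontage(8)$channel,
                       seed = 612)
  f <- prepareFeatures(ep, "broadband_erp", timeRange = c(6200, 7200))
  lab <- trialInfo(ep)$classification_type
  avg <- decodeTimecourse(f, lab, seed = 14)
  single <- decodeTimecourse(f, lab, seed = 14, average = FALSE)
  expect_gte(mean(accuracyCurve(avg, smoothed = FALSE)),
             mean(accuracyCurve(single, smoothed = FALSE)))
})

test_that("confusion summaries are symmetric for symmetric signals", {
  px <- plantedFeatureSet()
  f <- prepareFeatures(px$ep, "broadband_erp", timeRange = c(6000, 7400))
  res <- decodeTimecourse(f, px$md$classification_type, seed = 15)
  acc <- confusionSummary(res, c(6000, 7400))
  expect_length(acc, 2)
  expect_lt(abs(acc[1] - acc[2]), 0.1)
  expect_error(confusionSummary(res, c(20000, 21000)), "no decode time")
})

test_that("the fast libsvm path agrees with e1071::svm decision values", {
  set.seed(71)
  for (rep in 1:5) {
    X <- matrix(rnorm(28 * 12), 28, 12)
    y <- rep(1:2, each = 14)
    Xt <- matrix(rnorm(6 * 12), 6, 12)
    fit <- prioEEG:::.svmLinearTrain(X, y)
    ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
    dFast <- as.numeric(Xt %*% fit$w - fit$rho)
    dRef <- attr(predict(ref, Xt, decision.values = TRUE),
                 "decision.values")
    expect_equal(dFast, as.numeric(dRef), tolerance = 1e-10)
    predFast <- prioEEG:::.svmPredict(fit, Xt)
    expect_equal(as.integer(as.character(predict(ref, Xt))), predFast)
  }
})
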