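balancedMeta <- function(counts) {
  cells <- expand.grid(retrocue_side = c("left", "right"),
                       response_side = c("left", "right"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(4), function(i) {
    cells[rep(i, counts[i]), , drop = FALSE]
  }))
}

test_that("balanced drawing truncates every cell to the smallest one", {
  md <- balancedMeta(c(10, 10, 10, 10))
  expect_length(drawBalancedTrials(md, seed = 1), 40)
  md2 <- balancedMeta(c(10, 8, 9, 10))
  sel <- drawBalancedTrials(md2, seed = 1)
  expect_length(sel, 32)
  tab <- table(md2$retrocue_side[sel], md2$response_side[sel])
  expect_true(all(tab == 8))
  expect_identical(sel, drawBalancedTrials(md2, seed = 1))
  md3 <- balancedMeta(c(10, 0, 9, 10))
  expect_error(drawBalancedTrials(md3, seed = 1), "non-empty")
})

test_that("the index reproduces hand-computed values and boundaries", {
  # 2 trials (one per cue side), 1 pair, constant power in time/freq
  pw <- array(0, c(2, 2, 1, 3))
  pw[1, 1, 1, ] <- 3  # cue left: left channel (ipsi) = 3
  pw[1, 2, 1, ] <- 1  # cue left: right channel (contra) = 1
  pw[2, 1, 1, ] <- 1  # cue right: left channel (contra) = 1
  pw[2, 2, 1, ] <- 3  # cue right: right channel (ipsi) = 3
  md <- data.frame(retrocue_side = c("left", "right"))
  tfr <- makeToyTfr(pw, freqs = 10, times = 1:3, channels = c("O1", "O2"),
                    trialInfo = md)
  lat <- lateralizationIndex(tfr, metadata = md,
                             pairing = data.frame(left = "O1",
                                                  right = "O2"),
                             pooledPairs = data.frame(left = "O1",
                                                      right = "O2"),
                             pooledBand = c(8, 15))
  expect_equal(as.numeric(lat@index), rep(0.5, 3))
  expect_equal(pooledIndex(lat), rep(0.5, 3))

  # equal power on both members -> 0; zero contra -> boundary 1
  pw0 <- pw; pw0[] <- 2
  lat0 <- lateralizationIndex(makeToyTfr(pw0, 10, 1:3, c("O1", "O2"), md),
                              metadata = md,
                              pairing = data.frame(left = "O1",
                                                   right = "O2"),
                              pooledPairs = data.frame(left = "O1",
                                                       right = "O2"))
  expect_equal(as.numeric(lat0@index), rep(0, 3))
  pwB <- pw
  pwB[1, 2, 1, ] <- 0; pwB[2, 1, 1, ] <- 0
  latB <- lateralizationIndex(makeToyTfr(pwB, 10, 1:3, c("O1", "O2"), md),
                              metadata = md,
                              pairing = data.frame(left = "O1",
                                                   right = "O2"),
                              pooledPairs = data.frame(left = "O1",
                                                       right = "O2"))
  expect_equal(as.numeric(latB@index), rep(1, 3))
})

test_that("the index is bounded, antisymmetric under cue flips, and scale
          invariant", {
  set.seed(31)
  n <- 12
  pw <- array(stats::rexp(n * 4 * 2 * 5), c(n, 4, 2, 5))
  md <- data.frame(retrocue_side = rep(c("left", "right"), n / 2))
  pairing <- data.frame(left = c("O1", "P3"), right = c("O2", "P4"))
  tfr <- makeToyTfr(pw, c(9, 11), 1:5, c("O1", "O2", "P3", "P4"), md)
  lat <- lateralizationIndex(tfr, metadata = md, pairing = pairing,
                             pooledPairs = pairing)
  expect_true(all(lat@index >= -1 & lat@index <= 1))
  mdF <- md
  mdF$retrocue_side <- ifelse(md$retrocue_side == "left", "right", "left")
  latF <- lateralizationIndex(tfr, metadata = mdF, pairing = pairing,
                              pooledPairs = pairing)
  expect_equal(latF@index, -lat@index)
  tfrS <- makeToyTfr(pw * 7.3, c(9, 11), 1:5, c("O1", "O2", "P3", "P4"), md)
  latS <- lateralizationIndex(tfrS, metadata = md, pairing = pairing,
                              pooledPairs = pairing)
  expect_equal(latS@index, lat@index, tolerance = 1e-12)
})

test_that("decibel input and unpaired channels are rejected", {
  pw <- array(1, c(2, 2, 1, 3))
  md <- data.frame(retrocue_side = c("left", "right"))
  tfr <- makeToyTfr(pw, 10, 1:3, c("O1", "O2"), md)
  db <- dbBaseline(makeToyTfr(array(1, c(2, 2, 1, 5)), 10,
                              c(-800, -600, -400, -200, 0),
                              c("O1", "O2"), md))
  expect_error(lateralizationIndex(db, metadata = md,
                                   pairing = data.frame(left = "O1",
                                                        right = "O2")),
               "raw")
  expect_error(lateralizationIndex(tfr, metadata = md,
                                   pairing = data.frame(left = "O1",
                                                        right = "Oz")),
               "unpaired")
})

test_that("a planted asymmetry is recovered at its target magnitude and
          flagged by the 1-D cluster test", {
  # a few "subjects" sharing the generator's default 0.05 asymmetry; the
  # full posterior pair set keeps the index estimator's simulation error
  # well below the 0.01 recovery band
  nSub <- 6
  post <- posteriorPairs()
  chans <- c(post$left, post$right)
  curves <- NULL
  for (s in seq_len(nSub)) {
    sched <- makeSchedule(2, 24, seed = 300 + s)
    beh <- simulateBehavior(sched, seed = 350 + s)
    spec <- effectSpec(bandEffects = list(), decoding = list())
    ep <- simulateEpochs(sched, spec, behavior = beh, channels = chans,
                         seed = 400 + s)
    tfr <- tfrDecompose(ep, buildWavelets(200), freqs = 8:15,
                        decimate = 10L)
    md <- trialInfo(ep)
    bal <- drawBalancedTrials(md, seed = 500 + s)
    lat <- lateralizationIndex(tfr, pairing = mirrorPairs(chans),
                               trials = bal)
    curves <- rbind(curves, pooledIndex(lat))
    tms <- sampleTimes(lat)
  }
  plateau <- mean(curves[, tms >= 9900 & tms <= 10500])
  expect_lt(abs(plateau - 0.05), 0.01)
  outside <- mean(curves[, tms >= 1000 & tms <= 8000])
  expect_lt(abs(outside), 0.01)
  ct <- clusterTest1d(curves, reference = 0, times = tms, nPerm = 500,
                      seed = 1)
  sig <- clusterTable(ct)
  expect_true(any(sig$p < 0.05 & sig$sign > 0 &
                    sig$centroidTime > 9600 & sig$centroidTime < 10800))
})
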