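test_that("identical conditions produce no suprathreshold pixels", {
  set.seed(21)
  a <- array(rnorm(6 * 4 * 3 * 10), c(6, 4, 3, 10))
  g <- buildAdjacency(smallMontage(4), 2.1)
  expect_warning(
    r <- clusterTest3d(a, a, g, freqs = 1:3, times = 1:10, nPerm = 50,
                       seed = 1),
    "zero-variance")
  expect_equal(nrow(clusterTable(r)), 0)
  expect_false(any(significanceMask(r)))
})

test_that("single-pixel inference matches exhaustive sign-flip enumeration
          exactly", {
  set.seed(22)
  for (n in c(8, 10, 12)) {
    x <- matrix(rnorm(n, mean = 0.45), n, 1)
    res <- clusterTest1d(x, reference = 0, times = 0, nPerm = 0,
                         exact = TRUE)
    pOracle <- exactSignFlipOracle(x[, 1])
    if (is.null(pOracle)) {
      expect_equal(nrow(clusterTable(res)), 0)
    } else {
      expect_equal(clusterTable(res)$p, pOracle, tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo p approaches the exact enumeration p", {
  set.seed(23)
  n <- 10
  x <- matrix(rnorm(n, mean = 0.55), n, 1)
  exact <- clusterTest1d(x, reference = 0, times = 0, nPerm = 0,
                         exact = TRUE)
  mc <- clusterTest1d(x, reference = 0, times = 0, nPerm = 4000, seed = 9)
  expect_equal(clusterTable(mc)$p, clusterTable(exact)$p, tolerance = 0.02)
})

test_that("label exchange flips cluster signs but keeps the inference", {
  set.seed(24)
  g <- buildAdjacency(smallMontage(4), 2.1)
  a <- array(rnorm(8 * 4 * 3 * 10), c(8, 4, 3, 10))
  b <- a + array(rnorm(length(a), 0.6), dim(a))
  r1 <- clusterTest3d(a, b, g, freqs = 1:3, times = 1:10, nPerm = 300,
                      seed = 5)
  r2 <- clusterTest3d(b, a, g, freqs = 1:3, times = 1:10, nPerm = 300,
                      seed = 5)
  expect_equal(sort(clusterTable(r1)$mass), sort(-clusterTable(r2)$mass))
  expect_equal(sort(clusterTable(r1)$p), sort(clusterTable(r2)$p))
  expect_equal(statMap(r1), -statMap(r2))
})

test_that("scaling a planted effect up never decreases the max cluster
          mass", {
  set.seed(25)
  g <- buildAdjacency(smallMontage(4), 2.1)
  noiseA <- array(rnorm(8 * 4 * 3 * 12), c(8, 4, 3, 12))
  noiseB <- array(rnorm(8 * 4 * 3 * 12), c(8, 4, 3, 12))
  bump <- array(0, c(8, 4, 3, 12))
  bump[, 1:2, 2, 4:8] <- 1
  prev <- -Inf
  for (amp in c(0, 0.4, 0.8, 1.6)) {
    r <- clusterTest3d(noiseA + amp * bump, noiseB, g, freqs = 1:3,
                       times = 1:12, nPerm = 10, seed = 2)
    mx <- if (nrow(clusterTable(r))) max(abs(clusterTable(r)$mass)) else 0
    expect_gte(mx, prev)
    prev <- mx
  }
})

test_that("1-D variants handle degenerate inputs and paired self-comparison", {
  tms <- seq(0, 950, by = 50)
  zero <- matrix(0, 6, length(tms))
  expect_warning(r <- clusterTest1d(zero, reference = 0, times = tms,
                                    nPerm = 20, seed = 1),
                 "zero-variance")
  expect_equal(nrow(clusterTable(r)), 0)
  set.seed(26)
  v <- matrix(rnorm(6 * length(tms), 1), 6, length(tms))
  expect_warning(r2 <- clusterTest1d(v, partner = v, times = tms, nPerm = 20,
                                     seed = 1),
                 "zero-variance")
  expect_equal(nrow(clusterTable(r2)), 0)
})

test_that("shape mismatches and bad annotations are rejected", {
  g <- buildAdjacency(smallMontage(4), 2.1)
  a <- array(rnorm(6 * 4 * 3 * 10), c(6, 4, 3, 10))
  expect_error(clusterTest3d(a, a[1:5, , , ], g, freqs = 1:3, times = 1:10),
               "identical shape")
  expect_error(clusterTest3d(a, a, g, freqs = 1:2, times = 1:10),
               "annotations")
  expect_error(clusterTest3d(a[1, , , , drop = FALSE],
                             a[1, , , , drop = FALSE] + 1, g,
                             freqs = 1:3, times = 1:10),
               "2 subjects")
})

test_that("the effect-size map is the adjusted partial eta squared of the
          t map", {
  set.seed(27)
  x <- matrix(rnorm(8 * 5, 0.5), 8, 5)
  r <- clusterTest1d(x, reference = 0, times = 1:5, nPerm = 20, seed = 1)
  em <- effectSizeMap(r)
  expect_equal(as.numeric(em),
               adjustedPartialEtaSq(as.numeric(statMap(r)), 7))
})
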