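# Nonparametric cluster-based permutation inference over
# electrode x frequency x time grids (paired) and over time courses
# (one-sample or paired), with sign-flipping null distributions and the
# max-cluster-mass statistic.

.signMatrix <- function(n, nPerm, seed, exact) {
  if (exact) {
    if (n > 14)
      stop("exact enumeration supported for n <= 14 subjects (2^n sign ",
           "assignments)")
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    .withSeed(seed,
      matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
  }
}

.runClusterEngine <- function(diffs, dims, nbrs0, clusterAlpha, alpha,
                              nPerm, seed, exact, channels, freqs, times) {
  n <- nrow(diffs)
  if (n < 2) stop("at least 2 subjects are required")
  df <- n - 1
  tcrit <- stats::qt(1 - clusterAlpha / 2, df)
  signs <- .signMatrix(n, nPerm, seed, exact)
  eng <- .clusterPermEngine(diffs, as.integer(dims), nbrs0, tcrit, signs)
  if (eng$nZeroVar > 0)
    warning(eng$nZeroVar, " zero-variance pixel(s); their t was set to 0")

  nclust <- length(eng$masses)
  nPermEff <- nrow(signs)
  if (nclust > 0) {
    p <- vapply(abs(eng$masses), function(m) {
      hits <- sum(eng$permMax >= m - 1e-12)
      if (exact) hits / nPermEff else (1 + hits) / (1 + nPermEff)
    }, numeric(1))
    lab <- eng$labels
    pix <- split(seq_along(lab)[lab > 0], lab[lab > 0])
    cent <- t(vapply(pix, function(jj) {
      jj0 <- jj - 1L
      ch <- jj0 %% dims[1] + 1L
      f <- (jj0 %/% dims[1]) %% dims[2] + 1L
      tt <- jj0 %/% (dims[1] * dims[2]) + 1L
      c(chMode = as.numeric(which.max(tabulate(ch, dims[1]))),
        freq = mean(freqs[f]), time = mean(times[tt]))
    }, numeric(3)))
    clusters <- data.frame(
      id = seq_len(nclust),
      sign = ifelse(eng$masses > 0, 1L, -1L),
      mass = eng$masses,
      nPixels = lengths(pix),
      p = p,
      centroidChannel = channels[cent[, "chMode"]],
      centroidFreq = cent[, "freq"],
      centroidTime = cent[, "time"],
      row.names = NULL, stringsAsFactors = FALSE
    )
    clusters <- clusters[order(clusters$p, -abs(clusters$mass)), ]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(id = integer(0), sign = integer(0),
                           mass = numeric(0), nPixels = integer(0),
                           p = numeric(0), centroidChannel = character(0),
                           centroidFreq = numeric(0),
                           centroidTime = numeric(0))
  }

  labArr <- array(eng$labels, dims)
  sigIds <- clusters$id[clusters$p < alpha]
  maskArr <- array(labArr %in% sigIds, dims)
  new("ClusterTestResult",
      tmap = array(eng$t, dims), df = df, clusters = clusters,
      labels = labArr, mask = maskArr, permMax = as.numeric(eng$permMax),
      alpha = alpha, clusterAlpha = clusterAlpha, nPerm = nPermEff,
      exact = exact, seed = as.numeric(seed), channels = channels,
      freqs = freqs, times = times)
}

#' 3-D cluster-based permutation test (paired)
#'
#' Compares two within-subject conditions at every pixel of the
#' electrode x frequency x time space with paired t tests, clusters
#' suprathreshold pixels of equal sign that are adjacent spatially (montage
#' neighbours), spectrally or temporally (nearest neighbours), and evaluates
#' each cluster's mass (sum of t) against the permutation distribution of the
#' maximum absolute cluster mass obtained by sign-flipping the subject-wise
#' condition differences. Monte-Carlo p values use the +1 correction
#' `p = (1 + #\{perm max >= observed\}) / (1 + nPerm)`; with `exact = TRUE`
#' all `2^n` sign assignments are enumerated instead and
#' `p = #\{perm max >= observed\} / 2^n`.
#'
#' @param condA,condB numeric arrays subjects x channels x frequencies x time
#'   (decibel-normalised condition means), identical shape.
#' @param graph an [AdjacencyGraph-class] matching the channel axis.
#' @param freqs,times axis annotations (Hz, ms).
#' @param nPerm number of random sign-flip permutations (default 1000).
#' @param clusterAlpha two-sided per-pixel cluster-forming alpha
#'   (default 0.05).
#' @param alpha family-wise alpha for the significance mask (default 0.05).
#' @param seed RNG seed for the permutation draw.
#' @param exact enumerate all sign assignments (requires n <= 14).
#' @return a [ClusterTestResult-class].
#' @export
clusterTest3d <- function(condA, condB, graph, freqs, times, nPerm = 1000,
                          clusterAlpha = 0.05, alpha = 0.05, seed = 1,
                          exact = FALSE) {
  stopifnot(is(graph, "AdjacencyGraph"))
  if (!identical(dim(condA), dim(condB)))
    stop("condA and condB must have identical shape")
  d <- dim(condA)
  if (length(d) != 4L)
    stop("inputs must be 4-d arrays: subjects x channels x freqs x time")
  if (d[2] != length(graph@channels))
    stop("channel axis does not match the adjacency graph")
  if (d[3] != length(freqs) || d[4] != length(times))
    stop("freqs/times annotations do not match the input shape")
  diffs <- condA - condB
  dim(diffs) <- c(d[1], prod(d[2:4]))
  nbrs0 <- lapply(graph@neighbors, function(v) as.integer(v - 1L))
  .runClusterEngine(diffs, d[2:4], nbrs0, clusterAlpha, alpha, nPerm, seed,
                    exact, graph@channels, freqs, times)
}

#' 1-D cluster-based permutation test over time
#'
#' One-sample (against a scalar reference such as 0 or chance level) or
#' paired (against a partner curve) cluster test over a common time axis,
#' with clusters contiguous in time only. Inference is as in
#' [clusterTest3d()].
#'
#' @param values numeric matrix subjects x time.
#' @param reference scalar reference value (default 0); ignored when
#'   `partner` is given.
#' @param partner optional matrix subjects x time for a paired comparison.
#' @param times time axis in ms.
#' @inheritParams clusterTest3d
#' @return a [ClusterTestResult-class].
#' @export
clusterTest1d <- function(values, reference = 0, partner = NULL, times,
                          nPerm = 1000, clusterAlpha = 0.05, alpha = 0.05,
                          seed = 1, exact = FALSE) {
  values <- as.matrix(values)
  if (!is.null(partner)) {
    partner <- as.matrix(partner)
    if (!identical(dim(values), dim(partner)))
      stop("values and partner must have identical shape")
    diffs <- values - partner
  } else {
    diffs <- values - reference
  }
  if (ncol(diffs) != length(times))
    stop("times annotation does not match the number of time points")
  .runClusterEngine(diffs, c(1L, 1L, ncol(diffs)), list(integer(0)),
                    clusterAlpha, alpha, nPerm, seed, exact,
                    "pooled", 0, times)
}

#' Adjusted partial eta squared map of a cluster test
#'
#' Per-pixel effect size computed from the observed t map via `F = t^2` and
#' the adjusted-partial-eta-squared formula (see [adjustedPartialEtaSq()]).
#'
#' @param result a [ClusterTestResult-class].
#' @return numeric array shaped like the t map.
#' @export
effectSizeMap <- function(result) {
  stopifnot(is(result, "ClusterTestResult"))
  array(adjustedPartialEtaSq(result@tmap, result@df), dim(result@tmap))
}
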