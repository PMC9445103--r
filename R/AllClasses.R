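#' @import methods
NULL

#' Epoched multichannel EEG data
#'
#' Container for epoched EEG: a numeric array of trials x channels x samples
#' (microvolts), a uniform time axis in milliseconds relative to the
#' relevance-cue onset, and a per-trial metadata table (trial schedule plus,
#' optionally, behavioural outcomes and feedback scores).
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot sfreq sampling frequency in Hz.
#' @slot times sample times in ms, strictly increasing, uniform at 1000/sfreq.
#' @slot channels character vector of channel labels (10-10 montage).
#' @slot trialInfo data.frame with one row per trial.
#'
#' @seealso [simulateEpochs()], [tfrDecompose()]
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    sfreq = "numeric",
    times = "numeric",
    channels = "character",
    trialInfo = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character(0)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x samples)")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel count does not match length(channels)")
    if (d[3] != length(object@times))
      msg <- c(msg, "sample count does not match length(times)")
    if (nrow(object@trialInfo) != d[1])
      msg <- c(msg, "trialInfo row count does not match trial count")
  }
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (max(abs(dt - 1000 / object@sfreq)) > 1e-6)
      msg <- c(msg, "times must be uniform at 1000/sfreq ms")
  }
  if (anyDuplicated(object@channels))
    msg <- c(msg, "duplicated channel labels")
  if (length(msg)) msg else TRUE
})

#' Complex Morlet wavelet bank
#'
#' A family of complex Morlet wavelets parameterised by their Gaussian-envelope
#' full width at half maximum (FWHM). The spectral FWHM (of the amplitude
#' spectrum) is the primary parameter; the temporal FWHM follows from the
#' Gaussian time-frequency reciprocity `fwhm_t * fwhm_f = 4 log(2) / pi`.
#'
#' @slot freqs centre frequencies in Hz, strictly increasing.
#' @slot fwhmHz spectral FWHM per wavelet in Hz.
#' @slot fwhmMs temporal FWHM per wavelet in ms.
#' @slot sigmaSec temporal standard deviation of the Gaussian envelope (s).
#' @slot sfreq sampling frequency the bank was built for (Hz).
#'
#' @seealso [buildWavelets()]
#' @export
setClass("WaveletBank",
  representation(
    freqs = "numeric",
    fwhmHz = "numeric",
    fwhmMs = "numeric",
    sigmaSec = "numeric",
    sfreq = "numeric"
  )
)

setValidity("WaveletBank", function(object) {
  msg <- character(0)
  if (any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(object@fwhmHz) != length(object@freqs) ||
      length(object@fwhmMs) != length(object@freqs) ||
      length(object@sigmaSec) != length(object@freqs))
    msg <- c(msg, "fwhmHz, fwhmMs and sigmaSec must match freqs in length")
  recip <- object@fwhmMs / 1000 * object@fwhmHz
  if (length(recip) && max(abs(recip - 4 * log(2) / pi)) > 1e-8)
    msg <- c(msg, "temporal and spectral FWHM violate Gaussian reciprocity")
  if (length(msg)) msg else TRUE
})

#' Time-frequency power representation
#'
#' Power values from complex Morlet convolution: an array of
#' (trials or 1) x channels x frequencies x time, either raw (linear, >= 0)
#' or decibel-normalised against a pre-cue baseline.
#'
#' @slot power numeric array, (trials|1) x channels x frequencies x samples.
#' @slot freqs wavelet centre frequencies (Hz).
#' @slot times time axis in ms (edge-trimmed relative to the input epochs).
#' @slot channels channel labels.
#' @slot isDb TRUE when power is in dB relative to a baseline.
#' @slot baselineWindow baseline window in ms (length 2) if dB, else numeric(0).
#' @slot baseline channels x frequencies matrix of baseline power (dB sets
#'   only; 0 x 0 otherwise). Kept so dB values can be mapped back to raw
#'   power.
#' @slot trialInfo per-trial metadata (0 rows allowed for averaged data).
#'
#' @seealso [tfrDecompose()], [dbBaseline()], [tfrAverage()]
#' @export
setClass("TFRSet",
  representation(
    power = "array",
    freqs = "numeric",
    times = "numeric",
    channels = "character",
    isDb = "logical",
    baselineWindow = "numeric",
    baseline = "matrix",
    trialInfo = "data.frame"
  )
)

setValidity("TFRSet", function(object) {
  d <- dim(object@power)
  msg <- character(0)
  if (length(d) != 4L)
    msg <- c(msg, "power must be a 4-d array (trials x channels x freqs x time)")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel count mismatch")
    if (d[3] != length(object@freqs))
      msg <- c(msg, "frequency count mismatch")
    if (d[4] != length(object@times))
      msg <- c(msg, "time axis mismatch")
    if (nrow(object@trialInfo) > 0 && nrow(object@trialInfo) != d[1])
      msg <- c(msg, "trialInfo row count does not match trial count")
  }
  if (!object@isDb && length(object@power) && min(object@power) < 0)
    msg <- c(msg, "raw (linear) power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Channel adjacency graph
#'
#' Spatial neighbourhood structure over montage channels used to form clusters.
#' Temporal and spectral adjacency are always nearest-neighbour along their
#' axes and need no explicit representation.
#'
#' @slot channels channel labels.
#' @slot neighbors list of integer vectors; `neighbors[[i]]` holds the indices
#'   of channels adjacent to channel i. Symmetric, no self edges.
#' @slot threshold the Euclidean distance threshold used, if any.
#'
#' @seealso [buildAdjacency()]
#' @export
setClass("AdjacencyGraph",
  representation(
    channels = "character",
    neighbors = "list",
    threshold = "numeric"
  )
)

setValidity("AdjacencyGraph", function(object) {
  msg <- character(0)
  if (length(object@neighbors) != length(object@channels))
    msg <- c(msg, "one neighbor vector per channel required")
  for (i in seq_along(object@neighbors)) {
    nb <- object@neighbors[[i]]
    if (i %in% nb) {
      msg <- c(msg, "self edges are not allowed")
      break
    }
    bad <- vapply(nb, function(j) !(i %in% object@neighbors[[j]]), logical(1))
    if (any(bad)) {
      msg <- c(msg, "adjacency must be symmetric")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cluster-based permutation test result
#'
#' Observed per-pixel t map, clusters of connected suprathreshold pixels with
#' their mass statistics and Monte-Carlo p values, and the family-wise
#' significance mask at `alpha`.
#'
#' @slot tmap observed t statistic, array channels x freqs x time (degenerate
#'   axes have extent 1).
#' @slot df degrees of freedom of the per-pixel t.
#' @slot clusters data.frame: id, sign, mass, nPixels, p, and centroid
#'   coordinates (channel index, freq, time).
#' @slot labels integer array of cluster memberships (0 = background).
#' @slot mask logical array: pixels in clusters with p < alpha.
#' @slot permMax permutation distribution of the maximum absolute cluster mass.
#' @slot alpha family-wise alpha.
#' @slot clusterAlpha per-pixel cluster-forming alpha.
#' @slot nPerm number of permutations used (2^n for exact enumeration).
#' @slot exact TRUE when all sign assignments were enumerated.
#' @slot seed RNG seed of the permutation draw.
#' @slot channels,freqs,times axis annotations.
#'
#' @seealso [clusterTest3d()], [clusterTest1d()]
#' @export
setClass("ClusterTestResult",
  representation(
    tmap = "array",
    df = "numeric",
    clusters = "data.frame",
    labels = "array",
    mask = "array",
    permMax = "numeric",
    alpha = "numeric",
    clusterAlpha = "numeric",
    nPerm = "numeric",
    exact = "logical",
    seed = "numeric",
    channels = "character",
    freqs = "numeric",
    times = "numeric"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character(0)
  if (nrow(object@clusters) &&
      (any(object@clusters$p <= 0) || any(object@clusters$p > 1)))
    msg <- c(msg, "cluster p values must lie in (0, 1]")
  if (any(object@mask & object@labels == 0L))
    msg <- c(msg, "mask must be a subset of labelled cluster pixels")
  if (length(msg)) msg else TRUE
})

#' Hemispheric lateralization of oscillatory power
#'
#' Lateralization index `(ipsi - contra) / (ipsi + contra)` of trial-averaged
#' raw power relative to the retro-cue direction, per mirror electrode pair,
#' frequency and time point, plus the pooled time course averaged over the
#' posterior pairs and the pooled frequency band.
#'
#' @slot index numeric array pairs x freqs x time, in [-1, 1].
#' @slot pooled numeric time course (posterior pairs x pooled band average).
#' @slot pairs data.frame with columns left, right.
#' @slot pooledPairs indices (rows of `pairs`) entering the pooled curve.
#' @slot pooledBand frequency band (Hz, length 2) of the pooled curve.
#' @slot freqs,times axis annotations.
#'
#' @seealso [lateralizationIndex()]
#' @export
setClass("LateralizationResult",
  representation(
    index = "array",
    pooled = "numeric",
    pairs = "data.frame",
    pooledPairs = "integer",
    pooledBand = "numeric",
    freqs = "numeric",
    times = "numeric"
  )
)

setValidity("LateralizationResult", function(object) {
  msg <- character(0)
  idx <- object@index[is.finite(object@index)]
  if (length(idx) && (min(idx) < -1 - 1e-12 || max(idx) > 1 + 1e-12))
    msg <- c(msg, "index values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Time-resolved decoding result
#'
#' Accuracy of the trial-group-averaged linear SVM scheme per time point,
#' together with per-class confusion counts.
#'
#' @slot accuracy smoothed accuracy time course in [0, 1].
#' @slot accuracyRaw unsmoothed accuracy time course.
#' @slot times decode-time axis in ms.
#' @slot classLevels the two class labels.
#' @slot classCorrect matrix 2 x time: correct predictions per true class.
#' @slot classTotal predictions per true class per time point.
#' @slot nPredictions total predictions per time point (nIter * nGroups).
#' @slot groupSize trials averaged per group.
#' @slot nGroups,nIter cross-validation scheme parameters.
#' @slot featureKind "broadband_erp" or "alpha_power".
#' @slot seed RNG seed.
#'
#' @seealso [decodeTimecourse()], [confusionSummary()]
#' @export
setClass("DecodingResult",
  representation(
    accuracy = "numeric",
    accuracyRaw = "numeric",
    times = "numeric",
    classLevels = "character",
    classCorrect = "matrix",
    classTotal = "numeric",
    nPredictions = "numeric",
    groupSize = "numeric",
    nGroups = "numeric",
    nIter = "numeric",
    featureKind = "character",
    seed = "numeric"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character(0)
  if (length(object@accuracy) != length(object@times))
    msg <- c(msg, "accuracy and times must have equal length")
  acc <- object@accuracyRaw
  if (length(acc) && (min(acc) < 0 || max(acc) > 1))
    msg <- c(msg, "accuracy must lie in [0, 1]")
  if (ncol(object@classCorrect) != length(object@times))
    msg <- c(msg, "classCorrect must have one column per time point")
  tot <- colSums(object@classCorrect)
  exp_correct <- round(object@accuracyRaw * object@nPredictions)
  if (length(tot) && max(abs(tot - exp_correct)) > 1e-6)
    msg <- c(msg, "per-class correct counts must sum to total correct counts")
  if (length(msg)) msg else TRUE
})

#' Parametric follow-up inference result
#'
#' One-sample or paired t test on interval-averaged measures with Cohen's d,
#' adjusted partial eta squared, and the JZS Bayes factor (Cauchy prior on the
#' standardised effect size).
#'
#' @slot t t statistic.
#' @slot df degrees of freedom (n - 1).
#' @slot p two-sided p value.
#' @slot d Cohen's d (= t / sqrt(n)), carrying the sign of t.
#' @slot etaAdj adjusted partial eta squared.
#' @slot bf10 Bayes factor for H1 over H0; `bf01 = 1 / bf10`.
#' @slot bf01 reverse Bayes factor.
#' @slot priorScale Cauchy prior scale (default 0.707).
#' @slot n number of (paired) observations.
#' @slot estimate mean of the tested values (paired: mean difference).
#'
#' @seealso [inferenceTest()], [jzsBayesFactor()]
#' @export
setClass("InferenceResult",
  representation(
    t = "numeric",
    df = "numeric",
    p = "numeric",
    d = "numeric",
    etaAdj = "numeric",
    bf10 = "numeric",
    bf01 = "numeric",
    priorScale = "numeric",
    n = "numeric",
    estimate = "numeric"
  )
)

setValidity("InferenceResult", function(object) {
  msg <- character(0)
  if (is.finite(object@bf10) && is.finite(object@bf01) &&
      abs(object@bf10 * object@bf01 - 1) > 1e-8)
    msg <- c(msg, "bf10 * bf01 must equal 1")
  if (is.finite(object@t) && sign(object@d) != 0 &&
      sign(object@d) != sign(object@t))
    msg <- c(msg, "d must carry the sign of t")
  if (length(msg)) msg else TRUE
})
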