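# Time-resolved decoding of the classification type with the
# trial-group-averaged linear-SVM cross-validation scheme, for broadband ERP
# and alpha-band raw-power features.

#' Prepare decoding features
#'
#' Builds the trials x features x time feature tensor for time-resolved
#' decoding, downsampled to the decode rate by non-overlapping bin averaging.
#' Broadband ERP features are the voltages of all channels (one feature per
#' channel); alpha-power features are raw (not baseline-corrected) power
#' values at the alpha wavelet frequencies of all channels (channels x
#' frequencies features).
#'
#' @param x an [EpochSet-class] (`kind = "broadband_erp"`) or a trial-level
#'   raw-power [TFRSet-class] (`kind = "alpha_power"`).
#' @param kind feature kind.
#' @param alphaFreqs wavelet frequencies used for alpha-power features
#'   (default 8, 9, 10, 11, 12 Hz; must be present in the TFR).
#' @param decodeSfreq decode sampling rate in Hz (default 20); the input rate
#'   must be an integer multiple.
#' @param timeRange decoded interval in ms, default relevance-cue onset to
#'   1000 ms after working-memory target onset (`c(0, 11800)`).
#' @return list with `features` (array trials x features x time), `times`
#'   (ms), `kind`.
#' @export
prepareFeatures <- function(x, kind = c("broadband_erp", "alpha_power"),
                            alphaFreqs = 8:12, decodeSfreq = 20,
                            timeRange = c(0, 11800)) {
  kind <- match.arg(kind)
  if (kind == "broadband_erp") {
    stopifnot(is(x, "EpochSet"))
    times <- x@times
    dat <- x@data  # trials x channels x samples
  } else {
    stopifnot(is(x, "TFRSet"))
    if (x@isDb) stop("alpha-power decoding uses raw power, not decibels")
    fidx <- match(alphaFreqs, x@freqs)
    if (anyNA(fidx))
      stop("TFR does not contain the requested alpha frequencies: ",
           paste(alphaFreqs[is.na(fidx)], collapse = ", "))
    times <- x@times
    d <- dim(x@power)
    dat <- x@power[, , fidx, , drop = FALSE]
    dim(dat) <- c(d[1], d[2] * length(fidx), d[4])  # channels x freqs flat
  }
  step <- diff(times)[1]
  fac <- (1000 / decodeSfreq) / step
  if (abs(fac - round(fac)) > 1e-6 || fac < 1)
    stop("decodeSfreq must divide the input sampling rate")
  fac <- as.integer(round(fac))
  keep <- which(times >= timeRange[1] & times <= timeRange[2])
  if (length(keep) < fac)
    stop("input time axis does not cover the decode range")
  nb <- length(keep) %/% fac
  keep <- keep[seq_len(nb * fac)]
  binOf <- rep(seq_len(nb), each = fac)
  d <- dim(dat)
  out <- array(0, c(d[1], d[2], nb))
  flat <- matrix(dat[, , keep], d[1] * d[2], length(keep))
  binned <- t(rowsum(t(flat), binOf) / fac)
  out[] <- array(binned, c(d[1], d[2], nb))
  list(features = out,
       times = as.numeric(tapply(times[keep], binOf, mean)),
       kind = kind)
}

#' Trial-group-averaged SVM decoding over time
#'
#' At every time point, runs `nIter` repetitions of an `nGroups`-fold
#' cross-validation: trials of each class are randomly assigned to `nGroups`
#' equal-size groups (surplus trials randomly excluded), trials within a
#' group are averaged, a linear support vector machine (cost 1, no feature
#' scaling) is trained on the `2 * (nGroups - 1)` group averages of the
#' training folds, and the two held-out averages (one per class) are
#' classified. Accuracy per time point is the fraction of correct
#' predictions; the curve is finally smoothed with a centred moving average
#' (edge-truncated).
#'
#' Group assignment is re-randomized per iteration and kept constant across
#' time points; identical seeds give identical curves.
#'
#' @param feat feature list from [prepareFeatures()].
#' @param labels per-trial class labels (two levels, e.g. the classification
#'   type); each class needs at least `nGroups` trials.
#' @param nGroups number of groups/folds per class (default 15).
#' @param nIter number of cross-validation repetitions (default 10).
#' @param smoothPoints width of the moving-average window in decode samples
#'   (default 5, i.e. +/- 100 ms at 20 Hz).
#' @param average train and test on group averages (default). With
#'   `FALSE` the same group partition is used but the classifier is trained
#'   and tested on the individual trials, for comparing against single-trial
#'   decoding.
#' @param seed integer seed.
#' @return a [DecodingResult-class].
#' @export
decodeTimecourse <- function(feat, labels, nGroups = 15, nIter = 10,
                             smoothPoints = 5, average = TRUE, seed = 1) {
  stopifnot(is.list(feat), !is.null(feat$features))
  x <- feat$features
  d <- dim(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two classes")
  if (length(labels) != d[1])
    stop("labels must have one entry per trial")
  cls <- levels(labels)
  nPerClass <- table(labels)
  if (any(nPerClass < nGroups))
    stop("insufficient data: every class needs at least nGroups = ",
         nGroups, " trials")
  g <- floor(min(nPerClass) / nGroups)
  ntp <- d[3]

  res <- .withSeed(seed, {
    correct <- matrix(0, 2, ntp)  # per true class
    total <- matrix(0, 2, ntp)
    for (it in seq_len(nIter)) {
      groupIdx <- lapply(1:2, function(k) {
        ids <- sample(which(as.integer(labels) == k))  # shuffles + excludes
        matrix(ids[seq_len(g * nGroups)], nrow = g)    # columns = groups
      })
      # group averages: nGroups x 2 x features x time
      G <- array(0, c(nGroups, 2, d[2], ntp))
      for (k in 1:2) for (gr in seq_len(nGroups)) {
        rows <- groupIdx[[k]][, gr]
        if (g == 1L) {
          G[gr, k, , ] <- x[rows[1], , ]
        } else {
          sel <- x[rows, , , drop = FALSE]
          dim(sel) <- c(g, d[2] * ntp)
          G[gr, k, , ] <- colMeans(sel)
        }
      }
      yTrain <- rep(1:2, each = nGroups - 1L)
      for (tp in seq_len(ntp)) {
        for (gr in seq_len(nGroups)) {
          if (average) {
            Xtr <- rbind(G[-gr, 1, , tp], G[-gr, 2, , tp])
            Xte <- rbind(G[gr, 1, , tp], G[gr, 2, , tp])
            yTe <- 1:2
          } else {
            tri <- c(groupIdx[[1]][, -gr], groupIdx[[2]][, -gr])
            tei <- c(groupIdx[[1]][, gr], groupIdx[[2]][, gr])
            Xtr <- matrix(x[tri, , tp], length(tri), d[2])
            Xte <- matrix(x[tei, , tp], length(tei), d[2])
            yTrain <- rep(1:2, times = c(g * (nGroups - 1L),
                                         g * (nGroups - 1L)))
            yTe <- rep(1:2, each = g)
          }
          fit <- .svmLinearTrain(Xtr, yTrain)
          pred <- .svmPredict(fit, Xte)
          for (k in 1:2) {
            sel <- yTe == k
            correct[k, tp] <- correct[k, tp] + sum(pred[sel] == k)
            total[k, tp] <- total[k, tp] + sum(sel)
          }
        }
      }
    }
    list(correct = correct, total = total)
  })

  nPred <- sum(res$total[, 1])
  accRaw <- colSums(res$correct) / nPred
  acc <- .movingAverage(accRaw, smoothPoints)
  new("DecodingResult", accuracy = acc, accuracyRaw = accRaw,
      times = feat$times, classLevels = cls, classCorrect = res$correct,
      classTotal = res$total[, 1], nPredictions = nPred,
      groupSize = g, nGroups = nGroups, nIter = nIter,
      featureKind = feat$kind, seed = as.numeric(seed))
}

# centred moving average; the window shrinks at the curve ends
.movingAverage <- function(x, width) {
  if (width <= 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Per-class decoding accuracy over a time window
#'
#' Splits decoding accuracy by true class (the diagonal of the confusion
#' matrix), averaged over the decode time points inside `window`.
#'
#' @param result a [DecodingResult-class].
#' @param window time window in ms (length 2).
#' @return named numeric vector of per-class accuracies.
#' @export
confusionSummary <- function(result, window) {
  stopifnot(is(result, "DecodingResult"))
  idx <- which(result@times >= window[1] & result@times <= window[2])
  if (length(idx) == 0L)
    stop("no decode time points inside the window")
  acc <- rowSums(result@classCorrect[, idx, drop = FALSE]) /
    (result@classTotal * length(idx))
  names(acc) <- result@classLevels
  acc
}
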