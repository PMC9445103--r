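# Hemispheric alpha-power asymmetry relative to the retro-cue direction:
# balanced trial drawing, the lateralization index per mirror pair, and the
# posterior 8-15 Hz pooled time course.

#' Draw trials balanced over cue direction and response side
#'
#' Selects a trial subset in which every combination of retro-cue direction
#' (left/right) and number-classification response side (left/right) occurs
#' equally often. Each cell is randomly truncated to the size of the smallest
#' cell (the only count-preserving reading of "drawn ... equally often").
#'
#' @param metadata data.frame with columns `retrocue_side` and
#'   `response_side`.
#' @param seed integer seed; the draw is reproducible.
#' @return integer vector of selected row indices (sorted).
#' @export
#' @examples
#' md <- expand.grid(retrocue_side = c("left", "right"),
#'                   response_side = c("left", "right"),
#'                   rep = 1:5, stringsAsFactors = FALSE)
#' length(drawBalancedTrials(md, seed = 1))  # 20, all retained
drawBalancedTrials <- function(metadata, seed = 1) {
  stopifnot(all(c("retrocue_side", "response_side") %in% names(metadata)))
  cells <- split(seq_len(nrow(metadata)),
                 list(metadata$retrocue_side, metadata$response_side),
                 drop = FALSE)
  if (length(cells) != 4L || any(lengths(cells) == 0L))
    stop("every retro-cue side x response side cell must be non-empty")
  k <- min(lengths(cells))
  .withSeed(seed, {
    sort(unlist(lapply(cells, function(i) {
      if (length(i) == k) i else sample(i, k)
    }), use.names = FALSE))
  })
}

#' Lateralization index of oscillatory power
#'
#' For every mirror electrode pair, frequency and time point, averages raw
#' (linear) power across trials separately for the ipsilateral member (the
#' hemisphere on the same side as the retro-cued item) and the contralateral
#' member, and forms the normalised asymmetry
#' `index = (ipsi - contra) / (ipsi + contra)`, a dimensionless value in
#' \[-1, 1\]. Positive values indicate weaker alpha contralateral to the cued
#' item, i.e. attention oriented toward it. The pooled time course averages
#' the index over the posterior pairs and over wavelet frequencies in the
#' pooled band (default 8-15 Hz).
#'
#' @param tfr a raw-power, trial-level [TFRSet-class]. Decibel input is
#'   rejected: the index is defined on linear power.
#' @param metadata data.frame with one row per trial of `tfr`, containing
#'   `retrocue_side`; defaults to `trialInfo(tfr)`.
#' @param pairing data.frame of mirror pairs (columns `left`, `right`);
#'   default [mirrorPairs()] of the TFR's channels.
#' @param trials optional trial subset (e.g. from [drawBalancedTrials()]).
#' @param pooledPairs data.frame of pairs entering the pooled curve; default
#'   [posteriorPairs()].
#' @param pooledBand frequency band (Hz) pooled into the time course,
#'   default `c(8, 15)` (wavelet centres 8..15 Hz inclusive).
#' @return a [LateralizationResult-class].
#' @export
lateralizationIndex <- function(tfr, metadata = trialInfo(tfr),
                                pairing = mirrorPairs(channelNames(tfr)),
                                trials = NULL,
                                pooledPairs = posteriorPairs(),
                                pooledBand = c(8, 15)) {
  stopifnot(is(tfr, "TFRSet"))
  if (tfr@isDb)
    stop("lateralization requires raw (linear) power, not decibels")
  d <- dim(tfr@power)
  if (nrow(metadata) != d[1])
    stop("metadata must have one row per trial")
  if (!"retrocue_side" %in% names(metadata))
    stop("metadata must contain retrocue_side")
  if (anyDuplicated(c(pairing$left, pairing$right)))
    stop("a channel appears in more than one pair")
  li <- match(pairing$left, tfr@channels)
  ri <- match(pairing$right, tfr@channels)
  if (anyNA(li) || anyNA(ri))
    stop("unpaired channel(s): ",
         paste(c(pairing$left[is.na(li)], pairing$right[is.na(ri)]),
               collapse = ", "))

  idx <- if (is.null(trials)) seq_len(d[1]) else trials
  cueLeft <- metadata$retrocue_side[idx] == "left"
  npair <- nrow(pairing)

  # trial-mean power per pair member, split by cue side
  avgOver <- function(ch, rows) {
    if (length(rows) == 0L)
      return(array(0, c(length(ch), d[3], d[4])))
    apply(tfr@power[rows, ch, , , drop = FALSE], c(2, 3, 4), mean)
  }
  nl <- sum(cueLeft)
  nr <- sum(!cueLeft)
  if (nl == 0L || nr == 0L)
    stop("both retro-cue directions must be present in the trial set")
  Lcl <- avgOver(li, idx[cueLeft])    # left channels, cue left  -> ipsi
  Rcl <- avgOver(ri, idx[cueLeft])    # right channels, cue left -> contra
  Lcr <- avgOver(li, idx[!cueLeft])   # left channels, cue right -> contra
  Rcr <- avgOver(ri, idx[!cueLeft])   # right channels, cue right -> ipsi
  w <- c(nl, nr) / (nl + nr)
  ipsi <- w[1] * Lcl + w[2] * Rcr
  contra <- w[1] * Rcl + w[2] * Lcr
  index <- (ipsi - contra) / (ipsi + contra)
  index[!is.finite(index)] <- 0  # zero power on both members
  dim(index) <- c(npair, d[3], d[4])

  pp <- match(paste(pooledPairs$left, pooledPairs$right),
              paste(pairing$left, pairing$right))
  pp <- pp[!is.na(pp)]
  if (length(pp) == 0L)
    stop("none of the pooled pairs are present in the pairing")
  fidx <- which(tfr@freqs >= pooledBand[1] & tfr@freqs <= pooledBand[2])
  if (length(fidx) == 0L)
    stop("no wavelet frequencies inside the pooled band")
  pooled <- apply(index[pp, fidx, , drop = FALSE], 3, mean)

  new("LateralizationResult", index = index, pooled = pooled,
      pairs = pairing, pooledPairs = as.integer(pp),
      pooledBand = as.numeric(pooledBand), freqs = tfr@freqs,
      times = tfr@times)
}
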