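# Synthetic-data generator for the dual-task retro-cue paradigm: balanced
# trial schedules, behavioural outcomes, feedback scores, and epoched EEG
# with planted oscillatory effects.

#' Event onsets of the trial timeline
#'
#' Stimulus onsets in ms relative to relevance-cue onset: relevance cue at 0
#' (500 ms on screen), memory items at 3000 (400 ms), classification cue at
#' 5600 (200 ms), classification digit at 6800 (200 ms), retro-cue at 9600
#' (200 ms), and the working-memory target at 10800 ms.
#'
#' @return named numeric vector of onsets (ms).
#' @export
eventOnsets <- function() {
  c(relevance_cue = 0, memory_items = 3000, classification_cue = 5600,
    classification_digit = 6800, retrocue = 9600, wm_target = 10800)
}

#' Generate a balanced trial schedule
#'
#' Builds a randomized trial schedule for the dual-task paradigm. Within every
#' block each level of the three experimental factors -- important task
#' (number classification, NCT, vs working memory, WMT), retro-cue side, and
#' classification type -- appears equally often and all factor co-occurrences
#' are balanced; trial order within a block is randomized.
#'
#' With `trialsPerBlock` divisible by 8 every 2 x 2 x 2 factor cell is filled
#' equally within each block. With a remainder of 4 (as in the default
#' 60-trial blocks) the four surplus trials are assigned to the even- or
#' odd-parity cell class on alternating blocks, which keeps all single-factor
#' and pairwise co-occurrence counts exactly balanced within every block and
#' balances the full three-way cells across consecutive block pairs.
#'
#' @param nBlocks number of blocks (default 10).
#' @param trialsPerBlock trials per block; must be divisible by 4
#'   (2 tasks x 2 cue sides x 2 classification types with balanced pairwise
#'   co-occurrence). Default 60.
#' @param seed integer seed; the schedule is reproducible from it.
#' @return data.frame with columns `trial`, `block`, `important_task`
#'   (`"NCT"`/`"WMT"`), `retrocue_side` (`"left"`/`"right"`),
#'   `classification_type` (`"odd_even"`/`"smaller_bigger"`) and `digit`.
#'   Event onsets common to all trials are available via [eventOnsets()].
#' @export
#' @examples
#' sched <- makeSchedule(1, 8, seed = 1)
#' table(sched$important_task, sched$retrocue_side)
makeSchedule <- function(nBlocks = 10, trialsPerBlock = 60, seed = 1) {
  if (trialsPerBlock %% 4L != 0L)
    stop("trialsPerBlock must be divisible by 4 to balance the factor ",
         "levels and their co-occurrences")
  cells <- expand.grid(
    important_task = c("NCT", "WMT"),
    retrocue_side = c("left", "right"),
    classification_type = c("odd_even", "smaller_bigger"),
    stringsAsFactors = FALSE
  )
  parity <- (as.integer(cells$important_task == "WMT") +
               as.integer(cells$retrocue_side == "right") +
               as.integer(cells$classification_type == "smaller_bigger")) %% 2L
  base <- trialsPerBlock %/% 8L
  halfCell <- trialsPerBlock %% 8L == 4L
  .withSeed(seed, {
    blocks <- lapply(seq_len(nBlocks), function(b) {
      reps <- rep(base, 8L)
      if (halfCell) reps <- reps + (parity == (b %% 2L))
      blk <- cells[rep(seq_len(nrow(cells)), reps), ]
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      blk$block <- b
      blk
    })
    sched <- do.call(rbind, blocks)
    sched$trial <- seq_len(nrow(sched))
    sched$digit <- sample(c(1:4, 6:9), nrow(sched), replace = TRUE)
    rownames(sched) <- NULL
    sched[, c("trial", "block", "important_task", "retrocue_side",
              "classification_type", "digit")]
  })
}

#' Feedback points for the number classification task
#'
#' Scoring rule for a number-classification response: missing or incorrect
#' answers earn 0 points; response times between 200 and 400 ms earn the
#' maximum; beyond 400 ms points fall linearly to 0 at 1800 ms:
#' `FP = max - max / (1800 - 400) * (RT - 400)`.
#' The maximum is 75 points when the task is cued as important and 25
#' otherwise.
#'
#' @param rtMs response time in ms relative to digit onset, or `NA` for a
#'   missing response. Present values must lie in the registration window
#'   \[200, 1800\] ms.
#' @param correct logical: was the classification correct?
#' @param cued logical: was the task the important (cued) one?
#' @return feedback points (vectorised over the inputs).
#' @export
#' @examples
#' feedbackNct(300, TRUE, TRUE)     # 75
#' feedbackNct(1100, TRUE, FALSE)   # 12.5
feedbackNct <- function(rtMs, correct, cued) {
  ok <- is.na(rtMs) | (rtMs >= 200 & rtMs <= 1800)
  if (!all(ok))
    stop("rtMs outside the response registration window [200, 1800] ms")
  mx <- ifelse(cued, 75, 25)
  pts <- ifelse(rtMs <= 400, mx, mx - mx / (1800 - 400) * (rtMs - 400))
  ifelse(is.na(rtMs) | !correct, 0, pts)
}

#' Feedback points for the working memory task
#'
#' Scoring rule for the orientation reproduction: missing answers and angular
#' deviations above 45 degrees earn 0 points; otherwise
#' `FP = max - max / 45 * deviation`. The maximum is 75 points when the task
#' is cued as important and 25 otherwise.
#'
#' @param deviationDeg absolute angular deviation in degrees (>= 0), or `NA`
#'   for a missing response.
#' @param cued logical: was the task the important (cued) one?
#' @return feedback points (vectorised over the inputs).
#' @export
#' @examples
#' feedbackWmt(0, TRUE)      # 75
#' feedbackWmt(22.5, TRUE)   # 37.5
#' feedbackWmt(45, TRUE)     # 0
feedbackWmt <- function(deviationDeg, cued) {
  if (any(deviationDeg < 0, na.rm = TRUE))
    stop("deviationDeg must be non-negative")
  mx <- ifelse(cued, 75, 25)
  ifelse(is.na(deviationDeg) | deviationDeg > 45, 0,
         mx - mx / 45 * deviationDeg)
}

#' Default behavioural simulation parameters
#'
#' Per-condition means and standard deviations for response times and angular
#' deviations. "important"/"unimportant" refer to whether the respective task
#' was the cued one on that trial. Response times are drawn log-normally and
#' truncated to the registration windows; deviations are drawn from a normal
#' distribution truncated to \[0, 180\] degrees.
#'
#' @param rtNct,rtNctSd NCT response-time mean/SD (ms) per condition.
#' @param errNct NCT error rate per condition.
#' @param rtWmt,rtWmtSd WMT response-time mean/SD (ms) per condition.
#' @param devWmt,devWmtSd WMT angular deviation mean/SD (deg) per condition.
#' @param pMiss probability of a missing response in either task.
#' @return a named list of parameters for [simulateBehavior()].
#' @export
behaviorParams <- function(
    rtNct = c(important = 537.00, unimportant = 562.86),
    rtNctSd = c(important = 114.13, unimportant = 119.61),
    errNct = c(important = 0.0856, unimportant = 0.0866),
    rtWmt = c(important = 1368.91, unimportant = 1292.68),
    rtWmtSd = c(important = 300.92, unimportant = 267.38),
    devWmt = c(important = 11.77, unimportant = 13.48),
    devWmtSd = c(important = 4.07, unimportant = 5.23),
    pMiss = 0.01) {
  list(rtNct = rtNct, rtNctSd = rtNctSd, errNct = errNct,
       rtWmt = rtWmt, rtWmtSd = rtWmtSd, devWmt = devWmt,
       devWmtSd = devWmtSd, pMiss = pMiss)
}

# truncated log-normal with target (untruncated) mean m and sd s
.rlnormTrunc <- function(n, m, s, lower, upper) {
  if (s == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  lo <- stats::plnorm(lower, meanlog, sdlog)
  hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

# truncated normal on [lower, upper]
.rnormTrunc <- function(n, m, s, lower, upper) {
  if (s == 0) return(rep(m, n))
  lo <- stats::pnorm(lower, m, s)
  hi <- stats::pnorm(upper, m, s)
  stats::qnorm(stats::runif(n, lo, hi), m, s)
}

#' Simulate behavioural outcomes for a trial schedule
#'
#' Draws response times, accuracies, response sides and angular deviations
#' per trial, with condition-dependent means: responses in a task are faster
#' (NCT) or more precise (WMT) when that task is cued as important.
#'
#' @param schedule data.frame from [makeSchedule()].
#' @param params parameter list from [behaviorParams()].
#' @param seed integer seed.
#' @return data.frame with columns `rt_nct_ms`, `correct_nct`,
#'   `response_side`, `rt_wmt_ms`, `deviation_deg` (missing responses are
#'   `NA`).
#' @export
simulateBehavior <- function(schedule, params = behaviorParams(), seed = 1) {
  stopifnot(is.data.frame(schedule), "important_task" %in% names(schedule))
  n <- nrow(schedule)
  nctImp <- schedule$important_task == "NCT"
  cond <- ifelse(nctImp, "important", "unimportant")
  condW <- ifelse(nctImp, "unimportant", "important")
  .withSeed(seed, {
    rtN <- numeric(n)
    rtW <- numeric(n)
    dev <- numeric(n)
    for (lv in c("important", "unimportant")) {
      i <- cond == lv
      rtN[i] <- .rlnormTrunc(sum(i), params$rtNct[[lv]],
                             params$rtNctSd[[lv]], 200, 1800)
      j <- condW == lv
      rtW[j] <- .rlnormTrunc(sum(j), params$rtWmt[[lv]],
                             params$rtWmtSd[[lv]], 200, 4500)
      dev[j] <- .rnormTrunc(sum(j), params$devWmt[[lv]],
                            params$devWmtSd[[lv]], 0, 180)
    }
    correct <- stats::runif(n) >= params$errNct[cond]
    missN <- stats::runif(n) < params$pMiss
    missW <- stats::runif(n) < params$pMiss
    rtN[missN] <- NA_real_
    correct[missN] <- FALSE
    rtW[missW] <- NA_real_
    dev[missW] <- NA_real_
    data.frame(
      rt_nct_ms = rtN,
      correct_nct = correct,
      response_side = sample(c("left", "right"), n, replace = TRUE),
      rt_wmt_ms = rtW,
      deviation_deg = dev,
      stringsAsFactors = FALSE
    )
  })
}

#' Feedback scores for simulated trials
#'
#' Applies the two scoring rules to a schedule and its behavioural outcomes.
#' The cued (important) task is scored out of 75 points and the other out of
#' 25, so the total lies in \[0, 100\].
#'
#' @param schedule data.frame from [makeSchedule()].
#' @param behavior data.frame from [simulateBehavior()].
#' @return data.frame with columns `fp_nct`, `fp_wmt`, `total`.
#' @export
feedbackScores <- function(schedule, behavior) {
  nctCued <- schedule$important_task == "NCT"
  fpN <- feedbackNct(behavior$rt_nct_ms, behavior$correct_nct, nctCued)
  fpW <- feedbackWmt(behavior$deviation_deg, !nctCued)
  data.frame(fp_nct = fpN, fp_wmt = fpW, total = fpN + fpW)
}

#' Planted-effect specification for the EEG simulator
#'
#' Describes the additive structure of the synthetic EEG: the background noise
#' model (1/f "pink" noise plus white sensor noise), condition-contrasting
#' band-limited oscillatory bursts, a retro-cue-locked lateralized posterior
#' alpha component of a target asymmetry magnitude, and class-specific scalp
#' patterns during the classification-task window that make the
#' classification type decodable.
#'
#' The defaults plant the phenomena the analyses are designed to detect:
#' a theta burst stronger in NCT-important trials during the relevance-cue
#' interval and during task preparation, an alpha increase in WMT-important
#' trials during classification-task performance, a posterior alpha asymmetry
#' of index magnitude 0.05 between retro-cue and memory-target onset, and
#' classification-type-specific topographies (deterministic slow waveform for
#' ERP decoding plus random-phase alpha amplitude patterns for power
#' decoding). Setting all amplitudes to 0 yields pure-noise null data.
#'
#' @param noise list: `pinkSd` (uV), `whiteSd` (uV), `exponent` (power-law
#'   exponent of the background spectrum).
#' @param bandEffects list of band effects, each a list with `freq` (Hz),
#'   `window` (ms, length 2), `channels` (`"all"` or labels), `condition`
#'   (`"NCT"`, `"WMT"` or `"all"`), `amplitude` (uV peak).
#' @param lateralization list with `band` (Hz), `window` (ms), `index`
#'   (target lateralization magnitude), `amplitude` (uV RMS of the planted
#'   burst), `pairs` (data.frame left/right); or `list()` for none.
#' @param decoding list with `window` (ms), `erpAmplitude`, `erpFreq`,
#'   `alphaAmplitude`, `alphaFreq`; or `list()` for none.
#' @return a validated effect-specification list (class `"effectSpec"`).
#' @seealso [simulateEpochs()]
#' @export
effectSpec <- function(
    noise = list(pinkSd = 10, whiteSd = 2, exponent = 1),
    bandEffects = list(
      list(freq = 5, window = c(0, 900), channels = "all",
           condition = "NCT", amplitude = 1.2),
      list(freq = 5, window = c(3000, 5600), channels = "all",
           condition = "NCT", amplitude = 1.2),
      list(freq = 10, window = c(5665, 7830), channels = "all",
           condition = "WMT", amplitude = 1.2)
    ),
    lateralization = list(band = c(8, 15), window = c(9600, 10800),
                          index = 0.05, amplitude = 12,
                          pairs = posteriorPairs()),
    decoding = list(window = c(5600, 8000), erpAmplitude = 1, erpFreq = 2,
                    alphaAmplitude = 4, alphaFreq = 10)) {
  amps <- c(noise$pinkSd, noise$whiteSd,
            vapply(bandEffects, function(e) e$amplitude, numeric(1)),
            if (length(lateralization)) lateralization$amplitude,
            if (length(decoding)) c(decoding$erpAmplitude,
                                    decoding$alphaAmplitude))
  if (any(amps < 0)) stop("effect amplitudes must be non-negative")
  if (length(lateralization) &&
      (lateralization$index < -1 || lateralization$index > 1))
    stop("lateralization index magnitude must lie in [-1, 1]")
  structure(list(noise = noise, bandEffects = bandEffects,
                 lateralization = lateralization, decoding = decoding),
            class = "effectSpec")
}

#' Null (pure-noise) effect specification
#'
#' Convenience wrapper: background noise only, no planted effects.
#'
#' @inheritParams effectSpec
#' @return an `"effectSpec"` list with no planted effects.
#' @export
nullEffectSpec <- function(noise = list(pinkSd = 10, whiteSd = 2,
                                        exponent = 1)) {
  effectSpec(noise = noise, bandEffects = list(), lateralization = list(),
             decoding = list())
}

#' Simulate epoched EEG with planted effects
#'
#' Generates an [EpochSet-class] for a trial schedule: per-channel 1/f
#' background noise plus white sensor noise, with the additive planted
#' components described by an [effectSpec()]. Epochs span -3700 to +13700 ms
#' around the relevance cue at 200 Hz, leaving 700 ms on each side to be
#' trimmed after wavelet convolution. Identical `schedule`, `spec` and `seed`
#' give bit-identical output.
#'
#' @param schedule data.frame from [makeSchedule()].
#' @param spec an [effectSpec()].
#' @param behavior optional data.frame from [simulateBehavior()]; if supplied
#'   its columns are carried into the trial metadata.
#' @param channels channel labels (default: the shipped 64-channel montage).
#' @param sfreq sampling frequency in Hz (default 200).
#' @param tmin,tmax epoch span in ms relative to relevance-cue onset.
#' @param seed integer seed; fully determines the output.
#' @return an [EpochSet-class].
#' @export
#' @examples
#' sched <- makeSchedule(1, 8, seed = 1)
#' ep <- simulateEpochs(sched, nullEffectSpec(),
#'                      channels = c("C3", "C4", "Cz"), seed = 1)
#' ep
simulateEpochs <- function(schedule, spec = effectSpec(), behavior = NULL,
                           channels = readMontage()$channel, sfreq = 200,
                           tmin = -3700, tmax = 13700, seed = 1) {
  stopifnot(inherits(spec, "effectSpec"))
  times <- seq(tmin, tmax, by = 1000 / sfreq)
  n <- length(times)
  ntr <- nrow(schedule)
  nch <- length(channels)

  chanIdx <- function(sel, what) {
    if (identical(sel, "all")) return(seq_len(nch))
    idx <- match(sel, channels)
    if (anyNA(idx))
      stop("unknown channel label(s) in ", what, ": ",
           paste(sel[is.na(idx)], collapse = ", "))
    idx
  }
  for (e in spec$bandEffects)
    .assertWindow(e$window, times, "band-effect window")
  if (length(spec$lateralization))
    .assertWindow(spec$lateralization$window, times, "lateralization window")
  if (length(spec$decoding))
    .assertWindow(spec$decoding$window, times, "decoding window")

  arr <- .withSeed(seed, {
    arr <- array(0, c(ntr, nch, n))

    # class-specific unit-norm topographies, drawn once per run
    if (length(spec$decoding)) {
      pat <- replicate(2, {
        v <- stats::rnorm(nch)
        v / sqrt(sum(v^2))
      })
    }

    # background: 1/f amplitude-shaped noise + white sensor noise
    fmag <- c(0, seq_len(n - 1)) / n * sfreq
    fmag <- pmin(fmag, sfreq - fmag)
    amp <- c(0, fmag[-1]^(-spec$noise$exponent / 2))
    for (tr in seq_len(ntr)) {
      w <- matrix(stats::rnorm(n * nch), n, nch)
      if (spec$noise$pinkSd > 0) {
        pink <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
        sds <- sqrt(colMeans(pink^2) - colMeans(pink)^2)
        pink <- sweep(pink, 2, sds / spec$noise$pinkSd, "/")
        arr[tr, , ] <- t(pink)
      }
      if (spec$noise$whiteSd > 0)
        arr[tr, , ] <- arr[tr, , ] +
          t(matrix(stats::rnorm(n * nch, sd = spec$noise$whiteSd), n, nch))
    }

    # condition-contrasting oscillatory bursts
    for (e in spec$bandEffects) {
      if (e$amplitude == 0) next
      ci <- chanIdx(e$channels, "band effect")
      env <- .hannWindow(times, e$window)
      trials <- if (identical(e$condition, "all")) seq_len(ntr)
                else which(schedule$important_task == e$condition)
      for (tr in trials) {
        ph <- stats::runif(1, 0, 2 * pi)
        sig <- e$amplitude * env * cos(2 * pi * e$freq * times / 1000 + ph)
        arr[tr, ci, ] <- arr[tr, ci, ] + rep(sig, each = length(ci))
      }
    }

    # lateralized posterior band-limited burst, hemisphere follows the cue;
    # pairs whose members are not simulated are skipped so channel subsets
    # of the montage keep working with the default (full posterior) pairing
    lat <- spec$lateralization
    if (length(lat) && lat$amplitude > 0) {
      present <- lat$pairs$left %in% channels & lat$pairs$right %in% channels
      if (!any(present))
        stop("no lateralization pair is fully contained in the simulated ",
             "channels")
      lat$pairs <- lat$pairs[present, , drop = FALSE]
      li <- chanIdx(lat$pairs$left, "lateralization pairs")
      ri <- chanIdx(lat$pairs$right, "lateralization pairs")
      inw <- which(times >= lat$window[1] & times <= lat$window[2])
      env <- .hannWindow(times[inw], lat$window)
      gain <- sqrt(c(1 + lat$index, 1 - lat$index))
      for (tr in seq_len(ntr)) {
        cueLeft <- schedule$retrocue_side[tr] == "left"
        for (p in seq_along(li)) {
          for (sideIdx in 1:2) {  # 1 = left member, 2 = right member
            b <- .fftBandpass(stats::rnorm(length(inw)), sfreq, lat$band)
            b <- b / stats::sd(b)
            ipsi <- (sideIdx == 1) == cueLeft
            g <- lat$amplitude * if (ipsi) gain[1] else gain[2]
            ch <- if (sideIdx == 1) li[p] else ri[p]
            arr[tr, ch, inw] <- arr[tr, ch, inw] + g * env * b
          }
        }
      }
    }

    # classification-type-specific patterns in the task window
    dec <- spec$decoding
    if (length(dec) && (dec$erpAmplitude > 0 || dec$alphaAmplitude > 0)) {
      env <- .hannWindow(times, dec$window)
      erpWave <- env * cos(2 * pi * dec$erpFreq * (times - dec$window[1]) /
                             1000)
      cls <- ifelse(schedule$classification_type == "odd_even", 1L, 2L)
      for (tr in seq_len(ntr)) {
        p <- pat[, cls[tr]]
        if (dec$erpAmplitude > 0)
          arr[tr, , ] <- arr[tr, , ] +
            dec$erpAmplitude * outer(p, erpWave)
        if (dec$alphaAmplitude > 0) {
          ph <- stats::runif(1, 0, 2 * pi)
          aw <- env * cos(2 * pi * dec$alphaFreq * times / 1000 + ph)
          arr[tr, , ] <- arr[tr, , ] + dec$alphaAmplitude * outer(p, aw)
        }
      }
    }
    arr
  })

  info <- schedule
  if (!is.null(behavior)) {
    stopifnot(nrow(behavior) == ntr)
    info <- cbind(schedule, behavior)
  }
  new("EpochSet", data = arr, sfreq = sfreq, times = times,
      channels = channels, trialInfo = info)
}
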