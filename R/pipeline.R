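# Configuration handling and the end-to-end runner that reproduces the full
# analysis graph on synthetic data: simulation -> behaviour -> TFR cluster
# test -> decoding -> lateralization -> interval Bayes statistics.

.defaultConfig <- function() {
  list(
    nSubjects = 28,
    nBlocks = 10,
    trialsPerBlock = 60,
    channels = NULL,  # NULL = full shipped montage
    sfreq = 200,
    effects = effectSpec(),
    behavior = behaviorParams(),
    tfr = list(freqs = seq(2, 20, length.out = 19), fwhmHz = c(0.75, 4.25),
               trimMs = 700, decimate = 10L,
               baselineWindow = c(-700, -200)),
    cluster = list(nPerm = 1000, clusterAlpha = 0.05, alpha = 0.05,
                   adjacencyThreshold = 0.55),
    lateralization = list(band = c(8, 15)),
    decoding = list(features = c("broadband_erp", "alpha_power"),
                    alphaFreqs = 8:12, nGroups = 15, nIter = 10,
                    decodeSfreq = 20, timeRange = c(0, 11800),
                    smoothPoints = 5),
    inference = list(priorScale = sqrt(2) / 2),
    allowFreqOverride = FALSE,
    seed = 1
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills documented defaults for every missing entry (the defaults encode the
#' study design: 19 wavelets over 2-20 Hz, 15 groups x 10 iterations, prior
#' scale 0.707, the trial timeline windows) and rejects inconsistent
#' settings, reporting all violations at once.
#'
#' @param config named list of overrides (possibly nested); an empty list
#'   yields the fully defaulted configuration. May also be a YAML file path.
#' @return the normalised configuration list.
#' @export
#' @examples
#' cfg <- validateConfig(list(nSubjects = 4))
#' cfg$decoding$nGroups
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- .defaultConfig()
  merge2 <- function(d, o) {
    for (nm in names(o)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(o[[nm]]) &&
                     !inherits(o[[nm]], "effectSpec"))
        merge2(d[[nm]], o[[nm]]) else o[[nm]]
    }
    d
  }
  cfg <- merge2(def, config)

  errs <- character(0)
  addErr <- function(msg) errs <<- c(errs, msg)
  if (cfg$trialsPerBlock %% 4 != 0)
    addErr("trialsPerBlock must be divisible by 4")
  if (cfg$nSubjects < 1) addErr("nSubjects must be positive")
  checkWin <- function(w, nm) {
    if (length(w) != 2 || w[2] < w[1])
      addErr(paste0(nm, ": window end must not precede its start"))
  }
  checkWin(cfg$tfr$baselineWindow, "tfr$baselineWindow")
  checkWin(cfg$decoding$timeRange, "decoding$timeRange")
  checkWin(cfg$lateralization$band, "lateralization$band")
  fr <- range(cfg$tfr$freqs)
  if (!cfg$allowFreqOverride && (fr[1] < 2 || fr[2] > 20))
    addErr("tfr$freqs outside 2-20 Hz (set allowFreqOverride = TRUE)")
  if (cfg$lateralization$band[1] < fr[1] ||
      cfg$lateralization$band[2] > fr[2])
    addErr("lateralization$band outside the wavelet frequency range")
  if (!all(cfg$decoding$alphaFreqs %in% cfg$tfr$freqs))
    addErr("decoding$alphaFreqs must be wavelet centre frequencies")
  if (cfg$decoding$nGroups < 3) addErr("decoding$nGroups must be >= 3")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

.logStage <- function(verbose, ...) {
  if (verbose) message("[prioEEG] ", ...)
}

.summarizeInference <- function(x) {
  list(t = x@t, df = x@df, p = x@p, d = x@d, etaAdj = x@etaAdj,
       bf10 = x@bf10, bf01 = x@bf01, estimate = x@estimate)
}

.summarizeCluster <- function(x) {
  cl <- clusterTable(x)
  list(nClusters = nrow(cl), nSignificant = sum(cl$p < x@alpha),
       clusters = cl)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates `nSubjects` subjects under the configured effect specification
#' and runs the complete analysis graph: behavioural condition contrasts;
#' the 3-D electrode x frequency x time cluster-based permutation test on
#' decibel-normalised condition-mean power; per-condition time-resolved
#' decoding of the classification type with 1-D cluster tests against chance
#' and a paired condition comparison with Bayes factors; and the pooled
#' posterior alpha lateralization index with 1-D cluster tests against zero
#' and the analogous condition comparison. Every stage derives its seed
#' deterministically from the global seed and the stage name, so a rerun
#' with the same configuration reproduces the report exactly.
#'
#' @param config configuration list (see [validateConfig()], which is
#'   applied internally).
#' @param outDir optional directory: writes `results.json` and a
#'   human-readable `summary.txt`.
#' @param verbose log stage progress via `message()`.
#' @return a named list (the report): configuration echo, behavioural,
#'   cluster, decoding, lateralization and inference summaries.
#' @export
runPipeline <- function(config = list(), outDir = NULL, verbose = FALSE) {
  cfg <- validateConfig(config)
  seed <- cfg$seed
  montage <- readMontage()
  channels <- if (is.null(cfg$channels)) montage$channel else cfg$channels
  montage <- montage[match(channels, montage$channel), , drop = FALSE]
  if (anyNA(montage$x)) stop("unknown channel(s) in config$channels")
  graph <- buildAdjacency(montage, cfg$cluster$adjacencyThreshold)
  bank <- buildWavelets(cfg$sfreq, cfg$tfr$freqs, cfg$tfr$fwhmHz)
  pairing <- mirrorPairs(channels)
  posterior <- posteriorPairs()
  posterior <- posterior[posterior$left %in% channels &
                           posterior$right %in% channels, , drop = FALSE]
  conds <- c("NCT", "WMT")
  ns <- cfg$nSubjects

  behav <- list(rtNct = matrix(NA_real_, ns, 2, dimnames = list(NULL, conds)),
                devWmt = matrix(NA_real_, ns, 2, dimnames = list(NULL, conds)))
  dbMeans <- list(NCT = NULL, WMT = NULL)
  latCurves <- list(NCT = NULL, WMT = NULL)
  decCurves <- list()
  decTimes <- NULL
  latTimes <- NULL
  tfTimes <- NULL

  for (s in seq_len(ns)) {
    .logStage(verbose, "subject ", s, "/", ns, ": simulate")
    sSeed <- .stageSeed(seed, paste0("subject", s))
    sched <- makeSchedule(cfg$nBlocks, cfg$trialsPerBlock,
                          seed = .stageSeed(sSeed, "schedule"))
    beh <- simulateBehavior(sched, cfg$behavior,
                            seed = .stageSeed(sSeed, "behavior"))
    epochs <- simulateEpochs(sched, cfg$effects, behavior = beh,
                             channels = channels, sfreq = cfg$sfreq,
                             seed = .stageSeed(sSeed, "epochs"))
    md <- trialInfo(epochs)
    isN <- md$important_task == "NCT"

    behav$rtNct[s, "NCT"] <- mean(md$rt_nct_ms[isN], na.rm = TRUE)
    behav$rtNct[s, "WMT"] <- mean(md$rt_nct_ms[!isN], na.rm = TRUE)
    behav$devWmt[s, "NCT"] <- mean(md$deviation_deg[isN], na.rm = TRUE)
    behav$devWmt[s, "WMT"] <- mean(md$deviation_deg[!isN], na.rm = TRUE)

    .logStage(verbose, "subject ", s, ": time-frequency decomposition")
    tfr <- tfrDecompose(epochs, bank, trimMs = cfg$tfr$trimMs,
                        decimate = cfg$tfr$decimate)
    tfTimes <- sampleTimes(tfr)
    for (cond in conds) {
      avg <- tfrAverage(tfr, trials = md$important_task == cond)
      db <- dbBaseline(avg, baselineFrom = tfr,
                       window = cfg$tfr$baselineWindow)
      if (is.null(dbMeans[[cond]]))
        dbMeans[[cond]] <- array(NA_real_, c(ns, dim(tfrPower(db))[-1]))
      dbMeans[[cond]][s, , , ] <- tfrPower(db)[1, , , ]
    }

    .logStage(verbose, "subject ", s, ": lateralization")
    for (cond in conds) {
      condIdx <- which(md$important_task == cond)
      bal <- drawBalancedTrials(md[condIdx, , drop = FALSE],
                                seed = .stageSeed(sSeed, paste0("bal", cond)))
      lat <- lateralizationIndex(tfr, metadata = md,
                                 pairing = pairing,
                                 trials = condIdx[bal],
                                 pooledPairs = posterior,
                                 pooledBand = cfg$lateralization$band)
      if (is.null(latCurves[[cond]]))
        latCurves[[cond]] <- matrix(NA_real_, ns, length(pooledIndex(lat)))
      latCurves[[cond]][s, ] <- pooledIndex(lat)
      latTimes <- sampleTimes(lat)
    }

    .logStage(verbose, "subject ", s, ": decoding")
    for (kind in cfg$decoding$features) {
      featSrc <- if (kind == "broadband_erp") epochs else tfr
      feat <- prepareFeatures(featSrc, kind = kind,
                              alphaFreqs = cfg$decoding$alphaFreqs,
                              decodeSfreq = cfg$decoding$decodeSfreq,
                              timeRange = cfg$decoding$timeRange)
      decTimes <- feat$times
      for (cond in conds) {
        sel <- md$important_task == cond
        sub <- feat
        sub$features <- feat$features[sel, , , drop = FALSE]
        res <- decodeTimecourse(sub, md$classification_type[sel],
                                nGroups = cfg$decoding$nGroups,
                                nIter = cfg$decoding$nIter,
                                smoothPoints = cfg$decoding$smoothPoints,
                                seed = .stageSeed(sSeed,
                                                  paste0("dec", kind, cond)))
        key <- paste(kind, cond, sep = ".")
        if (is.null(decCurves[[key]]))
          decCurves[[key]] <- matrix(NA_real_, ns, length(res@accuracy))
        decCurves[[key]][s, ] <- accuracyCurve(res)
      }
    }
  }

  report <- list(config = list(nSubjects = ns, nBlocks = cfg$nBlocks,
                               trialsPerBlock = cfg$trialsPerBlock,
                               nChannels = length(channels), seed = seed))

  .logStage(verbose, "group statistics: behaviour")
  report$behavior <- list(
    rtNct = .summarizeInference(
      inferenceTest(behav$rtNct[, "WMT"], behav$rtNct[, "NCT"],
                    priorScale = cfg$inference$priorScale)),
    devWmt = .summarizeInference(
      inferenceTest(behav$devWmt[, "NCT"], behav$devWmt[, "WMT"],
                    priorScale = cfg$inference$priorScale))
  )

  .logStage(verbose, "group statistics: 3-D cluster test")
  tfrTest <- clusterTest3d(dbMeans$NCT, dbMeans$WMT, graph,
                           freqs = bank@freqs, times = tfTimes,
                           nPerm = cfg$cluster$nPerm,
                           clusterAlpha = cfg$cluster$clusterAlpha,
                           alpha = cfg$cluster$alpha,
                           seed = .stageSeed(seed, "cluster3d"))
  report$tfrClusterTest <- .summarizeCluster(tfrTest)

  .logStage(verbose, "group statistics: decoding")
  report$decoding <- list()
  for (kind in cfg$decoding$features) {
    res <- list()
    sigAny <- rep(FALSE, length(decTimes))
    for (cond in conds) {
      curves <- decCurves[[paste(kind, cond, sep = ".")]]
      ct <- clusterTest1d(curves, reference = 0.5, times = decTimes,
                          nPerm = cfg$cluster$nPerm,
                          clusterAlpha = cfg$cluster$clusterAlpha,
                          alpha = cfg$cluster$alpha,
                          seed = .stageSeed(seed, paste0("dec1d", kind, cond)))
      res[[cond]] <- .summarizeCluster(ct)
      res[[cond]]$meanAccuracy <- mean(curves)
      sigAny <- sigAny | significanceMask(ct)[1, 1, ]
    }
    pairComp <- clusterTest1d(decCurves[[paste(kind, "NCT", sep = ".")]],
                              partner = decCurves[[paste(kind, "WMT",
                                                         sep = ".")]],
                              times = decTimes,
                              nPerm = cfg$cluster$nPerm,
                              clusterAlpha = cfg$cluster$clusterAlpha,
                              alpha = cfg$cluster$alpha,
                              seed = .stageSeed(seed, paste0("decpair", kind)))
    res$conditionComparison <- .summarizeCluster(pairComp)
    if (any(sigAny)) {
      win <- range(decTimes[sigAny])
      a <- intervalAverage(decCurves[[paste(kind, "NCT", sep = ".")]],
                           decTimes, win)
      b <- intervalAverage(decCurves[[paste(kind, "WMT", sep = ".")]],
                           decTimes, win)
      res$intervalWindow <- win
      res$intervalVsChance <- lapply(
        list(NCT = a, WMT = b),
        function(v) .summarizeInference(
          inferenceTest(v, mu = 0.5, priorScale = cfg$inference$priorScale)))
      res$intervalConditionTest <- .summarizeInference(
        inferenceTest(a, b, priorScale = cfg$inference$priorScale))
    }
    report$decoding[[kind]] <- res
  }

  .logStage(verbose, "group statistics: lateralization")
  latRes <- list()
  sigAny <- rep(FALSE, length(latTimes))
  for (cond in conds) {
    ct <- clusterTest1d(latCurves[[cond]], reference = 0, times = latTimes,
                        nPerm = cfg$cluster$nPerm,
                        clusterAlpha = cfg$cluster$clusterAlpha,
                        alpha = cfg$cluster$alpha,
                        seed = .stageSeed(seed, paste0("lat1d", cond)))
    latRes[[cond]] <- .summarizeCluster(ct)
    latRes[[cond]]$meanIndex <- mean(latCurves[[cond]])
    sigAny <- sigAny | significanceMask(ct)[1, 1, ]
  }
  pairComp <- clusterTest1d(latCurves$NCT, partner = latCurves$WMT,
                            times = latTimes,
                            nPerm = cfg$cluster$nPerm,
                            clusterAlpha = cfg$cluster$clusterAlpha,
                            alpha = cfg$cluster$alpha,
                            seed = .stageSeed(seed, "latpair"))
  latRes$conditionComparison <- .summarizeCluster(pairComp)
  if (any(sigAny)) {
    win <- range(latTimes[sigAny])
    a <- intervalAverage(latCurves$NCT, latTimes, win)
    b <- intervalAverage(latCurves$WMT, latTimes, win)
    latRes$intervalWindow <- win
    latRes$intervalVsZero <- lapply(
      list(NCT = a, WMT = b),
      function(v) .summarizeInference(
        inferenceTest(v, mu = 0, priorScale = cfg$inference$priorScale)))
    latRes$intervalConditionTest <- .summarizeInference(
      inferenceTest(a, b, priorScale = cfg$inference$priorScale))
  }
  report$lateralization <- latRes

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    writeLines(.reportSummary(report), file.path(outDir, "summary.txt"))
  }
  report
}

.reportSummary <- function(report) {
  fmtI <- function(x)
    sprintf("t(%g) = %.2f, p = %.3g, d = %.2f, eta = %.2f, BF10 = %.4g",
            x$df, x$t, x$p, x$d, x$etaAdj, x$bf10)
  out <- c(
    sprintf("prioEEG pipeline report (%d subjects, seed %d)",
            report$config$nSubjects, report$config$seed),
    "",
    "Behaviour:",
    paste0("  NCT response time (WMT imp. - NCT imp.): ",
           fmtI(report$behavior$rtNct)),
    paste0("  WMT deviation (NCT imp. - WMT imp.):     ",
           fmtI(report$behavior$devWmt)),
    "",
    sprintf("3-D power cluster test: %d cluster(s), %d significant",
            report$tfrClusterTest$nClusters,
            report$tfrClusterTest$nSignificant))
  for (kind in names(report$decoding)) {
    r <- report$decoding[[kind]]
    out <- c(out, "", paste0("Decoding (", kind, "):"))
    for (cond in c("NCT", "WMT"))
      out <- c(out, sprintf(
        "  %s important: mean accuracy %.3f, %d significant cluster(s)",
        cond, r[[cond]]$meanAccuracy, r[[cond]]$nSignificant))
    if (!is.null(r$intervalConditionTest))
      out <- c(out, paste0("  condition comparison (interval): ",
                           fmtI(r$intervalConditionTest)))
  }
  r <- report$lateralization
  out <- c(out, "", "Lateralization:")
  for (cond in c("NCT", "WMT"))
    out <- c(out, sprintf(
      "  %s important: mean pooled index %.4f, %d significant cluster(s)",
      cond, r[[cond]]$meanIndex, r[[cond]]$nSignificant))
  if (!is.null(r$intervalConditionTest))
    out <- c(out, paste0("  condition comparison (interval): ",
                         fmtI(r$intervalConditionTest)))
  out
}
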