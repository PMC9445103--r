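# Accessor generics for the package's containers. Slot access from user code
# should go through these.

#' @rdname EpochSet-class
#' @param object an object of the documented class.
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))

#' @rdname EpochSet-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EpochSet-class
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname EpochSet-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname EpochSet-class
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))

#' @rdname TFRSet-class
#' @param object an object of the documented class.
#' @export
setGeneric("tfrPower", function(object) standardGeneric("tfrPower"))

#' @rdname TFRSet-class
#' @export
setGeneric("tfrFreqs", function(object) standardGeneric("tfrFreqs"))

#' @rdname TFRSet-class
#' @export
setGeneric("isDb", function(object) standardGeneric("isDb"))

#' @rdname ClusterTestResult-class
#' @param object an object of the documented class.
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("significanceMask", function(object) standardGeneric("significanceMask"))

#' @rdname ClusterTestResult-class
#' @export
setGeneric("statMap", function(object) standardGeneric("statMap"))

#' @rdname LateralizationResult-class
#' @param object an object of the documented class.
#' @export
setGeneric("pooledIndex", function(object) standardGeneric("pooledIndex"))

#' @rdname DecodingResult-class
#' @param object an object of the documented class.
#' @param smoothed return the smoothed curve (default) or the raw one.
#' @export
setGeneric("accuracyCurve",
  function(object, smoothed = TRUE) standardGeneric("accuracyCurve"))

#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@sfreq)

#' @rdname EpochSet-class
#' @export
setMethod("sampleTimes", "EpochSet", function(object) object@times)

#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channels)

#' @rdname EpochSet-class
#' @export
setMethod("trialInfo", "EpochSet", function(object) object@trialInfo)

#' @rdname TFRSet-class
#' @export
setMethod("tfrPower", "TFRSet", function(object) object@power)

#' @rdname TFRSet-class
#' @export
setMethod("tfrFreqs", "TFRSet", function(object) object@freqs)

#' @rdname TFRSet-class
#' @export
setMethod("sampleTimes", "TFRSet", function(object) object@times)

#' @rdname TFRSet-class
#' @export
setMethod("channelNames", "TFRSet", function(object) object@channels)

#' @rdname TFRSet-class
#' @export
setMethod("trialInfo", "TFRSet", function(object) object@trialInfo)

#' @rdname TFRSet-class
#' @export
setMethod("isDb", "TFRSet", function(object) object@isDb)

#' @rdname ClusterTestResult-class
#' @export
setMethod("clusterTable", "ClusterTestResult", function(object) object@clusters)

#' @rdname ClusterTestResult-class
#' @export
setMethod("significanceMask", "ClusterTestResult", function(object) object@mask)

#' @rdname ClusterTestResult-class
#' @export
setMethod("statMap", "ClusterTestResult", function(object) object@tmap)

#' @rdname LateralizationResult-class
#' @export
setMethod("pooledIndex", "LateralizationResult", function(object) object@pooled)

#' @rdname LateralizationResult-class
#' @export
setMethod("sampleTimes", "LateralizationResult", function(object) object@times)

#' @rdname DecodingResult-class
#' @export
setMethod("accuracyCurve", "DecodingResult", function(object, smoothed = TRUE) {
  if (smoothed) object@accuracy else object@accuracyRaw
})

#' @rdname DecodingResult-class
#' @export
setMethod("sampleTimes", "DecodingResult", function(object) object@times)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat("  sfreq:", object@sfreq, "Hz; time:", min(object@times), "..",
      max(object@times), "ms\n")
  cat("  metadata columns:", paste(names(object@trialInfo), collapse = ", "),
      "\n")
})

setMethod("show", "WaveletBank", function(object) {
  cat("WaveletBank:", length(object@freqs), "wavelets,",
      min(object@freqs), "-", max(object@freqs), "Hz\n")
  cat("  spectral FWHM:", min(object@fwhmHz), "-", max(object@fwhmHz),
      "Hz; temporal FWHM:", round(max(object@fwhmMs)), "-",
      round(min(object@fwhmMs)), "ms\n")
})

setMethod("show", "TFRSet", function(object) {
  d <- dim(object@power)
  cat("TFRSet:", d[1], "x", d[2], "channels x", d[3], "freqs x", d[4],
      "time points", if (object@isDb) "(dB)" else "(raw power)", "\n")
  cat("  freqs:", min(object@freqs), "..", max(object@freqs),
      "Hz; time:", min(object@times), "..", max(object@times), "ms\n")
  if (object@isDb)
    cat("  baseline:", object@baselineWindow[1], "..",
        object@baselineWindow[2], "ms\n")
})

setMethod("show", "AdjacencyGraph", function(object) {
  deg <- lengths(object@neighbors)
  cat("AdjacencyGraph:", length(object@channels), "channels, median degree",
      stats::median(deg), "\n")
})

setMethod("show", "ClusterTestResult", function(object) {
  cat("ClusterTestResult:", nrow(object@clusters), "cluster(s),",
      if (object@exact) "exact enumeration of" else "", object@nPerm,
      "permutations\n")
  if (nrow(object@clusters)) {
    sig <- object@clusters$p < object@alpha
    cat("  significant at alpha", object@alpha, ":", sum(sig), "\n")
    print(utils::head(object@clusters, 5))
  }
})

setMethod("show", "LateralizationResult", function(object) {
  cat("LateralizationResult:", nrow(object@pairs), "pairs x",
      length(object@freqs), "freqs x", length(object@times), "time points\n")
  cat("  pooled band:", object@pooledBand[1], "-", object@pooledBand[2],
      "Hz over", length(object@pooledPairs), "posterior pairs\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult (", object@featureKind, "): ",
      length(object@times), " time points, ",
      object@nPredictions, " predictions each (",
      object@nIter, " x ", object@nGroups, "), group size ",
      object@groupSize, "\n", sep = "")
  cat("  mean accuracy:", round(mean(object@accuracyRaw), 3), "\n")
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("t(%g) = %.2f, p = %.3g, d = %.2f, adj. partial eta^2 = %.2f\n",
              object@df, object@t, object@p, object@d, object@etaAdj))
  cat(sprintf("BF10 = %.4g, BF01 = %.4g (Cauchy prior scale %.3f)\n",
              object@bf10, object@bf01, object@priorScale))
})
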