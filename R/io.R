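# On-disk container for epoched data and TFR power: one binary float32 array
# (documented shape/order) + JSON sidecar + CSV trial metadata.

.writeArrayDir <- function(dir, arr, sidecar, trialInfo) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4)  # column-major, float32
  sidecar$dim <- dim(arr)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(trialInfo, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
}

.readArrayDir <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  n <- prod(sidecar$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  arr <- array(readBin(con, numeric(), n, size = 4), sidecar$dim)
  info <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  list(arr = arr, sidecar = sidecar, trialInfo = info)
}

#' Write an EpochSet to a directory
#'
#' Serialises the data as a float32 binary array (column-major, trials x
#' channels x samples) with a JSON sidecar (sampling rate, time axis, channel
#' names, dimensions) and a CSV trial-metadata table. Note the float32
#' round-trip truncates to single precision.
#'
#' @param x an [EpochSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEpochSet <- function(x, dir) {
  stopifnot(is(x, "EpochSet"))
  .writeArrayDir(dir, x@data,
                 list(type = "EpochSet", sfreq = x@sfreq, times = x@times,
                      channels = x@channels),
                 x@trialInfo)
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
  r <- .readArrayDir(dir)
  stopifnot(identical(r$sidecar$type, "EpochSet"))
  new("EpochSet", data = r$arr, sfreq = r$sidecar$sfreq,
      times = r$sidecar$times, channels = r$sidecar$channels,
      trialInfo = r$trialInfo)
}

#' Write a TFRSet to a directory
#'
#' Same container as [writeEpochSet()] with the power array (trials x
#' channels x frequencies x time) and the frequency axis, decibel flag and
#' baseline in the sidecar.
#'
#' @param x a [TFRSet-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeTfrSet <- function(x, dir) {
  stopifnot(is(x, "TFRSet"))
  .writeArrayDir(dir, x@power,
                 list(type = "TFRSet", freqs = x@freqs, times = x@times,
                      channels = x@channels, isDb = x@isDb,
                      baselineWindow = x@baselineWindow,
                      baseline = as.numeric(x@baseline),
                      baselineDim = dim(x@baseline)),
                 x@trialInfo)
  invisible(dir)
}

#' @rdname writeTfrSet
#' @export
readTfrSet <- function(dir) {
  r <- .readArrayDir(dir)
  stopifnot(identical(r$sidecar$type, "TFRSet"))
  bl <- matrix(as.numeric(r$sidecar$baseline),
               r$sidecar$baselineDim[1], r$sidecar$baselineDim[2])
  new("TFRSet", power = r$arr, freqs = r$sidecar$freqs,
      times = r$sidecar$times, channels = r$sidecar$channels,
      isDb = r$sidecar$isDb,
      baselineWindow = as.numeric(r$sidecar$baselineWindow),
      baseline = bl, trialInfo = r$trialInfo)
}
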