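# Complex Morlet wavelet time-frequency decomposition with FWHM
# parameterisation, decibel baseline normalisation and edge trimming.

#' Build a complex Morlet wavelet bank
#'
#' Constructs a family of complex Morlet wavelets with Gaussian envelopes,
#' parameterised by spectral full width at half maximum (FWHM of the
#' amplitude spectrum). Defaults: 19 centre frequencies linearly spaced from
#' 2 to 20 Hz with spectral FWHM linearly interpolated from 0.75 Hz at the
#' lowest to 4.25 Hz at the highest frequency. The temporal FWHM follows from
#' the Gaussian reciprocity `fwhm_t * fwhm_f = 4 log(2) / pi` (about 1177 ms
#' at 2 Hz down to 208 ms at 20 Hz).
#'
#' @param sfreq sampling frequency in Hz; must be at least twice the highest
#'   wavelet frequency.
#' @param freqs centre frequencies (Hz).
#' @param fwhmHz spectral FWHM per wavelet (Hz); recycled by linear
#'   interpolation endpoints if of length 2.
#' @return a [WaveletBank-class].
#' @export
#' @examples
#' bank <- buildWavelets(200)
#' bank
buildWavelets <- function(sfreq, freqs = seq(2, 20, length.out = 19),
                          fwhmHz = c(0.75, 4.25)) {
  if (sfreq < 2 * max(freqs))
    stop("sfreq must be at least twice the highest wavelet frequency ",
         "(Nyquist)")
  if (length(fwhmHz) == 2L && length(freqs) > 2L)
    fwhmHz <- seq(fwhmHz[1], fwhmHz[2], length.out = length(freqs))
  stopifnot(length(fwhmHz) == length(freqs))
  sigma <- sqrt(2 * log(2)) / (pi * fwhmHz)
  new("WaveletBank", freqs = freqs, fwhmHz = fwhmHz,
      fwhmMs = 1000 * 4 * log(2) / (pi * fwhmHz),
      sigmaSec = sigma, sfreq = sfreq)
}

#' Evaluate a wavelet of a bank on its time grid
#'
#' Returns the complex, unit-energy wavelet for one bank entry, sampled at
#' the bank's sampling rate over +/- 4 temporal standard deviations.
#'
#' @param bank a [WaveletBank-class].
#' @param which index of the wavelet.
#' @return list with `t` (seconds) and `w` (complex values).
#' @export
waveletKernel <- function(bank, which) {
  stopifnot(which >= 1, which <= length(bank@freqs))
  s <- bank@sigmaSec[which]
  h <- ceiling(4 * s * bank@sfreq)
  tt <- (-h:h) / bank@sfreq
  w <- exp(2i * pi * bank@freqs[which] * tt) * exp(-tt^2 / (2 * s^2))
  w <- w / sqrt(sum(Mod(w)^2))
  list(t = tt, w = w)
}

#' Time-frequency decomposition by Morlet convolution
#'
#' Convolves every trial and channel with each wavelet of the bank
#' (frequency-domain multiplication, "same" alignment) and extracts power as
#' the squared magnitude of the complex result. The first and last `trimMs`
#' of the epoch are deleted after convolution to diminish edge artifacts;
#' power can be decimated by non-overlapping bin averaging.
#'
#' @param epochs an [EpochSet-class].
#' @param bank a [WaveletBank-class] built for the same sampling rate.
#' @param freqs optional subset of centre frequencies to compute (must be
#'   elements of `bank`'s frequencies).
#' @param trimMs edge trim in ms (default 700) applied to each end.
#' @param decimate integer bin size for averaging power over time samples
#'   after trimming (default 1 = no decimation).
#' @return a [TFRSet-class] with raw (linear) power.
#' @export
tfrDecompose <- function(epochs, bank, freqs = NULL, trimMs = 700,
                         decimate = 1L) {
  stopifnot(is(epochs, "EpochSet"), is(bank, "WaveletBank"))
  if (abs(bank@sfreq - epochs@sfreq) > 1e-9)
    stop("bank was built for a different sampling rate")
  fidx <- if (is.null(freqs)) seq_along(bank@freqs)
          else match(freqs, bank@freqs)
  if (anyNA(fidx))
    stop("requested frequencies are not in the wavelet bank")

  times <- epochs@times
  keep <- which(times >= min(times) + trimMs & times <= max(times) - trimMs)
  if (length(keep) < 1L)
    stop("epoch too short: nothing remains after trimming ", trimMs,
         " ms per side")

  d <- dim(epochs@data)
  ntr <- d[1]; nch <- d[2]; n <- d[3]
  kernels <- lapply(fidx, function(f) waveletKernel(bank, f))
  maxL <- max(vapply(kernels, function(k) length(k$w), integer(1)))
  if (n < maxL / 2)
    stop("epoch too short for the longest wavelet (", maxL, " samples)")
  nfft <- stats::nextn(n + maxL - 1L)
  wf <- vapply(kernels, function(k) {
    stats::fft(c(k$w, complex(real = rep(0, nfft - length(k$w)))))
  }, complex(nfft))
  half <- vapply(kernels, function(k) (length(k$w) - 1L) %/% 2L, integer(1))

  decimate <- as.integer(decimate)
  nt <- length(keep)
  nb <- nt %/% decimate
  binOf <- rep(seq_len(nb), each = decimate)
  tOut <- as.numeric(tapply(times[keep][seq_len(nb * decimate)], binOf, mean))

  out <- array(0, c(ntr, nch, length(fidx), nb))
  pad <- matrix(0, nfft, nch)
  for (tr in seq_len(ntr)) {
    slice <- epochs@data[tr, , , drop = FALSE]
    dim(slice) <- c(nch, n)
    pad[seq_len(n), ] <- t(slice)
    X <- stats::mvfft(pad)
    for (k in seq_along(fidx)) {
      conv <- stats::mvfft(X * wf[, k], inverse = TRUE) / nfft
      seg <- conv[half[k] + keep, , drop = FALSE]
      pw <- Mod(seg)^2
      if (decimate > 1L) {
        pw <- pw[seq_len(nb * decimate), , drop = FALSE]
        pw <- rowsum(pw, binOf) / decimate
      }
      out[tr, , k, ] <- t(pw)
    }
    pad[] <- 0
  }
  new("TFRSet", power = out, freqs = bank@freqs[fidx], times = tOut,
      channels = epochs@channels, isDb = FALSE, baselineWindow = numeric(0),
      baseline = matrix(numeric(0), 0, 0), trialInfo = epochs@trialInfo)
}

#' Average a TFR over trials
#'
#' Mean power across (a subset of) trials. Averaging is done in the input
#' domain: average raw power before decibel conversion.
#'
#' @param tfr a [TFRSet-class].
#' @param trials integer or logical index of trials (default: all).
#' @return a [TFRSet-class] with a single "trial" and empty trial metadata.
#' @export
tfrAverage <- function(tfr, trials = NULL) {
  stopifnot(is(tfr, "TFRSet"))
  d <- dim(tfr@power)
  idx <- if (is.null(trials)) seq_len(d[1]) else seq_len(d[1])[trials]
  if (length(idx) == 0L) stop("no trials selected")
  avg <- apply(tfr@power[idx, , , , drop = FALSE], c(2, 3, 4), mean)
  new("TFRSet", power = array(avg, c(1, d[2], d[3], d[4])), freqs = tfr@freqs,
      times = tfr@times, channels = tfr@channels, isDb = tfr@isDb,
      baselineWindow = tfr@baselineWindow, baseline = tfr@baseline,
      trialInfo = tfr@trialInfo[0, , drop = FALSE])
}

#' Decibel baseline normalisation
#'
#' Converts raw power to decibels relative to a condition-unspecific
#' baseline: `dB = 10 * log10(P / B)` where `B` is, per channel and
#' frequency, the mean raw power over all trials of `baselineFrom` (pooled
#' over conditions) and over the baseline time window, by default 700 to
#' 200 ms before the relevance cue.
#'
#' @param tfr a raw-power [TFRSet-class] to convert (trial-level or
#'   trial-averaged).
#' @param baselineFrom [TFRSet-class] supplying the baseline trials; default:
#'   `tfr` itself. Pass the pooled-trials set here to baseline per-condition
#'   averages condition-unspecifically.
#' @param window baseline window in ms, default `c(-700, -200)`.
#' @return a [TFRSet-class] in dB (`isDb = TRUE`) with the baseline stored.
#' @export
dbBaseline <- function(tfr, baselineFrom = tfr, window = c(-700, -200)) {
  stopifnot(is(tfr, "TFRSet"), is(baselineFrom, "TFRSet"))
  if (tfr@isDb) stop("input is already decibel-normalised")
  if (baselineFrom@isDb) stop("baselineFrom must hold raw power")
  .assertWindow(window, baselineFrom@times, "baseline window")
  tidx <- which(baselineFrom@times >= window[1] &
                baselineFrom@times <= window[2])
  B <- apply(baselineFrom@power[, , , tidx, drop = FALSE], c(2, 3), mean)
  if (any(B <= 0)) {
    bad <- which(B <= 0, arr.ind = TRUE)
    stop("zero baseline power at channel/frequency: ",
         paste(sprintf("%s/%g Hz", baselineFrom@channels[bad[, 1]],
                       baselineFrom@freqs[bad[, 2]]), collapse = ", "))
  }
  d <- dim(tfr@power)
  db <- 10 * log10(sweep(tfr@power, c(2, 3), B, "/"))
  new("TFRSet", power = db, freqs = tfr@freqs, times = tfr@times,
      channels = tfr@channels, isDb = TRUE, baselineWindow = window,
      baseline = B, trialInfo = tfr@trialInfo)
}

#' Invert decibel normalisation
#'
#' Maps a decibel-normalised [TFRSet-class] back to raw power using its
#' stored baseline.
#'
#' @param tfr a dB [TFRSet-class] produced by [dbBaseline()].
#' @return a raw-power [TFRSet-class].
#' @export
dbToRaw <- function(tfr) {
  stopifnot(is(tfr, "TFRSet"))
  if (!tfr@isDb) stop("input is not decibel-normalised")
  raw <- sweep(10^(tfr@power / 10), c(2, 3), tfr@baseline, "*")
  new("TFRSet", power = raw, freqs = tfr@freqs, times = tfr@times,
      channels = tfr@channels, isDb = FALSE, baselineWindow = numeric(0),
      baseline = matrix(numeric(0), 0, 0), trialInfo = tfr@trialInfo)
}
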