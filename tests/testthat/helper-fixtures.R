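# Shared fixtures, built once per run and memoised. All data are generated
# in code; sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a hand-built TFRSet with fully controlled power values
makeToyTfr <- function(power, freqs, times, channels,
                       trialInfo = data.frame()[seq_len(dim(power)[1]), ]) {
  new("TFRSet", power = power, freqs = freqs, times = times,
      channels = channels, isDb = FALSE, baselineWindow = numeric(0),
      baseline = matrix(numeric(0), 0, 0), trialInfo = trialInfo)
}

# small montage subset with a valid adjacency graph
smallMontage <- function(n = 8) {
  m <- readMontage()
  m[seq(1, nrow(m), length.out = n), , drop = FALSE]
}

# epochs with noise only, few channels, reused across files
nullEpochsSmall <- function() {
  fixture("nullEpochsSmall", function() {
    sched <- makeSchedule(1, 16, seed = 101)
    simulateEpochs(sched, nullEffectSpec(),
                   channels = c("C3", "C4", "P3", "P4"), seed = 102)
  })
}

# bind two equally shaped 4-d arrays along the trial axis
abind2 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3], d[4]))
  out[seq_len(d[1]), , , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , , ] <- b
  out
}

# independent oracle: exhaustive sign-flip permutation p of a one-sample
# cluster test on a single value series (single pixel), written directly from
# the definition
exactSignFlipOracle <- function(x, clusterAlpha = 0.05) {
  n <- length(x)
  tstat <- function(v) mean(v) / (stats::sd(v) / sqrt(length(v)))
  tcrit <- stats::qt(1 - clusterAlpha / 2, n - 1)
  tobs <- tstat(x)
  if (abs(tobs) <= tcrit) return(NULL)  # no cluster forms
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  permMax <- apply(signs, 1, function(s) {
    tp <- tstat(s * x)
    if (abs(tp) > tcrit) abs(tp) else 0
  })
  mean(permMax >= abs(tobs) - 1e-12)
}
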