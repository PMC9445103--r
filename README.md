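# prioEEG

Simulation and analysis of task-prioritization EEG experiments in R.

## The problem

In dual-task paradigms, a trial-initial *relevance cue* can mark one of two
nested tasks as more important — for example a cued number classification
task (NCT) performed inside the retention interval of a retro-cue working
memory task (WMT), with feedback from the important task weighted three
times as strongly. Analysing such experiments requires a chain of
specialised methods: Morlet time–frequency decomposition, cluster-based
permutation statistics over the electrode × frequency × time space,
time-resolved multivariate decoding, hemispheric alpha lateralization
indices, and Bayesian follow-up inference. prioEEG implements that chain as
a tested, reusable package for cognitive-neuroscience researchers, together
with a synthetic-data generator that emulates the paradigm so every stage
can be validated against planted ground truth without any recordings.

## The methods at its core

* **Feedback scores.** `FP_NCT = max − max/(1800−400)·(RT−400)` (max for
  RT ≤ 400 ms, 0 for misses/errors) and `FP_WMT = max − max/45°·deviation`,
  with `max` = 75 points for the cued and 25 for the un-cued task.
* **Time–frequency decomposition.** 19 complex Morlet wavelets, 2–20 Hz,
  spectral FWHM 0.75–4.25 Hz (temporal FWHM from the Gaussian reciprocity
  `fwhm_t·fwhm_f = 4 ln 2/π`), 700 ms edge trim, and decibel normalisation
  `10·log₁₀(P/B)` against a condition-pooled −700…−200 ms baseline.
* **Cluster-based permutation tests.** Per-pixel paired *t*; clusters of
  same-signed suprathreshold pixels connected over montage neighbours,
  adjacent frequencies and adjacent time points; cluster mass = Σt tested
  against the sign-flip permutation distribution of the maximum absolute
  mass, `p = (1 + hits)/(1 + n_perm)` (exact enumeration for n ≤ 14).
* **Trial-group-averaged decoding.** Per time point, 10 × 15-fold
  cross-validation of a linear SVM trained on group-averaged trials
  (features: 64 broadband channels, or 64 × 5 raw alpha-power values at
  8–12 Hz), accuracy smoothed with a ±100 ms moving average.
* **Lateralization index.** `(ipsi − contra)/(ipsi + contra)` on raw power
  relative to the retro-cue side, from cue-direction × response-side
  balanced trial draws, pooled over 17 posterior mirror pairs and 8–15 Hz.
* **Inference.** Two-sided one-sample/paired *t* tests with
  `d = t/√n`, adjusted partial eta squared
  `(F−1)/(F−1+(df_err+1)/df_eff)`, and JZS Bayes factors (Cauchy prior,
  scale 0.707) computed by log-space quadrature.

## Worked example

```r
library(prioEEG)

# one synthetic subject: schedule, behaviour, feedback
sched <- makeSchedule(nBlocks = 1, trialsPerBlock = 24, seed = 1)
beh   <- simulateBehavior(sched, seed = 2)
fp    <- feedbackScores(sched, beh)
head(cbind(sched[, c("important_task", "retrocue_side")], fp), 4)
#>   important_task retrocue_side   fp_nct   fp_wmt    total
#> 1            WMT          left  0.00000 58.02418 58.02418
#> 2            NCT         right 73.12403 15.35312 88.47715
#> 3            NCT          left 64.96500 13.98498 78.94997
#> 4            NCT          left 67.17438 16.57005 83.74443
```

Trial 1 missed (or erred on) the digit classification — zero NCT points —
but reproduced the memory orientation well while the WMT was cued
(58 of 75). Trials 2–4 answered the digit fast while the NCT was cued.

```r
# epoched EEG over a posterior channel subset, with the default planted
# alpha lateralization of magnitude 0.05
chans <- c("PO3", "PO4", "O1", "O2")
spec  <- effectSpec(bandEffects = list(), decoding = list())
ep    <- simulateEpochs(sched, spec, behavior = beh, channels = chans, seed = 3)
ep
#> EpochSet: 24 trials x 4 channels x 3481 samples
#>   sfreq: 200 Hz; time: -3700 .. 13700 ms

# wavelet power, balanced trial draw, lateralization index
tfr <- tfrDecompose(ep, buildWavelets(200), freqs = 8:15, decimate = 10)
bal <- drawBalancedTrials(trialInfo(ep), seed = 4)
lat <- lateralizationIndex(tfr, pairing = mirrorPairs(chans), trials = bal,
                           pooledPairs = mirrorPairs(chans))
mean(pooledIndex(lat)[sampleTimes(lat) >= 9900 & sampleTimes(lat) <= 10500])
#> 0.044
```

The pooled index between retro-cue and memory-target onset recovers the
planted asymmetry of 0.05 up to single-subject simulation noise, and stays
near zero elsewhere in the trial.

```r
# follow-up inference on per-subject interval averages
set.seed(5)
vals <- rnorm(28, mean = 0.02, sd = 0.02)
inferenceTest(vals, mu = 0)
#> t(27) = 5.62, p = 5.84e-06, d = 1.06, adj. partial eta^2 = 0.52
#> BF10 = 3491, BF01 = 0.0002865 (Cauchy prior scale 0.707)
```

`runPipeline(config)` chains all stages (simulation → behaviour → 3-D
cluster test → decoding → lateralization → interval Bayes statistics) into
a reproducible report; see the vignette in `vignettes/` for the model
details, parameter conventions and design decisions.

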