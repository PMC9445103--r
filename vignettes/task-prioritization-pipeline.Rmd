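---
title: "Analysing task-prioritization EEG experiments with prioEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing task-prioritization EEG experiments with prioEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioEEG)
```

## The paradigm and what the package computes

prioEEG analyses a dual-task paradigm in which every trial nests a cued
number classification task (NCT) inside the retention interval of a
retro-cue working memory task (WMT). A relevance cue at trial start marks
one of the two tasks as *important*: feedback from that task is weighted
three times as strongly (75 of 100 possible points, versus 25 for the
un-cued task). The trial timeline is fixed: relevance cue at 0 ms (500 ms on
screen), bilateral memory items at 3000 ms (400 ms), classification cue at
5600 ms (200 ms), classification digit at 6800 ms (200 ms), retro-cue at
9600 ms (200 ms), memory target at 10800 ms (`eventOnsets()`).

Four analysis families ask where in the trial, and at which level of
control, prioritization acts:

1. **Mass-univariate power analysis.** Condition-mean, decibel-normalised
   Morlet power is compared between NCT-important and WMT-important trials
   at every electrode x frequency x time pixel with a paired cluster-based
   permutation test.
2. **Time-resolved decoding.** Within each importance condition, a linear
   SVM decodes the classification type (odd/even vs smaller/bigger five)
   from scalp topographies over time, using the trial-group-averaged
   cross-validation scheme; condition curves are compared with cluster
   tests and interval Bayes factors.
3. **Alpha lateralization.** Hemispheric asymmetry of raw alpha power
   relative to the retro-cue direction is summarised by the index
   `(ipsi - contra) / (ipsi + contra)`, pooled over 17 posterior mirror
   pairs and 8-15 Hz.
4. **Follow-up inference.** Interval-averaged measures get two-sided t
   tests with Cohen's `d = t / sqrt(n)`, adjusted partial eta squared
   `(F - 1) / (F - 1 + (df_error + 1) / df_effect)` with `F = t^2`, and JZS
   Bayes factors (Cauchy prior scale 0.707).

Because the analyses are stochastic and high-dimensional, the package ships
a synthetic-data generator whose planted effects give every stage a known
ground truth. All tests and the acceptance script run entirely on synthetic
data.

## The synthetic generator: what it emulates, and what it does not

`makeSchedule()` reproduces the factorial design: blocks in which important
task, retro-cue side and classification type each appear equally often with
balanced co-occurrences, in randomized order. With the default 60-trial
blocks the full three-way cells cannot balance exactly within a block
(60 / 8 = 7.5); the generator balances all single factors and all pairwise
co-occurrences exactly within every block, and assigns the four surplus
trials to the even- or odd-parity cell class on alternating blocks, so full
cells balance exactly across consecutive block pairs (600 trials over 10
blocks give exactly 75 per cell).

`simulateBehavior()` draws response times from log-normal distributions
truncated to the registration windows ([200, 1800] ms for the digit
response, [200, 4500] ms for the memory response) and angular deviations
from truncated normals. Defaults are the published condition means and
standard deviations (e.g. digit-response means 537.00 vs 562.86 ms,
deviations 11.77 vs 13.48 degrees, about 8.6% classification errors). Only
means and SDs are reported for the real data; the log-normal family is a
modelling choice made once -- right-skewed, strictly positive, and standard
for response times. The printed SDs are used as trial-level SDs, which is
deliberately conservative (between-subject SDs of subject means would be
smaller).

`simulateEpochs()` emits epochs spanning -3700 to +13700 ms at 200 Hz --
700 ms wider on each side than the analysis window, so the wavelet stage
can trim edge artifacts -- for any subset of the shipped 64-channel 10-10
montage. The additive signal model is:

* **Background.** Per channel, 1/f ("pink") noise with exponent 1 and 10 uV
  SD plus 2 uV white sensor noise. This matches the broadband spectral
  shape the wavelet stage expects; preprocessing (filtering, ICA, artifact
  rejection) is out of scope, so the generator emits "clean" data directly.
* **Condition-contrasting bursts.** Hann-windowed sinusoids of a given
  frequency, window, channel set, amplitude and condition. The defaults
  plant a 5 Hz NCT>WMT burst during the relevance-cue interval and during
  task preparation (3000-5600 ms) and a 10 Hz WMT>NCT burst during task
  performance (5665-7830 ms) -- the qualitative phenomena the 3-D cluster
  test is meant to detect, at the realistic sub-decibel scale (1.2 uV on a
  10 uV background).
* **Lateralized alpha.** In the retro-cue-to-target window (9600-10800 ms),
  band-limited 8-15 Hz noise bursts at the posterior pairs whose amplitude
  is `sqrt(1 + m)` on the hemisphere ipsilateral to the cue and
  `sqrt(1 - m)` contralateral. Expressing the planted magnitude directly as
  the target index `m` (default 0.05, the scale of published retro-cue
  effects) makes recovery testable; the default burst amplitude (12 uV RMS)
  keeps background dilution of the measured index below 0.005.
* **Decodable class patterns.** Two fixed random unit-norm channel
  topographies (drawn once per run) carry a deterministic slow waveform
  (for ERP decoding) and a random-phase 10 Hz amplitude modulation (for
  alpha-power decoding) during 5600-8000 ms, scaled by the class of each
  trial's classification type.

What the generator does **not** emulate: volume-conducted correlations
between channels (noise is independent per channel), eye and muscle
artifacts, realistic forward-model topographies, trial-to-trial drift, or
behavioural-neural coupling. Passing tests therefore demonstrate the
*statistical machinery* -- calibration under the null, recovery of planted
effects, determinism -- not performance on real recordings.

## Time-frequency decomposition

`buildWavelets()` constructs 19 complex Morlet wavelets linearly spaced
2-20 Hz, parameterised by the full width at half maximum of their Gaussian
envelope. The published description gives spectral FWHM 0.75-4.25 Hz "and"
temporal FWHM 1000-200 ms, but a Gaussian cannot satisfy both pairs at
once: the amplitude-spectrum reciprocity is
`fwhm_t * fwhm_f = 4 log(2) / pi ~ 0.8825`, so 0.75 Hz pairs with 1177 ms
and 4.25 Hz with 208 ms. The bank is anchored on the spectral values
(stated first, and the 200 ms endpoint agrees with them to 4%); temporal
FWHM follows from the reciprocity. FWHM interpolation across wavelets is
linear in frequency between the two endpoints.

Wavelets are unit-energy in the time domain, evaluated over +/- 4 temporal
SDs, and applied by frequency-domain multiplication with "same" alignment.
Power is the squared magnitude of the complex result; the first and last
700 ms of each epoch are deleted afterwards. Unit-energy normalisation is
one consistent choice among several -- the decibel baseline and the
lateralization index are ratios, so any frequency-consistent normalisation
yields identical statistics.

Decibel normalisation uses a condition-unspecific baseline: per channel and
frequency, the mean raw power over *all* trials (both conditions pooled)
in -700 to -200 ms before the relevance cue. Condition averages are formed
on raw power first and converted afterwards; with the shared baseline, the
dB difference between conditions reduces to `10 log10(Pa / Pb)` and is
baseline-invariant, which is why a pre-cue cluster onset cannot leak into
later condition contrasts. Statistics operate on per-subject condition
means in dB.

## Cluster-based permutation inference

The 3-D test forms, per pixel, a paired t statistic across subjects;
pixels with two-sided `p < 0.05` (the cluster-forming threshold -- a
configurable convention of the method, not a reconstruction of any
particular analysis's unstated setting) are clustered
by connectivity: montage neighbours at the same frequency and time, plus
nearest neighbours along the frequency and the time axis, with equal sign
required. The cluster statistic is the summed t ("mass"); the null
distribution is the maximum absolute cluster mass over sign-flips of the
subject-wise condition differences. Monte-Carlo p values use the +1
correction `p = (1 + hits) / (1 + nPerm)` (default 1000 permutations,
seeded); for `n <= 14` subjects all `2^n` sign assignments can be
enumerated exactly, and the test suite pins the single-pixel case to an
independent exhaustive-enumeration oracle. Zero-variance pixels get t = 0
with a warning rather than NaN. The 1-D variant reuses the same engine
with a chain adjacency for decoding-accuracy and lateralization curves
(one-sample against 0 or chance, or paired).

Channel neighbourhoods come from the shipped idealized unit-sphere montage:
two channels are neighbours below a Euclidean distance threshold whose
default (0.55) gives a median of 6 neighbours, a typical density for EEG
cluster statistics. The montage coordinates are an idealized geodesic
construction of the 10-10 system, adequate for neighbourhood structure and
simulation but not digitised head positions.

## Decoding scheme

Features are downsampled to 20 Hz by non-overlapping bin averaging (the
original description says only "down-sampled"; bin averaging denoises and
keeps alignment trivial). Broadband ERP decoding uses one feature per
channel; alpha-power decoding uses raw, non-baselined power at the 8-12 Hz
wavelets (channels x 5 features). Per time point and iteration, trials of
each class are randomly split into 15 groups (surplus trials randomly
excluded, so training sets always hold equally many averages per class),
group averages are formed, and a linear SVM (cost 1, no feature scaling --
none is reported) is trained on the 28 training-fold averages and applied
to the two held-out averages. With 10 iterations this gives 300 classified
averages per time point (the published count of 150 enumerates folds;
accuracy, correct/total, is unaffected). Group assignment is re-randomized
per iteration and held constant across time points. Curves are smoothed
with a 5-point (+/- 100 ms) moving average whose window shrinks at the
ends rather than padding.

Group size is whatever the balanced trial count divided by 15 yields; the
published "six to nine trials per group" describes that study's trial
counts and is not enforced. The SVM itself is libsvm via e1071; because the
scheme requires tens of thousands of fits on 28 x features problems, the
package calls the library's training routine directly with pre-validated
input (the test suite pins decision-value equality against `e1071::svm()`).

## Lateralization conventions

"Ipsilateral" means the hemisphere on the same side as the retro-cued item,
so a positive index (ipsi > contra) encodes the classic attention pattern
of reduced contralateral alpha. Trials enter the index through a balanced
draw: equal counts in every retro-cue side x response side cell, each cell
truncated to the smallest cell's size -- the only count-preserving reading
of drawing "equally often". The pooled curve averages the 17 posterior
pairs and the wavelet centres 8-15 Hz inclusive (8 wavelets). The published
pair list contains the typo "C3(C4", read as the C3/C4 pair. The index
requires linear power; decibel input is rejected.

## Inference conventions

The effect-size conventions `d = t / sqrt(n)` and the adjusted partial eta
squared formula above are adopted because they reproduce every published
(t, d, eta) triple the defaults are calibrated against to two decimals;
that consistency is asserted in the test suite. The JZS Bayes factor integrates the Cauchy
prior via its inverse-gamma mixture representation with adaptive
quadrature in log space (relative tolerance 1e-8, integrand re-centred at
its mode), which keeps `|t|` up to 60 finite; an independent fine-grid
trapezoid oracle checks the quadrature. Extreme Bayes factors (1e24-1e27)
are computed but not held to printed values: rounding the underlying t to
two decimals already shifts them by tens of percent.

## Pipeline, configuration and reproducibility

`validateConfig()` fills a complete default configuration (the study
design: 10 x 60 trials, 28 subjects, 19 wavelets, 15 groups x 10
iterations, prior scale 0.707) and rejects inconsistent windows and bands
with a collected error list. `runPipeline()` executes the full graph --
simulation, behaviour, TFR cluster test, decoding, lateralization, interval
Bayes statistics -- deriving every stage's seed deterministically from the
global seed and the stage name, so identical configurations reproduce
byte-identical reports. Containers can be serialized per stage
(`writeEpochSet()`/`writeTfrSet()`: float32 binary + JSON sidecar + CSV
metadata), so stages can be rerun from upstream outputs.

A full-scale default run (28 subjects x 600 trials x 64 channels) holds
about 8.6 GB of epochs per subject in memory at double precision and is
intended for machines sized accordingly; the shipped tests and the
acceptance script use reduced problem sizes chosen to exercise every code
path with stable statistics: 2-3 subjects and 1-2 blocks for unit tests,
6-8 subjects with 16-34 channels for recovery checks, 500 reduced-grid
experiments (12 subjects, 8 channels x 5 frequencies x 40 time points, 500
permutations) for the family-wise error calibration, and 20 subjects x 120
trials for the chance-level calibration of decoding. Planted-effect
amplitudes in the recovery tests are scaled to those reduced designs (for
example a 4 uV theta contrast where the generator's realistic default is
1.2 uV), since detectability, not realism, is what those tests certify.

## Known limitations

* The generator's channels are statistically independent; spatial
  correlation structure of real EEG (volume conduction) is absent, so
  cluster extents on synthetic data are smaller than on real recordings.
* The cluster-forming threshold and permutation count are conventions, not
  reconstructions of unpublished settings; results at other settings are a
  configuration change away.
* Exact sign-flip enumeration is limited to 14 subjects; beyond that the
  Monte-Carlo error of 1000 permutations (about +/- 0.007 at p = 0.05)
  applies.
* The decoding stage assumes exactly two classes, as in the paradigm;
  multi-class wrappers are out of scope.
* Bayes factors are two-sided; directional hypotheses and posterior
  estimation are not implemented.
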