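---
title: "Screening for hypertension from mattress BCG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for hypertension from mattress BCG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BCGcar)
```

## The problem and the approach

A ballistocardiogram (BCG) records the micro-vibrations of the body caused
by cardiac ejection of blood. A pressure-sensitive mattress can record it
through a full night of sleep without electrodes, which makes it attractive
for screening: hypertension is symptomless for years, and an unobtrusive
overnight measurement reaches people who would never wear a Holter monitor.

`BCGcar` turns a single-channel 100 Hz BCG recording into a screening
decision in three stages:

1. **Conditioning and beat detection** — normalize, bandpass to the
   heartbeat band, reconstruct the low-frequency wavelet approximation, and
   detect beats with an overlapping sliding window, yielding the RR
   (inter-beat) interval sequence.
2. **Fourteen features per subject** — ten heart rate variability (HRV)
   features from the RR sequence (time, frequency and non-linear domains)
   and four fluctuation descriptors of the conditioned BCG trace itself.
3. **Rule mining and classification** — discretize features into five
   equal-width levels, mine all class association rules (CARs) above
   support and confidence thresholds with a levelwise Apriori search, sort
   them by precedence, and build a database-coverage classifier whose
   ordered rule list is directly readable by a clinician.

The interpretability is the point: instead of a margin or a probability,
the model's output is backed by rules such as "ANEP high *and* DFA low
⟹ hypertensive", each with its support and confidence on training data.

## Signal conditioning

**Normalization.** Body weight scales BCG amplitude, so each recording is
z-scored first. We use the population (1/N) standard deviation; with
recordings of thousands of samples the distinction from the sample
estimator is immaterial, but it is fixed and documented so results are
bit-reproducible.

**Bandpass.** An order-4 elliptic bandpass with corners at 5/6 and
13/6 Hz, 0.2 dB passband ripple and 8 dB stopband attenuation isolates
the heartbeat band (50–130 bpm). The filter is applied forward and
backward (`signal::filtfilt`), which squares the magnitude response and,
critically, has zero phase: beat peaks are not displaced. The signal is
reflection-padded before filtering so edge transients do not reach the
data.

**Wavelet approximation.** Beats are detected on the low-frequency
approximation of a db6 wavelet filter bank at level 5, which at 100 Hz
retains content roughly below 1.56 Hz — the heartbeat fundamental — and
discards the sharper waves, noise, and spike artifacts. We use the
*undecimated* (MODWT/à-trous) transform rather than the decimated
pyramid. The decimated transform is shift-variant: in our measurements
its level-5 approximation wiggles the peaks of even a pure 1 Hz tone by
up to ±12 samples depending on where the tone sits relative to the
decimation grid, an error an order of magnitude larger than everything
else in the timing budget. The undecimated smooth uses the same db6
filter pair, is strictly shift-invariant, and its analysis–synthesis
chain is a symmetric (zero-phase) operator, so pulse peaks stay put. The
level-1 smooth and detail still add up to the input exactly, and the
level-5 band edge is unchanged.

**Beat detection.** A 100-sample window advancing by 40 samples (60-sample
overlap) nominates its maximum as a candidate peak; the window is short
enough that every beat wins some window at normal heart rates. Three
validation rules then apply, all fixed before any evaluation:

* a candidate must be a strict local maximum of the trace — this discards
  window-boundary artifacts in windows that contain no beat;
* candidates below 20% of the median candidate amplitude are dropped —
  this removes low-amplitude ripple that can survive near the recording
  edges;
* candidates closer than 40 samples (0.4 s, i.e. 150 bpm) are merged,
  keeping the larger — the same physical peak can win several overlapping
  windows.

Finally RR intervals outside [0.4, 2.0] s are discarded (not bridged or
split): outside 30–150 bpm an interval from a sleeping adult is a
detection error, not physiology. Recordings whose beats point downward
can be processed with `invert = TRUE`.

## The fourteen features

**Time domain** (`hrvTimeDomain`): mean RR, SDNN (sample sd), RMSSD (root
mean square of the N−1 successive differences), and pNN50. pNN50 is
implemented as the standard *fraction of successive differences exceeding
50 ms*. A literal reading of "RR intervals longer than 50 ms" would be
≈100% for any human and could never produce the ≈0.25 values reported on
real cohorts, so the standard definition is the only self-consistent one.

**Frequency domain** (`hrvFrequencyDomain`): the RR tachogram (interval
against cumulative beat time) is resampled at 4 Hz by cubic spline,
demeaned, and its PSD estimated by Welch's method — Hann window,
256-sample (64 s) segments, 50% overlap. Powers are integrated over
vLF (0.0033–0.04 Hz), LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz); LF/HF is
their ratio. Any consistent PSD estimator preserves the band-dominance
properties the pipeline relies on; Welch is chosen for its variance
behaviour on short records. Band powers are absolute by default
(`normalize = TRUE` divides by their sum). A 60 s minimum duration is
enforced; the vLF band is only meaningful on records of several minutes.

**Non-linear domain**: sample entropy with m = 2 and tolerance
r = 0.15·sd (Chebyshev distance, self-matches excluded, both template
counts over positions 1..N−m), and the DFA scaling exponent α with
linear detrending over 15 log-spaced segment lengths in 40 ≤ s ≤ 240
beats. The lower scale bound skips the respiratory periodicity (3–6
beats per breath); white noise gives α ≈ 0.5 and integrated noise
α ≈ 1.5, which the test suite verifies by Monte Carlo.

**BCG fluctuation** (`zcr`, `acac`, `anep`, `astc`): computed on the
normalized, bandpass-filtered trace — the same trace the wavelet stage
consumes. Normalization is what makes the fixed ASTC threshold
Th = 0.01 comparable across subjects. ZCR is the zero-crossing rate with
sgn(0) = 0; ACAC the total variation per second; ANEP the number of
strict local extrema (second-difference sign pattern ±2) plus one
end-compensation, per second — plateau-topped peaks are deliberately not
counted, following the formula rather than intuition; ASTC counts turns
whose amplitude gaps to both neighbours reach Th, per second. All four
are offset-invariant except ZCR, which depends on sign by construction.
Hypertensive recordings show more "signal thorns" (isolated spikes), so
ANEP and ASTC run higher in that class; this direction is what the
synthetic generator reproduces and the tests assert.

## Rule mining

Each feature is split into five equal-width intervals over its *training*
range ("very low" … "very high", coded 1–5); intervals are
left-closed/right-open except the last, and test-time values outside the
training range clip to bins 1/5 so no subject is unclassifiable. The
class is item 1 (hypertensive) or 2 (normotensive). A subject becomes a
transaction: one item per feature plus the class item.

`mineCARs` performs a levelwise Apriori search. Internally class items
take the lowest item ids, so sorted itemsets always carry the class item
first and the classic prefix join of frequent (k−1)-itemsets generates
every candidate class-bearing k-itemset; candidates with two items on
one attribute are pruned during the join. A rule's support is the
fraction of transactions containing antecedent *and* class (so support
≤ confidence always); its confidence is the ratio of that count to the
antecedent count. Support is filtered first, confidence second, and
levels are pooled. The property suite checks the miner rule-for-rule
against exhaustive enumeration on hundreds of random small tables, and
checks monotonicity: raising either threshold never adds a rule.

The search space explodes as support drops (real-data rule counts grow
roughly 10× from minSup 0.3 to 0.2), so `maxLen` optionally caps the
items per rule; the default is uncapped.

**Choosing minSup.** The package defaults are minSup 0.3 and minConf 0.8,
the operating point established on the real 128-subject cohort. That
support level demands a single rule cover ≥ 60% of one class. Whether
that is attainable depends on the shape of the feature distributions
under equal-width binning: skewed features concentrate most of a class
in one bin; Gaussian features do not. For the package's synthetic
cohorts, whose features are Gaussian by construction, a class spreads
over ≈2.5 of the 5 bins and the best single bin captures only ~55% of
it, so at minSup 0.3 the miner structurally finds almost no rules no
matter how separated the classes are. The synthetic-cohort experiments
in this package therefore use minSup 0.2 (minConf unchanged at 0.8,
maxLen 3), which is the same reasoning a practitioner would apply before
mining any cohort: pick a support threshold below the achievable
single-rule class coverage.

## The classifier

Rules are sorted by precedence: higher confidence first, ties by higher
support, then by more items (the more specific rule first), remaining
ties stable. Construction is by database coverage: walking the sorted
list, a rule is *marked* if it correctly classifies (antecedent
contained *and* class equal) at least one remaining training
transaction; marked rules are appended to the model and their correctly
classified transactions removed. Transactions a rule matches but
mislabels remain in play — the literal reading of the build algorithm.
The default class is the majority class of the uncovered remainder; when
everything is covered it falls back to the majority of the full training
set. Majority ties resolve to *hypertensive*: in a screening context a
missed patient costs more than a false alarm, so the tie-break favours
recall. Prediction is first-match over the ordered rules, with the
default class as the fallback, so every subject receives a label.

Models serialize to a single JSON document (rules, order, default class,
bin edges, thresholds, schema version); a reloaded model predicts
identically, which the suite asserts.

## Evaluation protocol

Evaluation uses ten repeated stratified 2:1 train/test splits — the
protocol described for the real cohort (the description calls it
ten-fold cross-validation but specifies random 2:1 partitions repeated
ten times, which is what is implemented). Per-class training counts use
largest-remainder rounding of the 2/3 quotas against the floored total,
ties to the hypertensive class: 61 + 67 subjects split 85/43 with
41/44 vs 20/23 per class. Metrics are accuracy, precision and recall
with hypertensive as the positive class, averaged over repeats.

`ttestScreen` (Welch's two-sample t-test per feature, p < 0.05) exists
for building baseline classifiers; the rule miner itself consumes all
fourteen features and ignores unhelpful ones on its own. `ablation` runs
the cumulative group combinations TD, TD+FD, TD+FD+ND, TD+FD+ND+BF.

## The synthetic generator

`simulateBCG` emulates exactly the structure the pipeline exploits:

* a quasi-periodic pulse train — each beat a Gaussian-windowed cosine
  (carrier 1.2 Hz, envelope σ = 0.12 s), symmetric about the beat time so
  zero-phase conditioning keeps peaks centred;
* RR variability — Gaussian jitter (default sd 20 ms, a realistic
  beat-to-beat variability for sleep) plus a 30 ms sinusoidal modulation
  at 0.1 Hz for controllable LF/HF band content;
* respiration — an additive 0.25 Hz sinusoid at 0.3 relative amplitude;
* thorns — single-sample spikes of random sign and twice the pulse
  amplitude at a Poisson rate, denser for simulated hypertensives
  (defaults 2.0/s vs 0.5/s; no quantitative thorn statistics exist for
  real data, so these are free parameters fixed once);
* white Gaussian noise (default sd 0.1).

The default mean RR is 0.8 s, matching the ≈74–77 bpm heart rates of the
real cohorts. The beat train continues ≈2 s past both edges of the
recording window (those phantom beats are not ground truth) because the
heart does not stop when the recording does; without them the first and
last in-window pulses see asymmetric neighbourhoods and their detected
peaks shift by 1–2 samples.

What the generator does *not* emulate: real BCG wave morphology (I/J/K
complexes), body-movement artifacts, non-stationary heart rate drifts,
and apnea-like events. Passing the end-to-end tests therefore
demonstrates that the pipeline is implemented correctly and recovers
known ground truth under realistic signal structure — not that it
reproduces clinical performance on real patients.

`simulateFeatureTable` draws feature vectors directly from
class-conditional normals. Its default effect profile follows the group
means and standard deviations observed on real data (direction is what
matters downstream: hypertensive lower in mean RR, vLF, ACAC, DFA;
higher in SampEn, ZCR, ANEP, ASTC). `defaultEffectProfile(separation = 3)`
rescales all class mean differences to 3 pooled sds for constructing
clearly separable cohorts.

## Numerical choices and degenerate inputs

* Constant signals: z-scoring, sample entropy and the discretizer refuse
  degenerate (zero-variance) input explicitly rather than returning NaN;
  the discretizer drops constant features with a warning.
* Sample entropy returns `Inf` when no length-(m+1) template pair
  matches and errors when no length-m pair does (the quantity is
  undefined); both conditions are reachable on short noisy series.
* Interval edges: discretization bins are `[a, b)` except the last;
  `findInterval(..., rightmost.closed = TRUE)` implements the closed
  last bin, and clipping handles out-of-range test values.
* The miner compares `count/n >= minSup` in exact floating point; the
  test oracle uses the identical expression, so threshold-boundary rules
  cannot diverge between the two.
* Reflection padding (512 samples) is used before both filtering and the
  wavelet transform to keep circular wrap-around and filter transients
  out of the analyzed span.

## Problem sizes used by the test and acceptance suites

Module tests use 20–60 s simulated recordings, feature tables of 128
subjects (64 per class, mirroring the real cohort's size), 200 random
rule-mining tables of ≤ 30 transactions and ≤ 5 attributes, 100 random
sequences of length ≤ 200 for the sample-entropy oracle, and 50
Monte-Carlo replicates of length-2000 series for DFA calibration. The
full-feature extraction test uses one 360 s recording, the shortest
duration for which the DFA scale range (240 beats) and the vLF band are
both well-defined. These sizes were chosen as the smallest that make the
assertions statistically meaningful.

## Known limitations

* Beat detection assumes a dominant heartbeat fundamental inside
  0.83–1.56 Hz; bradycardia below 50 bpm would fall outside the bandpass
  design and is untested.
* The equal-width discretizer is sensitive to extreme outliers in the
  training range (they stretch the bins); a robust variant (quantile
  clipping before binning) is a natural extension.
* The miner is a plain levelwise Apriori in R; at minSup well below 0.2
  on 14 features it will be slow. `maxLen` is the practical control.
* The pipeline classifies; it does not estimate blood pressure.
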