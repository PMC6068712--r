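---
title: "The four-stage arrhythmia discrimination cascade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-stage arrhythmia discrimination cascade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgkit)
```

## The problem and the model

A monitoring device sees a single-lead ECG stream with no prior knowledge of
which arrhythmia, if any, the wearer experiences. `ecgkit` implements a
screening cascade that classifies every 8 s window with strict ordering:

1. **Ventricular fibrillation (VF) first**, because it is immediately
   life-threatening. VF has no discrete QRS complexes; it is detected from
   six segment-level features: four derived from binary images of two
   time-delay phase plots, one spectral count, and the amplitude Shannon
   entropy.
2. **Atrial fibrillation (AF) second**, detected from the irregularity of
   RR intervals (Shannon entropy, turning point ratio, RMSSD) after
   premature beats are excluded.
3. **Premature ventricular contraction (PVC) beats third**: every beat of a
   non-VF, non-AF segment is classified PVC/normal from four beat-level
   features (peak-to-valley amplitude, maximum spectral amplitude, wavelet
   Shannon entropy, kurtosis).
4. **Episode grammar last**: the per-beat 0/1 label vector is mapped to one
   of seven episode codes (NSR, couplet, triplet, VT, bigeminy, trigeminy,
   quadrigeminy), yielding one code per segment - the vector of episode
   type (VET).

A segment never receives both a VF call and an episode code; each stage
stops the cascade when it fires.

## Preprocessing

Records are resampled to 300 Hz (Fourier method - exact for band-limited
signals; the subsequent band-pass removes any edge ringing), filtered with
a third-order Butterworth band-pass of 0.4-30 Hz, and cut into 8 s windows
(2400 samples) every 5 s (3 s overlap). Both window length and overlap are
configurable; overlapped windows shorten detection latency when a dangerous
rhythm starts mid-window.

Filtering is zero-phase (forward-backward) so QRS morphology is not
distorted; the implementation pads with odd reflection and initializes each
pass at its steady state, so a constant input maps to zero without start-up
transients. Each window is normalized to zero mean and unit *population*
variance after cutting: per-window unit variance is exactly what the
phase-plot binning and the beat-feature scales assume. Constant windows are
rejected as degenerate.

## Stage 1: image-based phase-plot features

For a segment $s_1,\dots,s_n$ two embeddings are built: $(s_i, s_{i+1})$
and $(s_i, s_{i+5})$; a lag of 5 samples (16.7 ms) unfolds disorganized
dynamics while lag 1 hugs the identity diagonal. Each embedding is
rasterized into a binary image on a $100 \times 100$ grid over
$[-3, 3]^2$ (unit-variance segments rarely exceed $\pm 3$; outliers clip to
edge bins). Consecutive trajectory points are **joined** when rasterizing,
as a plotted phase portrait would be: at 300 Hz a smooth trajectory sampled
pointwise is a chain of disconnected dots, and line structure only exists
once the trajectory is drawn. Point-occupancy rasterization remains
available (`connect = FALSE`).

The features:

* **F1, self-similarity**: $r_5 - r_1$, the difference of occupied-pixel
  fractions of the two images. Disorganized rhythms spread the lag-5
  embedding far more than the lag-1 embedding.
* **F2/F3, 45-degree lines**: the difference image is scanned along every
  main-diagonal direction; maximal runs of foreground pixels strictly
  longer than 20 pixels are counted (F2) and their lengths summed (F3).
* **F4, filled fraction**: 4-connected background regions of the
  difference image not reachable from the border (holes) are filled, and
  the foreground fraction is reported. Normalizing by the pixel count keeps
  F4 comparable across resolutions.

The difference image holds the pixels unique to the *lag-5* embedding
(`subtract_images(B5, B1)`). The lag-5 image is the larger set for every
rhythm class - the self-similarity index is positive throughout - so the
opposite clamped difference would be nearly empty and featureless; the
lag-1 image acts as a mask of the organized near-diagonal trajectory, and
what remains measures how far the unfolded dynamics depart from it. On
synthetic data this composition reproduces the expected ordering (VF well
above normal sinus rhythm on F2, F3 and F4) with line counts of the order
of tens and filled fractions of 0.1-0.2.

**F5** counts spectral bins whose amplitude strictly exceeds the mean of
the single-sided, maximum-normalized amplitude spectrum (2400-point FFT,
0.125 Hz resolution, rectangular window). Spiky rhythms with discrete QRS
trains push many harmonics above the mean; narrowband disorganized rhythms
concentrate power in few bins, so F5 falls for VF. The count spans the full
single-sided range by default, with a configurable upper cut.

**F6** is the Shannon entropy of a 16-bin amplitude histogram taken over
the segment's own range, normalized by $\log_2 16$ to $[0, 1]$. Histogram
entropy over the data range makes F6 invariant to affine amplitude
rescaling; the normalization matches the feature's expected sub-unity
range. Constant input yields 0 by convention (single occupied bin).

## Stage 2: RR-interval features

R peaks are detected with a Pan-Tompkins-style pipeline: first difference,
squaring, 150 ms moving-window integration, adaptive thresholding with
separate running signal/noise-peak estimates
($\mathrm{thr} = \mathrm{NPK} + 0.25(\mathrm{SPK} - \mathrm{NPK})$,
both updated with weight 0.125), a 200 ms refractory period, and
refinement of each trigger to the raw-signal maximum in a 150 ms look-back
window. Two triggers inside the refractory keep the larger raw peak, which
suppresses tall P/T triggers, and accepted peaks below 30% of the median
peak amplitude are discarded as edge or T-wave artifacts.

RR intervals pass a physiologic guard ($0.2$-$3$ s) and an ectopic
exclusion: intervals deviating more than 30% from the *window median* are
dropped. The reference is deliberately the global window median, not a
short running median - in bigeminy every other interval is ectopic and a
5-point running median locks onto the alternation itself, hiding exactly
the pattern the exclusion exists to remove. An 8 s window holds only 8-12
intervals, so the global and running medians agree in every other regime.

On the cleaned series three features are computed: normalized Shannon
entropy of the intervals (8 bins here - a window's worth of intervals
cannot populate 16), the turning point ratio (fraction of interior strict
local extrema; 2/3 expected for independent variation, with equal
neighbours counted as non-turning), and RMSSD divided by the mean interval
so that thresholds transfer across heart rates. Windows with fewer than 5
detected beats or fewer than 5 cleaned intervals are flagged unusable:
variability statistics over a handful of intervals are noise. In the
cascade, a peak-sufficient window whose AF features are uncomputable
(usually because ectopic exclusion removed much of the series) is treated
as non-AF and passed to the PVC stage - heavy ectopic exclusion is itself
evidence of beat-driven rather than fibrillatory irregularity.

## Stage 3: beat features

Beats are 200-sample windows (70 samples left of the R point, 129 right;
0.66 s at 300 Hz covers the full PQRST complex even for wide ectopic
beats). Windows crossing a segment boundary are skipped, not padded -
padding would distort the beat spectra.

* **LMMD**: the window's peak-to-valley amplitude (global extrema; for a
  centered beat these are the R and S waves).
* **MSA**: the maximum of the beat's raw single-sided amplitude spectrum.
  Raw, not maximum-normalized: normalizing would make the feature
  identically 1.
* **WSE**: energy entropy of a 4-level Daubechies-4 wavelet decomposition
  (symmetric boundary extension), $p_i = c_i^2 / \sum c_j^2$ over all
  approximation and detail coefficients, normalized by $\log_2$ of the
  coefficient count. Family and depth are configurable; db4 at 4 levels
  puts the QRS energy scale around 10-40 Hz.
* **Kurt**: population (non-excess) kurtosis, 3 for Gaussian amplitudes.
  Narrow tall normal beats are heavy-tailed (high kurtosis); wide ectopic
  complexes spread their energy and sit lower.

Kurtosis and WSE are amplitude-scale invariant; LMMD and MSA scale
linearly. Because each segment is normalized to unit variance, amplitude
features are *context dependent* - a normal beat inside a pure-NSR window
is numerically larger than a PVC inside an all-PVC (VT) window. The shape
features are what transfers across contexts, and the training-data design
(below) makes sure the classifier can rely on them.

## Classifiers and evaluation protocols

Two families are supported at every stage: a binary decision tree (Gini
impurity, depth effectively unlimited at 30, rpart's standard complexity
pruning) and a linear SVM with $C = 1$. Fully grown trees (complexity
penalty 0, minimum leaf 1) were rejected after they repeatedly produced
single-training-sample leaves whose spurious thresholds flipped
whole-segment episode labels on one noisy beat; the pruning defaults trade
a fraction of a percent of training fit for stable decision boundaries,
and the fully-grown configuration remains available through the `control`
argument. SVM features are standardized using training data only (the
standardization is part of the fitted model); trees are scale-equivariant
and fit raw features.

Two evaluation protocols are provided. *Unbalanced*: all samples are
randomly split in half into train/test, five times, unstratified;
degenerate single-class splits are re-drawn. *Balanced*: the majority
class is subsampled to the minority size B (five times), and each balanced
pool is split into B train / B test samples (five times), for 25 trials.
Results are reported as mean and standard deviation of accuracy,
sensitivity and specificity in percent. Balancing recovers sensitivity on
majority-negative data at some cost in specificity.

## The synthetic generator

The generator exists so that every stage can be built and tested without
external recordings; it emulates the *statistical structure each stage
discriminates on*, not clinical morphology.

* **Normal sinus rhythm**: a PQRST template of Gaussian bumps (P 0.12 mV
  at -170 ms, Q -0.10, R 1.0 with 12 ms width, S -0.25, T 0.30 at
  +220 ms), heart rate configurable (default 70 bpm), uniform RR jitter of
  ±2%, and ±10% beat-to-beat amplitude modulation emulating respiratory
  modulation. The amplitude modulation matters: without it, feature
  clusters are unrealistically tight and a decision tree can thread
  hair-width gaps between rhythm contexts that no real recording would
  leave open.
* **PVC beats**: no P wave, QRS width doubled, R/S amplitudes scaled for a
  1.6-fold peak-to-valley excursion, discordant (inverted, wider) T. PVCs
  arrive early at 0.65 RR - the clinically typical 60-80% coupling
  interval - followed by a full compensatory pause (1.35 RR). The coupling
  ratio is chosen so that generated premature beats are actually premature
  in the sense the 30% ectopic-exclusion band expects; a near-threshold
  prematurity would generate "premature" beats that no exclusion rule
  could remove. The six pattern rhythms schedule PVCs as repeating
  bigeminy (10), trigeminy (100), quadrigeminy (1000), couplet (110),
  triplet (1110) and VT (all 1) templates.
* **AF**: the sinus template without P waves and RR intervals drawn iid
  from U(0.4, 1.2) s - irregularly irregular by construction.
* **VF**: no beats at all; the sum of three oscillators with random
  frequencies in 3-7 Hz, random amplitudes, and random-walk phase noise,
  standing in for the disorganized, QRS-free fibrillatory waveform.
* All rhythms receive additive white Gaussian noise (default 0.02 mV
  against a 1 mV R peak, a clean-recording noise floor).

Truth labels are exact by construction, so downstream metrics need no
annotation files. Everything is deterministic given a seed.

`synth_dataset()` builds balanced labelled feature tables through the real
pipeline. Negative classes mirror the populations each stage screens in
the cascade: stage-1 non-VF and stage-2 non-AF pools are half NSR and half
other rhythms (AF and the PVC patterns for stage 1; the PVC patterns for
stage 2). Stage-3 beats are harvested in equal shares per class from a
rotation of NSR, bigeminy, trigeminy, couplet and VT recordings, because
per-segment normalization shifts amplitude features with rhythm content
and the classifier must see every context. Beats whose 200-sample window
overlaps an opposite-class neighbour's QRS-T support (within 0.55 s) are
excluded from *training only* - at fast rates a premature PVC bleeds into
the preceding normal beat's window, and such transitional windows carry
both morphologies and no clean label. Heart rate is drawn per record from
U(55, 95) bpm.

What the generator does **not** emulate: real QRS morphology variability
between subjects and leads, bundle-branch blocks and other wide-QRS
non-PVC beats, paced rhythms, baseline wander beyond the filter band,
motion artifacts, and the noisy transitions between rhythms in real
recordings. Passing the synthetic checks therefore demonstrates that the
pipeline is implemented correctly and that the features separate the
intended structure - not that the trained models transfer to clinical
recordings; for that, the classifiers must be retrained on annotated data
read through `read_ecg()`.

## Episode grammar

Per segment, the longest run of consecutive PVC labels (NCPVC) decides
first: 0 is NSR, runs of 2 and 3 are couplet and triplet, 4 or more is VT.
Isolated PVCs (NCPVC = 1) are classified by the spacing of PVC positions:
a modal spacing of 2, 3 or 4 beats gives bigeminy, trigeminy or
quadrigeminy. Tied modal spacings resolve to the smaller spacing (bigeminy
before trigeminy before quadrigeminy); a single isolated PVC, or spacings
outside 2-4, fall back to NSR - the canonical decision table starts at
NCPVC 0 and 2 and leaves singletons unmapped, and flagging a lone ectopic
beat as an arrhythmic episode would be clinically wrong.

## Numerical conventions and degenerate inputs

* Phase-plot binning is half-open with edge clipping; the mirror symmetry
  of the images under amplitude sign flip is exact up to rasterization
  tie-breaks at cell boundaries.
* Entropy sums skip zero-probability bins; constant signals have zero
  entropy by convention.
* Spectra of all-zero signals, normalization of constant windows, and
  kurtosis of constant beats raise classed degenerate-input errors rather
  than returning NaN.
* Classifier protocols re-draw degenerate single-class splits instead of
  failing a run; the draw is capped.
* Evaluation metrics with an empty denominator (no positives in a test
  fold) are NA and excluded from protocol averages.

## Problem sizes

The test-suite checks stage separability with balanced decision-tree
protocols at 200 samples per class, feature directionality over 10
generator seeds, oracle equivalence over 200 random inputs per operation,
and the full cascade over several independent 128 s recordings containing
all seven episode classes in 16 s blocks. These sizes give stable
statistics for a desk-scale synthetic study; larger studies only require
turning the same knobs.

## Known limitations

* The cascade's episode accuracy is bounded by per-beat PVC accuracy; a
  single beat error can change a segment's episode code, which is why
  classifier robustness (pruning, training-context coverage) matters more
  here than raw training fit.
* AF detection within 8 s windows rests on 8-12 RR intervals; entropy and
  TPR are coarse at that length, and RMSSD carries most of the signal.
* The VF stage's image features depend on the rasterization convention
  and grid resolution (both configurable); values are comparable only
  within one convention.
* WFDB support covers the common format 16/212 single-signal layouts of
  the PhysioNet arrhythmia databases, read-only.
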