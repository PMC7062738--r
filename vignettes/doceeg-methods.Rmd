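---
title: "EEG markers of consciousness: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG markers of consciousness: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doceeg)
```

# Scope

`doceeg` implements a complete electrophysiological pipeline for quantifying
conscious state in disorders-of-consciousness (DoC) patients from
high-density EEG, built around the question of whether a behavioral response
to prefrontal transcranial direct-current stimulation (tDCS) is paralleled by
objective EEG changes. It covers automated preprocessing, seventeen
resting-state markers, a multivariate (SVM) predictor of minimally conscious
state, oddball ERP contrasts with temporal-generalization decoding, two-step
cluster-based permutation statistics over four data geometries, and a
voxelwise electric-field correlation test. Because no patient data are
distributed, the package ships a seeded synthetic-cohort generator that
emulates the responder/non-responder (R+/R−) structure of such a study; all
calibration and recovery claims in the test suite are statements about that
generator, not about patients.

# Preprocessing

Continuous recordings are band-pass filtered with a 6th-order Butterworth
high-pass at 0.5 Hz, an 8th-order Butterworth low-pass at 45 Hz and
band-stop notches at 50 and 100 Hz; task data additionally get a 20-Hz
low-pass before ERP analysis. All filters are applied forward–backward
(zero-phase): ERP latency claims require no phase distortion, and the quoted
orders are interpreted as the design order of each pass. Channels are
demeaned before filtering to suppress edge transients.

Resting data are cut into 800-ms epochs separated by a uniform random
550–850-ms jitter. Since the placement is random, the segmentation is
repeated (100 iterations at full scale) and marker values averaged over
iterations; tests and desk-scale analyses use 1–5 iterations, which changes
only the Monte-Carlo error of that average. Task epochs span −800 to
+740 ms around the onset of the fifth sound of each tone quintet (half-open
windows, 0-based sample indexing) and are baseline-corrected by their
pre-onset mean.

Artifact rejection is a fixed-order cascade: (a) channels exceeding 150 µV
peak-to-peak in more than 50% of epochs; (b) channels whose mean variance is
an outlier (z > 4 across channels), applied twice with recomputation;
(c) epochs exceeding 150 µV peak-to-peak in more than 10% of retained
channels; (d) the variance rule again, twice, on 25-Hz high-passed data.
The high-pass in (d) is a 4th-order zero-phase Butterworth, applied
epoch-wise. Retained channels are re-referenced to their average; rejected
channels are interpolated by inverse-distance weighting over layout
neighbors — spherical splines would add realism on a true geodesic net, but
inverse-distance weighting is layout-agnostic and exactly testable (it
reproduces a uniform field identically). A recording passes quality control
only if at least 75% of channels and 30% of epochs survive; failed
recordings are excluded from the affected modality only.

# Resting-state markers

Seventeen markers are computed per epoch and channel, then summarized per
channel with the 80% trimmed mean across epochs (drop the lowest and highest
10%):

* **Spectral (14).** Welch PSD with 512-ms Hann-tapered segments and 400-ms
  overlap; raw and normalized band powers in δ (1–4 Hz), θ (4–8), α (8–12),
  β (12–30), γ (30–45 Hz), the normalization dividing by the five-band
  total so normalized powers sum to one. Spectral entropy is the Shannon
  entropy of the 1–45-Hz PSD normalized by log of the bin count, so it lies
  in [0, 1]; the median spectral frequency and 90/95% spectral edges invert
  the cumulative power distribution treating each bin's mass as uniform
  over its width — the only interpolation convention under which a
  single-line spectrum returns exactly its bin frequency while a flat
  spectrum returns the band midpoint.
* **Complexity (2).** A Kolmogorov–Chaitin proxy: each epoch × channel
  signal is quantized to 32 equal-width amplitude bins, serialized to one
  byte per sample and deflate-compressed; complexity is the compressed/raw
  size ratio. With 32 levels the incompressibility ceiling is about
  5/8 plus container overhead, so values are comparable within this
  implementation only. Permutation entropy uses ordinal patterns of k = 3
  samples spaced τ apart (ties broken by order of occurrence), normalized
  by log 6; the default τ = 32 ms tunes it to the theta–alpha range.
* **Connectivity (1).** Weighted symbolic mutual information (wSMI) between
  all channel pairs: the joint distribution of simultaneous ordinal
  patterns, with weight zero for identical and sign-opposite pattern pairs
  (discounting common-source and volume-conduction coupling) and one
  otherwise. τ = 32 ms targets 4–10 Hz; τ = 64 ms and τ = 16 ms map the
  same k = 3 sensitivity rule onto the delta–theta (2–5 Hz) and alpha–beta
  (8–20 Hz) ranges. τ must be an integer number of samples (32 ms at
  250 Hz = 8 samples); non-integer products are rejected rather than
  rounded. The 3-D pair structure is reduced to a topography by the median
  wSMI of each channel with all others (its connection "degree").

Small-sample wSMI estimates carry a positive bias (roughly
(cells−1)/2N nats); it cancels in the within-subject post-minus-pre
contrasts the pipeline tests, which is why those, not raw values, are the
analysis currency.

# Multivariate prediction of conscious state

Each subject/session is summarized by 68 features: all 17 markers crossed
with {trimmed mean, SD} over epochs × {mean, SD} over channels. A linear
SVM predicts MCS vs VS/UWS from a labeled reference cohort with 20%
univariate-F feature selection (14 of 68, selection fitted inside training
folds only), the penalty C chosen by nested 5-fold stratified
cross-validation over {1e-6 … 1e-1} (the printed grid's duplicated
exponents deduplicated), and Platt scaling for probabilities. When inner-CV
AUCs tie across C — routine on separable synthetic data, since AUC is
scale-invariant — the tie breaks toward the *largest* C: collapsing to the
smallest would shrink the margin to numerical zero and flatten the Platt
sigmoid to a constant. The tDCS effect measure is the post-minus-pre
difference in the predicted MCS probability, analysed with an
aligned-rank-transform (ART) mixed ANOVA (response group between subjects,
session within), which provides a valid nonparametric interaction test
where plain rank transformation does not.

# Oddball ERPs and temporal generalization

Condition ERPs are 80% trimmed means across trials. The group contrast is
the double difference [Deviant − Standard]post − [Deviant − Standard]pre,
compared between R+ and R− over channel × time elements. Decoding trains a
linear SVM on the channel voltages at each time point to separate deviant
from standard trials and tests it at every other time point (AUC of the
decision values, averaged over repeated stratified 5-fold CV). Per-timepoint
features are standardized by the training fold's statistics; the
hyperplane's sign is oriented on the training data so positive scores mean
"deviant". A sustained square of above-chance AUC off the diagonal indicates
metastable activity, the late (~300–600 ms) signature of conscious access;
group statistics consume per-subject after-minus-before AUC matrices.

# Cluster-based permutation statistics

All multi-element contrasts use the same two-step engine. First step: an
elementwise statistic — Welch t for marker topographies and ERPs,
Mann-Whitney z for decoding AUCs; dependent t / signed-rank z in paired
mode — thresholded two-sided at p = 0.05, with positive and negative
clusters formed separately (both signed effects are of interest).
Suprathreshold neighbors are clustered under the geometry's adjacency:
layout neighbors for channels; for channel pairs, two pairs are neighbors
when they share an electrode and the non-shared electrodes are layout
neighbors, or when one cross-assignment maps both endpoints onto neighbors
(the pair geometry needs *some* adjacency rule and none is standard; this
one reduces to the intuitive rule on rings and grids); same channel at
consecutive samples plus neighbor channels at the same sample for
channel × time; a 4-neighborhood lattice for decoding matrices. Cluster
mass is the sum of member statistics, and the p-value compares each mass to
the permutation distribution of the *maximum* cluster mass over the whole
element set (max-statistic control of the family-wise error). Group labels
are permuted unpaired; condition assignments are sign-flipped within
subject in paired mode. With few subjects the test enumerates all
relabelings exactly instead of sampling. Effect sizes are Hedges' g (pooled
SD, small-sample correction J = 1 − 3/(4N − 9)) with 10,000-iteration
bootstrap CIs, and r = z/√N for rank tests.

# Electric-field correlation

Per-subject field-magnitude volumes (consumed as arrays; tissue
segmentation and current-flow modeling are out of scope) are masked to
voxels whose across-subject mean exceeds 0.5 V/m (1 V/m supported), then
correlated voxelwise (Pearson) with the per-subject change in MCS
prediction. Signed suprathreshold masks use the analytic two-sided p = 0.01
critical r for the actual N by default — for N = 47 that is ≈ 0.372; a
literal cutoff (e.g. the 0.327 sometimes quoted for that design, which
matches neither the two-sided nor the one-sided critical value) can be
supplied explicitly. The overall strength statistic is the mean r inside
each signed mask, tested by shuffling outcome labels; the null *re-derives
the signed masks per permutation*, because freezing the observed,
data-selected masks would double-dip and is anticonservative. Permutations
with empty masks contribute the least extreme value (zero).

# The synthetic generator

Signals are pink (1/f) noise plus five jittered-phase narrowband sinusoids
(δ–γ; planted power is analytically amplitude²/2, anchoring calibration),
white sensor noise, optional rectangular ≥150-µV transients and dead
channels to exercise the rejection thresholds exactly. Cross-channel
coupling adds a shared band-limited (4–10 Hz) latent signal to designated
channel pairs at a 40-ms lag — band-limited *noise* rather than a sinusoid,
because a shared pure tone concentrates the ordinal-symbol distribution
into identical/opposite patterns that wSMI's weights deliberately discount.
By default the coupled set is a triangle of channel 1 and two of its
neighbors, so planted coupling forms a connected cluster in the pair graph.
Oddball recordings place five-tone trials with an exact 20% deviant
fraction; deviants carry an anterior-weighted biphasic MMN-like deflection
(100–200 ms) and a posterior-weighted sustained P3-like component
(300–600 ms). Neither topography is spatially uniform — a uniform component
would be annihilated by average referencing. Responders' post-stimulation
sessions receive the planted theta/alpha power, coupling and P3 increments;
CRS-R totals are drawn consistently with the response label (strict
increase for R+, stability for R−).

What the generator does *not* emulate: realistic head-volume conduction and
spatial covariance (the study's net is emulated only as a geometric layout
with a free smoothness choice), pathological EEG morphologies, eye/muscle
artifact structure, or CRS-R item-level behavior. Passing recovery tests
therefore demonstrates that the *pipeline* detects the planted effects it
is designed for, not that it would perform identically on patients.

# Desk-scale configurations

Calibration and recovery suites run at a reduced scale chosen to keep the
statistics honest while staying tractable: cohorts of 6 R+ and 6 R−
subjects, 12 channels, 20-s resting recordings, 80 oddball trials, 6-µV
pink noise, one epoching iteration, 200 permutations per cluster test, time
decimation 10 (ERP) and 20 (decoding), 3 decoding CV repetitions; the
full-scale defaults (12/48 subjects, 32 channels, 95-s rest, 150 trials,
100 iterations, 10,000 permutations) remain the package defaults. Strong
planted effects are +3 µV theta and alpha amplitude, +7 µV coupling and
+8 µV P3. Null calibrations use 200 seeds; family-wise error is checked
against [0.02, 0.09] at α = 0.05, the two-sided binomial band around the
nominal rate at that seed count.

# Numerical choices and degenerate inputs

Half-open epoch windows with 0-based event samples; peak-to-peak computed
over the full epoch window; variance z-scores use the mean over epochs of
per-epoch sample variance, standardized across channels. Constant channels
have zero wSMI by construction (their single pattern carries zero weight);
zero-variance voxels correlate as 0 and flag the run; a constant outcome
flags the whole correlation map; zero total spectral power raises an error
rather than returning markers. FFT-based noise synthesis pads to highly
composite lengths (mixed-radix FFTs degrade to quadratic cost at large
prime lengths). Welch tapering uses Hann, and spectral entropy is
normalized by log(bin count) — neither is dictated by the upstream
literature, both are stated here as package conventions.

# Known limitations

Kolmogorov complexity values depend on the exact quantization and
compressor and are not comparable across implementations. The pair-graph
adjacency rule is a package convention. The ART ANOVA is implemented for
the 2 × 2 mixed design only. Decoding uses a fixed SVM penalty (C = 1) per
timepoint; per-timepoint hyperparameter search would be disproportionate at
these trial counts. EDF export is not provided; recordings and results
serialize to plain CSV/JSON and NIfTI for volumes.
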