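# doceeg

EEG markers of consciousness for disorders-of-consciousness (DoC) research.

Severely brain-injured patients may remain in a vegetative state /
unresponsive wakefulness syndrome (VS/UWS) or a minimally conscious state
(MCS). Behavioral scoring with the Coma Recovery Scale-Revised (CRS-R,
0-23) is the clinical gold standard, but EEG provides objective,
quantitative signatures of conscious state — theta-alpha spectral power,
signal complexity, long-range connectivity — and of conscious access to
stimuli (the late P300 to auditory novelty). `doceeg` implements the full
analysis pipeline used to test whether a behavioral response to prefrontal
tDCS (an increase in CRS-R total: responders, R+) is paralleled by changes
in these EEG signatures, end to end:

* **Preprocessing** — zero-phase Butterworth filtering (0.5-45 Hz band,
  50/100 Hz notches, 20 Hz for ERPs), jittered 800-ms resting epochs, a
  hierarchical artifact-rejection cascade (150 µV peak-to-peak and
  variance-outlier rules), average reference, neighbor interpolation, and
  a 75%-channels / 30%-epochs quality gate.
* **Seventeen resting-state markers** — raw/normalized band powers
  (δ 1-4, θ 4-8, α 8-12, β 12-30, γ 30-45 Hz; Welch, 512-ms Hann segments,
  400-ms overlap), spectral entropy and edge frequencies, Lempel-Ziv
  (Kolmogorov) compression complexity, permutation entropy, and weighted
  symbolic mutual information

  wSMI(i,j) = Σ w(s,s') p(s,s') log[ p(s,s') / (p(s) p(s')) ],

  over k = 3 ordinal patterns at τ = 32 ms (4-10 Hz), with weights zeroing
  identical and sign-opposite pattern pairs; summarized per channel by the
  80% trimmed mean across epochs and, for wSMI, by the per-channel median
  degree.
* **Multivariate prediction of conscious state** — 68 features
  (17 markers × {trimmed mean, SD over epochs} × {mean, SD over channels}),
  20% univariate-F feature selection, linear SVM with nested-CV choice of
  C ∈ {1e-6 … 1e-1} and Platt-scaled probabilities; the tDCS effect is the
  post-minus-pre change in P(MCS), tested with an aligned-rank-transform
  mixed ANOVA.
* **Oddball ERPs and temporal-generalization decoding** — trimmed-mean
  ERPs on [-800, +740) ms epochs around the fifth tone, the double
  difference [Deviant − Standard]post − [Deviant − Standard]pre, and
  per-timepoint linear-SVM decoding tested across all timepoints (AUC
  train × test matrices; a late sustained "square" marks the P3b-like
  signature of conscious access).
* **Two-step cluster-based permutation statistics** over four geometries
  (channels, electrode pairs, channel × time, decoding matrices): Welch t
  or Mann-Whitney z first step at p < 0.05, cluster mass, max-statistic
  permutation control (exact enumeration at small N), Hedges' g and
  r = z/√N effect sizes with bootstrap CIs, plus a continuity-corrected
  χ² for response-rate comparisons.
* **Electric-field correlation** — voxelwise Pearson correlation of
  modeled tDCS field magnitudes (mean field > 0.5 V/m mask) with the EEG
  prediction change, and a label-shuffle test on the mean correlation in
  the signed suprathreshold masks, re-deriving the masks per permutation.
* **A seeded synthetic-cohort generator** (layouts, resting/task EEG with
  planted group × session effects, a VS/MCS reference database, 3-D field
  maps) that makes every pipeline claim testable without patient data.

## Worked example

Simulate a small responder/non-responder cohort with planted theta-alpha
and coupling increases in responders, and analyse one subject:

```r
library(doceeg)

spec <- cohort_spec(n_rplus = 3, n_rminus = 3, n_channels = 12,
                    rest_duration = 20, noise_sd = 6,
                    effect_theta = 3, effect_alpha = 3, effect_coupling = 7,
                    seed = 42)
cohort <- simulate_cohort(spec, recordings = "rest")
cohort[1:4, 1:5]
#> # A tibble: 4 × 5
#>   subject_id group diagnosis crsr_pre crsr_post
#>   <chr>      <chr> <chr>        <int>     <int>
#> 1 S001       R+    MCS              9        12
#> 2 S002       R+    MCS             11        12
#> 3 S003       R+    VS/UWS           7         9
#> 4 S004       R-    MCS              9         9

rest <- rest_session_analysis(cohort$rest_pre[[1]], seed = 1, n_iterations = 2)
rest$passed
#> [1] TRUE
```

`rest$topography` holds one value per channel for each of the 17 markers
(here, channel 1's delta power is ~17 µV²; responders' *post* recordings
would show elevated θ/α values), and `rest$features` is the 68-feature
summary fed to the classifier. The response-rate comparison against an
independent trial cohort uses the continuity-corrected χ²:

```r
compare_proportions(12, 60, 15, 55)
#> # A tibble: 1 × 5
#>   statistic    df p_value prop1 prop2
#>       <dbl> <int>   <dbl> <dbl> <dbl>
#> 1     0.488     1   0.485   0.2 0.273
```

i.e. a 20% response rate is statistically indistinguishable from the 27%
reference rate (χ²(1) = 0.4885, p = 0.485). A full study — marker,
connectivity, ERP and decoding contrasts plus the MVPA interaction — runs
with `run_study()` (or `run_desk_study()` at the reduced calibration
scale), returning a `study_report` whose components have `tidy()`,
`glance()` and `autoplot()` methods.

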