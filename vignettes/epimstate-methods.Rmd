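---
title: "Methods: microstate, complexity and spectral characterization of preictal EEG"
author: "epimstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstate, complexity and spectral characterization of preictal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimstate)
```

## The problem

Short-term seizure prediction reduces to a two-class problem: distinguishing
*interictal* EEG (between seizures) from *preictal* EEG (the stretch
immediately preceding a seizure). `epimstate` characterizes 3-second scalp
EEG epochs from three complementary perspectives and feeds the fused feature
set to a classifier:

1. **Microstate temporal dynamics** — scalp topography is quasi-stable for
   tens of milliseconds at a time; the succession of these "microstates"
   summarizes large-scale network dynamics. Per class we report mean segment
   duration (ms), time coverage (fraction) and occurrence (segments/s).
2. **Nonlinear complexity** — Lempel-Ziv complexity (LZC) of the binarized
   voltage signal under three thresholds, permutation entropy (PermEn) of
   the voltage signal, and their microstate-sequence counterparts mLZC and
   mPermEn, which quantify the repetitiveness and randomness of the
   *cognitive state sequence* rather than of raw voltages.
3. **Spectral power** — absolute power in δ `[1,4)`, θ `[4,8)`, α `[8,12)`
   and β `[12,30)` Hz plus the θ/β ratio (TBR).

That yields 12 + 6 + 5 = 23 features per epoch.

## Preprocessing

`preprocessEEG()` applies the standard chain: reduction to the 19 standard
10–20 channels, resampling to 250 Hz, a 48–52 Hz zero-phase band-stop
(power-line), a 1–40 Hz zero-phase band-pass, replacement of channels whose
absolute amplitude exceeds 150 µV on more than 20% of samples by
spherical-spline interpolation from the remaining electrodes, and an average
reference.

Numerical choices worth stating:

* **Filters** are Hamming-windowed-sinc FIR with a 1 Hz transition band,
  applied forward-backward (zero phase). A literal "second-order FIR" cannot
  realize these bands, so the order is set by the transition bandwidth
  (≈ 3.3·fs / 1 Hz taps) and capped on short inputs. Band-stop is applied
  before band-pass; the order is immaterial for LTI filters but fixed for
  reproducibility.
* **Bad channels are detected before filtering**, because filtering
  attenuates the very excursions the 150 µV rule is meant to catch;
  interpolation then uses the *filtered* good channels, and the average
  reference is applied last so each sample's channel mean is exactly zero.
* Artifact handling is purely amplitude-based. Automatic ICA component
  classification needs a trained component classifier and is out of scope;
  recordings cleaned by an external ICA step can be fed in unchanged.
* Sample indexing is 0-based with half-open `[start, end)` intervals;
  `segmentEpochs()` cuts non-overlapping epochs per annotated interval and
  discards trailing partial windows. Where preictal annotations are placed
  relative to seizure onset is the caller's choice; the package takes the
  annotation intervals at face value (by convention the preictal window ends
  at onset).

## Microstate analysis

The per-sample **global field power** is the spatial standard deviation
across electrodes; topographies at GFP peaks (strict local maxima) are the
clustering input because they have the best topographic signal-to-noise.

**T-AAHC clustering.** Starting from singleton clusters, the cluster
contributing least to the global explained variance (GEV, weighted by
squared GFP) is dissolved ("atomized") and each freed map is reassigned to
the cluster with the highest absolute spatial correlation; this repeats
until the target class count remains. Two choices make the procedure
polarity-free, as microstate analysis requires: similarity is |Pearson r|
across channels of average-referenced maps, and the cluster centroid is the
dominant eigenvector of the member outer-product sum rather than the mean.
Ties (equal GEV contributions, equal |r|) resolve to the lowest index, so
results are deterministic. One agglomeration pass yields the fits for every
candidate k.

**Choosing k.** The class count is selected over k = 3..8 by the median rank
of three normalized criteria: the GEV elbow (negative second difference of
the GEV curve), the polarity-invariant mean silhouette with distance
1 − |r|, and a Krzanowski–Lai-style ratio of successive dispersion
differences. One extra k on each side of the range is fitted internally so
the elbow and the ratio are defined at the boundaries; ties favour the
higher silhouette, then the smaller k. This is a consensus recipe assembled
here (the criteria are documented and swappable); it recovers planted class
counts of 3–5 in the test battery. Group-level maps come from pooling
individual optimal templates and re-clustering at a fixed k = 4, the
canonical resting-state class count.

**Backfitting** labels *every* sample (not only GFP peaks) with the template
of highest |r|; samples below the 0.5 correlation threshold, or with zero
spatial variance, stay unassigned. The epoch is first normalized by its
median GFP at peaks — a scalp-conductivity normalization that does not
affect labels (correlation is scale-free) but keeps amplitudes comparable
across subjects.

**Smoothing.** Segments shorter than 32 ms are halved: the first half (the
larger half for odd lengths, e.g. a 5-sample run splits 3/2) joins the
preceding segment, the second half the following one; boundary runs join
their single neighbour wholly. Unassigned stretches count as segments —
short unassigned blips are smoothed away — but never absorb samples from
neighbours, so the correlation threshold keeps its meaning. The rule is
applied left-to-right until no removable short segment remains; each
application reduces the run count, so termination is guaranteed.

With the parameter definitions used here, occurrence × mean duration =
coverage × 1000 ms holds *exactly* per class, and coverages plus the
unassigned fraction sum to one; both identities are asserted in the tests.

## Complexity features

**LZ76.** The pattern count C_w is the number of words in the exhaustive
left-to-right parsing (Kaspar–Schuster formulation, compiled code); the
trailing incomplete word counts as one word, and an independent pure-R
substring parser in the test suite agrees with the compiled counter on
*every* binary sequence up to length 12 and every quaternary sequence of
length 8. Normalization is `C_w / (N / log_b N)`. For the EEG-based LZC the
alphabet is binary (thresholds: mean, median, mid-range) and b = 2. For the
microstate-based mLZC over the 4-letter alphabet the default is b = 4 — a
binary logarithm under a quaternary alphabet would not normalize the random
baseline to ≈ 1 — with `logBase = 2` available for the literal binary form.

**PermEn** uses ordinal patterns of the delay embedding (default m = 4,
τ = 1 for EEG; both configurable — the recurrence-based selection sometimes
used to tune them is not reproducible from published descriptions), stable
tie-breaking (earlier index first), and normalization by ln(m!).

**mPermEn** first removes adjacent repeats of the label sequence (a dwell
period would otherwise swamp the pattern distribution), then embeds with m
equal to the class count, maps each embedded tuple to its row in the m^m × m
state-pattern matrix `a_jh = ceil(j / m^(m−h)) mod m` (0 → m), and takes the
Shannon entropy of the index distribution. The default normalization is
ln(m^m), the size of the state-pattern space, which guarantees a value in
[0, 1]; dividing by ln(m!) (offered as `normalization = "factorial"`) can
exceed 1 because the state-pattern space is larger than the ordinal one.
Post-dedup, only 4·3³ = 108 of the 256 tuples are reachable, so the
uniform-transition ceiling is ln(108)/ln(256) ≈ 0.844 — a value the test
suite confirms by simulation.

EEG-based features are computed per channel and averaged over the 19
channels, matching how the spectral statistics are aggregated; the paper
trail for per-channel versus channel-averaged classifier input is ambiguous,
and averaging keeps the feature count fixed.

## Spectral features

One-sided periodogram over the full epoch (rectangular window; a Welch
option with 1-s Hamming segments and 50% overlap is exposed as
`method = "welch"`), scaled so the summed bin power equals the mean squared
amplitude — band powers are then in µV² and satisfy Parseval within 1% for
band-limited input. Band edges are half-open so each bin is counted exactly
once. TBR is θ power over β power; a zero β power raises an error rather
than returning an infinity.

## Prediction protocol

Per repetition: a stratified 10% test split; z-scoring with training-set
statistics only; a 5-fold stratified CV grid search over the RBF-SVM
hyperparameters C ∈ 2^{−3..7}, γ ∈ 2^{−7..3} (powers of two, step 2²)
scored by CV accuracy; a refit on the full 90%; one evaluation on the
held-out 10%. Ten repetitions with seeds 0..9 by default; reports are
bitwise reproducible given the seeds. A canary test (a feature equal to the
label on the predetermined test rows and noise elsewhere) asserts that
nothing about the held-out rows leaks into normalization or tuning.

Metrics: accuracy, sensitivity (preictal = positive), specificity and
Cohen's kappa in percent; AUC from the SVM decision values; and FPR/h — the
count of interictal epochs wrongly flagged, divided by the hours of
interictal data evaluated. Epoch-level counting is the default because the
mapping from epochs to "predicted seizure events" is not uniquely defined;
`eventMergedFPR = TRUE` merges consecutive false-positive epochs into single
alarms for the event-style reading. Note that with small held-out sets a
single false alarm translates into a large per-hour figure; per-hour rates
comparable to long-term clinical monitoring require correspondingly long
interictal test data.

## Statistics

Each feature is compared between states with a Shapiro–Wilk-routed paired
test: paired t when the *differences* look normal, Wilcoxon signed-rank
(exact where the sample permits) otherwise. Routing on differences rather
than on each sample separately is deliberate — the differences are the
object the paired tests make assumptions about. Effect size is paired
Cohen's d = mean(diff)/sd(diff), and the significance flag uses the dual
criterion p < α **and** |d| > 0.3, with α a plain configuration value
(5·10⁻⁴ for microstate/nonlinear features, 0.05 for spectral ones, following
the convention of power-adjusting α at large epoch counts; the power
analysis behind a specific α is left to external tools). Kruskal–Wallis
tests compare per-subject map statistics between groups; the exact Wilcoxon
p-values are validated against a full 2^n sign-enumeration oracle in the
tests.

## The synthetic generator

`syntheticSpec()`/`generateDataset()` define the validation conditions:

* k orthogonal zero-mean scalp templates (smooth random patterns built from
  low-order polynomial fields on the idealized 10–20 sphere, then
  orthonormalized — pairwise |r| = 0, guaranteeing identifiability);
* a semi-Markov state sequence: transitions from a uniform off-diagonal
  matrix, dwell times geometric by default (memoryless, analytic mean
  control; default mean 80 ms, the typical resting microstate scale) or
  lognormal (`dwellDistribution = "lognormal"`, sdlog 0.25) when a dwell
  distribution with negligible sub-32 ms mass is needed;
* a global 10 Hz sinusoidal carrier (its rectified waveform produces GFP
  peaks at 20/s, and its sign changes exercise polarity invariance),
  scaled to 30 µV;
* background oscillations at 2, 6 and 22 Hz (8, 5, 3 µV) with fixed random
  topographies that are *identical across the two classes* — derived from
  the spec seed, not the flowing RNG — so that only the planted amplitude
  effects, never a topography difference, separate the classes;
* white noise scaled (after average-referencing) so the empirical
  template-signal-to-noise ratio equals `snrDb` exactly (default 10 dB, a
  realistic scalp regime; recovery experiments use 20 dB).

Preictal class effects mirror the directions reported for epilepsy: class-A
dwell × 1.5 and class-C dwell × 1/1.5 (duration/coverage up for A, down for
C), δ background × 0.6 and θ × 1.3, and a transition-regularity blend of 0.5
toward a deterministic cycle (lowering mLZC/mPermEn — reduced preictal
complexity). Magnitudes are free parameters chosen once as a "large effect"
condition; `labelNoiseRate` can corrupt epoch labels.

**What the generator does not emulate:** 1/f background spectra, true
artifact morphologies (blinks, EMG), non-stationarity across a recording,
volume-conduction-correct forward fields, or seizure waveforms. Passing the
recovery and separation tests therefore demonstrates the correctness of the
algorithms under the stated statistical structure, not clinical performance
on real recordings.

**Problem sizes.** The validation battery uses 5 minutes of 250 Hz synthetic
EEG (≤ 1000 GFP-peak maps) for template/dwell recovery, 60 s per run for the
30 class-count-selection runs, and 100 epochs per class for the end-to-end
classifier; these sizes give stable estimates for every tested property
while keeping a full run of suite plus acceptance script in the
single-digit-minutes range on one core.

The dwell-recovery experiment uses the lognormal dwell option: under
geometric dwell at an 80 ms mean, about 30% of segments fall below the
32 ms smoothing floor, so the *smoothed* mean duration is, by construction,
not an estimator of the planted mean — with a tight dwell distribution it
is, and the pipeline recovers it to within 10%.

## Known limitations

* EDF writing quantizes to 16 bits over the per-channel range and pads
  recordings to whole 1-s records.
* The meta-criterion is a consensus construction; other published recipes
  combine more criteria and may choose differently near ties.
* mLZC/mPermEn require an assigned label for the samples they consume;
  `extractFeatures()` drops unassigned samples, which shortens the symbol
  sequence at low SNR.
* FPR/h from short held-out sets is a coarse-grained quantity (see above).
* The SVM grid is the conventional powers-of-two lattice; no model beyond
  the RBF SVM is provided by design.

## A minimal worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(seed = 1)
ds <- generateDataset(spec, nEpochsPerClass = 60)
inter <- which(epochLabels(ds$epochs) == "interictal")
X <- do.call(cbind, lapply(inter, function(i) epochData(ds$epochs, i)))
g <- computeGFP(X)
pk <- findGFPPeaks(g)
tpl <- taahcCluster(t(X[, pk]), k = 4, gfp = g[pk], level = "group")
feats <- extractFeatures(ds$epochs, tpl)
report <- runPrediction(assembleFeatures(feats, "fusion"))
report
compareFeatureTable(feats, alpha = 5e-4)
```
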