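# epimstate

Multi-perspective characterization of interictal vs. preictal scalp EEG for
seizure prediction: **microstate temporal dynamics**, **nonlinear
complexity** of both the voltage signal and the microstate sequence, and
**spectral band power**, fused into a repeated cross-validated SVM
classifier. Written for EEG researchers who want the full pipeline — EDF in,
per-epoch features and prediction metrics out — validated end-to-end on
synthetic recordings with planted ground truth.

## The methods in brief

**Microstates.** The global field power of a sample `x` over `n` channels,

    GFP(x) = sqrt( sum_i (V_i − V̄)² / n ),

marks, at its local maxima, the topographies used for clustering. T-AAHC
(topographic atomize & agglomerate hierarchical clustering) repeatedly
dissolves the cluster contributing least global explained variance and
reassigns its maps by highest `|r|` (the polarity-invariant spatial
correlation); the class count k is chosen over 3..8 by a median-rank
meta-criterion (GEV elbow, polarity-invariant silhouette, Krzanowski–Lai
ratio). Backfitting labels every sample with the best-correlated template
(minimum `|r|` 0.5, segments under 32 ms smoothed away), yielding per-class
mean duration, coverage and occurrence.

**Complexity.** Lempel-Ziv complexity `LZC = C_w / (N / log_b N)` with `C_w`
the LZ76 exhaustive-parsing word count, on the binarized EEG (mean / median /
mid-range thresholds, b = 2) and on the 4-letter microstate sequence (mLZC,
b = 4). Permutation entropy `H_p / ln(m!)` on the voltage signal (m = 4,
τ = 1) and its microstate counterpart mPermEn: adjacent repeats removed, the
deduplicated sequence delay-embedded and matched against the `m^m × m`
state-pattern matrix `a_jh = ⌈j/m^(m−h)⌉ mod m`, entropy normalized by
`ln(m^m)`.

**Spectrum.** Absolute δ/θ/α/β power from a Parseval-scaled periodogram with
half-open band edges, plus the θ/β ratio.

**Prediction.** Per repetition: stratified 90/10 split, z-scoring from the
training part only, 5-fold CV grid search for the RBF-SVM (C ∈ 2^{−3..7},
γ ∈ 2^{−7..3}), one evaluation on the held-out 10%; ten seeded repetitions.
Metrics: accuracy, sensitivity, specificity, kappa, AUC, and false alarms
per interictal hour.

**Statistics.** Shapiro–Wilk-routed paired t / exact Wilcoxon tests with
paired Cohen's d and the dual significance criterion `p < α` and
`|d| > 0.3`; Kruskal–Wallis for map-level comparisons.

## Worked example

Generate a balanced synthetic dataset with planted preictal effects, learn
group templates from the interictal epochs, extract the 23-feature set and
run the prediction protocol:

```r
library(epimstate)

spec <- syntheticSpec(seed = 1)                  # planted class effects
ds   <- generateDataset(spec, nEpochsPerClass = 60)

inter <- which(epochLabels(ds$epochs) == "interictal")
X  <- do.call(cbind, lapply(inter, function(i) epochData(ds$epochs, i)))
g  <- computeGFP(X)
pk <- findGFPPeaks(g)
pk <- pk[round(seq(1, length(pk), length.out = 800))]
tpl <- taahcCluster(t(X[, pk]), k = 4, gfp = g[pk], level = "group")
tpl
#> MicrostateTemplates (group level): k = 4, 19 channels, GEV = 0.897

feats  <- extractFeatures(ds$epochs, tpl)
report <- runPrediction(assembleFeatures(feats, "fusion"))
report
#> ClassifierReport: 10 repetitions
#>   accuracy       92.500 (sd 7.297)
#>   sensitivity    90.000 (sd 16.102)
#>   specificity    95.000 (sd 8.051)
#>   kappa          85.000 (sd 14.593)
#>   auc             0.981 (sd 0.035)
#>   fprPerHour     60.000 (sd 96.609)
```

GEV ≈ 0.90 says the four group maps explain 90% of the GFP-weighted
topographic variance at the clustered peaks. The classifier separates the
planted effects at AUC ≈ 0.98; the per-hour false-alarm figure is large
because each repetition evaluates only six interictal epochs (18 s), so a
single false alarm scales to 200/h — long interictal test data are needed
for clinically scaled FPR values.

The statistical battery on the same features ranks the planted effects
(interictal − preictal differences; class letters refer to the fitted
clusters):

```r
st <- compareFeatureTable(feats, alpha = 5e-4)
head(st[order(st$p), c("feature", "test", "p", "d", "significant")], 5)
#>       feature     test        p      d significant
#> 19      delta paired-t 2.84e-22  1.982        TRUE
#> 8  coverage_C paired-t 3.77e-07 -0.738        TRUE
#> 23        TBR wilcoxon 8.88e-06 -0.570        TRUE
#> 1  duration_A wilcoxon 1.43e-05  0.545        TRUE
#> 2  coverage_A paired-t 2.38e-05  0.592        TRUE
```

Real recordings enter the same pipeline through `readEDF()` →
`preprocessEEG()` → `segmentEpochs()`; a thin command-line front end for the
simulate/features/predict/stats steps lives in `inst/cli/epimstate.R`.

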