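#' @include classes.R
NULL

.microstateFeatureNames <- function(k = 4)
  as.vector(outer(c("duration", "coverage", "occurrence"),
                  LETTERS[seq_len(k)], paste, sep = "_"))
.nonlinearFeatureNames <- function()
  c("LZC_mean", "LZC_median", "LZC_mid_p", "mLZC", "PermEn", "mPermEn")
.spectralFeatureNames <- function() c("delta", "theta", "alpha", "beta", "TBR")

#' Extract the full per-epoch feature table
#'
#' For each epoch: backfits the templates (with optional 32 ms temporal
#' smoothing), computes the 12 microstate parameters (duration, coverage and
#' occurrence for each of the k = 4 classes), the 6 nonlinear features
#' (three-threshold EEG Lempel-Ziv complexity, mLZC, permutation entropy and
#' mPermEn — EEG-based values are channel averages, microstate-based values
#' use the epoch's label sequence with unassigned samples dropped), and the
#' 5 spectral features (four absolute band powers and TBR, channel
#' averages).
#'
#' @param epochs an [EpochSet-class].
#' @param templates a [MicrostateTemplates-class] (group level in the
#'   standard protocol).
#' @param minCorr backfitting assignment threshold.
#' @param smooth apply [smoothSequence()] before the parameters.
#' @param minDurationMs smoothing floor in milliseconds.
#' @param config [ordinalConfig()] for the entropies.
#' @return data.frame with one row per epoch: `label` plus 23 feature
#'   columns.
#' @export
extractFeatures <- function(epochs, templates, minCorr = 0.5, smooth = TRUE,
                            minDurationMs = 32, config = ordinalConfig(4, 1)) {
  stopifnot(is(epochs, "EpochSet"), is(templates, "MicrostateTemplates"))
  k <- nStates(templates)
  fs <- sampleRate(epochs)
  n <- nEpochs(epochs)
  cols <- c(.microstateFeatureNames(k), .nonlinearFeatureNames(),
            .spectralFeatureNames())
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    ep <- epochData(epochs, i)
    seq <- backfit(templates, ep, sampleRate = fs, minCorr = minCorr)
    if (smooth) seq <- smoothSequence(seq, minDurationMs)
    par <- microstateParameters(seq)
    for (c in seq_len(k)) {
      out[i, paste0("duration_", LETTERS[c])] <- par$meanDurationMs[c]
      out[i, paste0("coverage_", LETTERS[c])] <- par$coverage[c]
      out[i, paste0("occurrence_", LETTERS[c])] <- par$occurrencePerS[c]
    }
    nl <- tryCatch(complexityFeatures(ep, seq, config = config, k = k),
                   error = function(e)
                     stop("nonlinear features failed for epoch ", i, ": ",
                          conditionMessage(e)))
    out[i, names(nl)] <- nl
    bp <- bandPowers(ep, fs)
    out[i, .spectralFeatureNames()] <- bp$average
  }
  cbind(data.frame(label = as.character(epochLabels(epochs)),
                   stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Assemble a feature matrix for classification
#'
#' Selects the requested feature family (or the 23-column fusion of all
#' three) from an extracted feature table. Raw values are returned;
#' z-scoring happens inside [runPrediction()] with parameters estimated on
#' training data only.
#'
#' @param features data.frame from [extractFeatures()].
#' @param mode "fusion" (23 columns), "microstate" (12), "nonlinear" (6) or
#'   "spectrum" (5).
#' @return list with `x` (numeric matrix) and `labels` (character vector).
#' @export
assembleFeatures <- function(features,
                             mode = c("fusion", "microstate", "nonlinear",
                                      "spectrum")) {
  mode <- match.arg(mode)
  k <- sum(grepl("^duration_", names(features)))
  want <- switch(mode,
                 fusion = c(.microstateFeatureNames(k),
                            .nonlinearFeatureNames(), .spectralFeatureNames()),
                 microstate = .microstateFeatureNames(k),
                 nonlinear = .nonlinearFeatureNames(),
                 spectrum = .spectralFeatureNames())
  missing <- setdiff(want, names(features))
  if (length(missing))
    stop("assembly error: feature(s) absent from the table: ",
         paste(missing, collapse = ", "))
  x <- as.matrix(features[, want, drop = FALSE])
  if (anyNA(x)) {
    badRows <- which(rowSums(is.na(x)) > 0)
    stop("assembly error: missing values in epoch(s) ",
         paste(badRows, collapse = ", "))
  }
  list(x = x, labels = features$label)
}

#' Write a tidy feature CSV
#'
#' Long format: one row per (epoch, feature) with columns `subject`,
#' `epoch`, `label`, `feature`, `value`.
#'
#' @param features data.frame from [extractFeatures()].
#' @param path output path.
#' @param subject subject identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
writeFeaturesCSV <- function(features, path, subject = "S1") {
  fcols <- setdiff(names(features), "label")
  long <- do.call(rbind, lapply(seq_len(nrow(features)), function(i)
    data.frame(subject = subject, epoch = i, label = features$label[i],
               feature = fcols,
               value = as.numeric(features[i, fcols]),
               stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
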