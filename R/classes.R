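#' @include epimstate-package.R
NULL

# ---------------------------------------------------------------------------
# EEGRecording
# ---------------------------------------------------------------------------

#' EEGRecording: a multichannel scalp EEG recording
#'
#' Container for a continuous recording: a channels x samples matrix in
#' microvolts, the sampling rate, channel labels, unit-sphere electrode
#' positions and state annotations (intervals labelled e.g. "interictal" or
#' "preictal").
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelLabels character vector, one label per data row.
#' @slot channelPositions numeric matrix channels x 3 (unit sphere); may
#'   contain NA rows for channels without a known template position.
#' @slot annotations data.frame with columns `onset` (s), `duration` (s) and
#'   `label`.
#' @exportClass EEGRecording
setClass("EEGRecording",
  slots = c(data = "matrix", sampleRate = "numeric",
            channelLabels = "character", channelPositions = "matrix",
            annotations = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@channelLabels))
      msg <- c(msg, "data row count must equal channel label count")
    if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (nrow(object@channelPositions) != nrow(object@data))
      msg <- c(msg, "channelPositions must have one row per channel")
    if (!all(c("onset", "duration", "label") %in% names(object@annotations)))
      msg <- c(msg, "annotations needs columns onset, duration, label")
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sampleRate sampling rate in Hz.
#' @param channelLabels channel names; defaults to rownames of `data`.
#' @param channelPositions channels x 3 unit-sphere coordinates; looked up
#'   from the idealized 10-20 template when omitted.
#' @param annotations data.frame of (onset, duration, label) intervals in
#'   seconds.
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, sampleRate, channelLabels = rownames(data),
                         channelPositions = NULL,
                         annotations = emptyAnnotations()) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(channelPositions))
    channelPositions <- suppressWarnings(standardPositions1020(channelLabels))
  rownames(data) <- channelLabels
  new("EEGRecording", data = data, sampleRate = as.numeric(sampleRate),
      channelLabels = as.character(channelLabels),
      channelPositions = as.matrix(channelPositions),
      annotations = as.data.frame(annotations))
}

#' An empty annotation table
#' @return zero-row data.frame with columns onset, duration, label.
#' @export
emptyAnnotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# EpochSet
# ---------------------------------------------------------------------------

#' EpochSet: fixed-length labelled EEG epochs
#'
#' @slot data numeric array channels x samples x epochs (microvolts).
#' @slot labels factor of per-epoch state labels.
#' @slot epochLengthS epoch length in seconds.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelLabels channel names.
#' @slot channelPositions channels x 3 electrode coordinates.
#' @exportClass EpochSet
setClass("EpochSet",
  slots = c(data = "array", labels = "factor", epochLengthS = "numeric",
            sampleRate = "numeric", channelLabels = "character",
            channelPositions = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3)
      msg <- c(msg, "data must be a 3D array (channels x samples x epochs)")
    else {
      if (d[3] != length(object@labels))
        msg <- c(msg, "one label per epoch required")
      if (d[1] != length(object@channelLabels))
        msg <- c(msg, "one channel label per data row required")
      if (abs(d[2] - object@epochLengthS * object@sampleRate) > 0.5)
        msg <- c(msg, "sample count must equal epochLengthS * sampleRate")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an EpochSet
#' @param data channels x samples x epochs array.
#' @param labels per-epoch state labels (coerced to factor).
#' @param epochLengthS epoch length in seconds.
#' @param sampleRate sampling rate in Hz.
#' @param channelLabels channel names.
#' @param channelPositions channels x 3 coordinates (10-20 template default).
#' @return an [EpochSet-class] object.
#' @export
EpochSet <- function(data, labels, epochLengthS, sampleRate,
                     channelLabels = NULL, channelPositions = NULL) {
  if (is.null(channelLabels)) {
    channelLabels <- dimnames(data)[[1]]
    if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(dim(data)[1]))
  }
  if (is.null(channelPositions))
    channelPositions <- suppressWarnings(standardPositions1020(channelLabels))
  new("EpochSet", data = data, labels = as.factor(labels),
      epochLengthS = as.numeric(epochLengthS),
      sampleRate = as.numeric(sampleRate),
      channelLabels = as.character(channelLabels),
      channelPositions = as.matrix(channelPositions))
}

# ---------------------------------------------------------------------------
# MicrostateTemplates
# ---------------------------------------------------------------------------

#' MicrostateTemplates: a set of polarity-free microstate maps
#'
#' Each map is an average-referenced (zero-mean across channels), unit-norm
#' scalp topography. The sign of a map is arbitrary: all comparisons against
#' templates are polarity-invariant.
#'
#' @slot maps k x channels matrix of topographies.
#' @slot gev global explained variance of the clustering that produced the
#'   maps, in `[0, 1]`.
#' @slot level "individual" or "group".
#' @slot channelLabels channel names (column order of `maps`).
#' @exportClass MicrostateTemplates
setClass("MicrostateTemplates",
  slots = c(maps = "matrix", gev = "numeric", level = "character",
            channelLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@maps) < 1) msg <- c(msg, "at least one map required")
    mm <- rowMeans(object@maps)
    nn <- sqrt(rowSums(object@maps^2))
    if (any(abs(mm) > 1e-6)) msg <- c(msg, "maps must be zero-mean across channels")
    if (any(abs(nn - 1) > 1e-6)) msg <- c(msg, "maps must be unit norm")
    if (length(object@gev) != 1 || object@gev < -1e-12 || object@gev > 1 + 1e-12)
      msg <- c(msg, "gev must be a single value in [0, 1]")
    if (!object@level %in% c("individual", "group"))
      msg <- c(msg, "level must be 'individual' or 'group'")
    if (ncol(object@maps) != length(object@channelLabels))
      msg <- c(msg, "one channel label per map column required")
    if (length(msg)) msg else TRUE
  })

#' Construct MicrostateTemplates
#' @param maps k x channels matrix; rows are centred and normalized.
#' @param gev global explained variance in `[0, 1]`.
#' @param level "individual" or "group".
#' @param channelLabels channel names.
#' @return a [MicrostateTemplates-class] object.
#' @export
MicrostateTemplates <- function(maps, gev = NA_real_, level = "individual",
                                channelLabels = colnames(maps)) {
  maps <- as.matrix(maps)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(ncol(maps)))
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("template maps must have non-zero spatial variance")
  maps <- maps / nrm
  if (is.na(gev)) gev <- 0
  colnames(maps) <- channelLabels
  rownames(maps) <- LETTERS[seq_len(nrow(maps))]
  new("MicrostateTemplates", maps = maps, gev = as.numeric(gev),
      level = level, channelLabels = as.character(channelLabels))
}

# ---------------------------------------------------------------------------
# MicrostateSequence
# ---------------------------------------------------------------------------

#' MicrostateSequence: per-sample microstate labels
#'
#' Labels are integers in `1..k`; `0` marks unassigned samples (best spatial
#' correlation below the backfitting threshold, or zero spatial variance).
#'
#' @slot labels integer vector of per-sample classes (0 = unassigned).
#' @slot correlations per-sample best absolute spatial correlation.
#' @slot sampleRate sampling rate in Hz.
#' @slot k number of microstate classes.
#' @exportClass MicrostateSequence
setClass("MicrostateSequence",
  slots = c(labels = "integer", correlations = "numeric",
            sampleRate = "numeric", k = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) != length(object@correlations))
      msg <- c(msg, "labels and correlations must have equal length")
    if (any(object@labels < 0L | object@labels > object@k))
      msg <- c(msg, "labels must lie in 0..k")
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a MicrostateSequence
#' @param labels integer per-sample labels (0 = unassigned).
#' @param sampleRate sampling rate in Hz.
#' @param k number of classes; defaults to `max(labels)`.
#' @param correlations per-sample best absolute correlation (defaults to NA).
#' @return a [MicrostateSequence-class] object.
#' @export
MicrostateSequence <- function(labels, sampleRate, k = max(labels, 1L),
                               correlations = rep(NA_real_, length(labels))) {
  new("MicrostateSequence", labels = as.integer(labels),
      correlations = as.numeric(correlations),
      sampleRate = as.numeric(sampleRate), k = as.integer(k))
}

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' @rdname accessors
#' @param object an epimstate data object.
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname accessors
#' @param i epoch index.
#' @export
setGeneric("epochData", function(object, i) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("maps", function(object) standardGeneric("maps"))
#' @rdname accessors
#' @export
setGeneric("gev", function(object) standardGeneric("gev"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("stateCorrelations", function(object) standardGeneric("stateCorrelations"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Accessors for epimstate data objects
#'
#' Small accessor family: `sampleRate()`, `channelLabels()`,
#' `channelPositions()`, `nChannels()`, `recordingData()` (the raw
#' channels x samples matrix), `annotations()`, `nEpochs()`, `epochLabels()`,
#' `epochData(x, i)` (one epoch as a matrix), `maps()`, `gev()`,
#' `stateLabels()`, `stateCorrelations()` and `nStates()`.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("sampleRate", "EEGRecording", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "EpochSet", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "MicrostateSequence", function(object) object@sampleRate)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "MicrostateTemplates", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelPositions", "EEGRecording", function(object) object@channelPositions)
#' @rdname accessors
setMethod("channelPositions", "EpochSet", function(object) object@channelPositions)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(object) nrow(object@data))
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(object) dim(object@data)[1])
#' @rdname accessors
setMethod("recordingData", "EEGRecording", function(object) object@data)
#' @rdname accessors
setMethod("annotations", "EEGRecording", function(object) object@annotations)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[3])
#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(object) object@labels)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(object, i) {
  m <- object@data[, , i, drop = FALSE]
  dim(m) <- dim(object@data)[1:2]
  rownames(m) <- object@channelLabels
  m
})
#' @rdname accessors
setMethod("maps", "MicrostateTemplates", function(object) object@maps)
#' @rdname accessors
setMethod("gev", "MicrostateTemplates", function(object) object@gev)
#' @rdname accessors
setMethod("nStates", "MicrostateTemplates", function(object) nrow(object@maps))
#' @rdname accessors
setMethod("nStates", "MicrostateSequence", function(object) object@k)
#' @rdname accessors
setMethod("stateLabels", "MicrostateSequence", function(object) object@labels)
#' @rdname accessors
setMethod("stateCorrelations", "MicrostateSequence", function(object) object@correlations)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sampleRate,
              ncol(object@data) / object@sampleRate))
  cat("  channels:", paste(head(object@channelLabels, 8), collapse = ", "),
      if (length(object@channelLabels) > 8) "...", "\n")
  if (nrow(object@annotations))
    cat(sprintf("  annotations: %d interval(s) [%s]\n",
                nrow(object@annotations),
                paste(unique(object@annotations$label), collapse = ", ")))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs of %g s (%d channels @ %g Hz)\n",
              d[3], object@epochLengthS, d[1], object@sampleRate))
  print(table(object@labels))
})

setMethod("show", "MicrostateTemplates", function(object) {
  cat(sprintf("MicrostateTemplates (%s level): k = %d, %d channels, GEV = %.3f\n",
              object@level, nrow(object@maps), ncol(object@maps), object@gev))
})

setMethod("show", "MicrostateSequence", function(object) {
  n <- length(object@labels)
  cat(sprintf("MicrostateSequence: %d samples @ %g Hz, k = %d, %.1f%% assigned\n",
              n, object@sampleRate, object@k,
              if (n) 100 * mean(object@labels > 0L) else 0))
})
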