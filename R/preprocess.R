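#' @include classes.R
NULL

#' Preprocessing configuration
#'
#' Parameters of the standard preprocessing chain: montage reduction to the
#' 19 10-20 channels, resampling, a band-stop filter around the power-line
#' frequency, a band-pass filter, amplitude-based bad-channel replacement by
#' spherical-spline interpolation, and average referencing.
#'
#' @param targetRate target sampling rate in Hz.
#' @param bandpass length-2 numeric, band-pass edges in Hz.
#' @param bandstop length-2 numeric, band-stop edges in Hz (power line).
#' @param transitionHz FIR transition bandwidth in Hz; sets the filter order
#'   (Hamming-windowed sinc).
#' @param amplitudeThresholdUV absolute amplitude above which a sample counts
#'   as an artifact, in microvolts.
#' @param badFraction fraction of artifact samples above which a channel is
#'   replaced by interpolation.
#' @param channels channel names the montage must provide.
#' @return a list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(targetRate = 250,
                             bandpass = c(1, 40),
                             bandstop = c(48, 52),
                             transitionHz = 1,
                             amplitudeThresholdUV = 150,
                             badFraction = 0.2,
                             channels = standardChannels1020()) {
  structure(list(targetRate = targetRate, bandpass = bandpass,
                 bandstop = bandstop, transitionHz = transitionHz,
                 amplitudeThresholdUV = amplitudeThresholdUV,
                 badFraction = badFraction, channels = channels),
            class = "PreprocessConfig")
}

# Hamming-windowed sinc FIR: order from the transition bandwidth, capped so
# zero-phase filtering stays well-conditioned on short signals.
.firOrder <- function(fs, transitionHz, nSamples) {
  ord <- ceiling(3.3 * fs / transitionHz)
  ord <- min(ord, max(8, floor(nSamples / 4) - 1))
  if (ord %% 2 == 1) ord <- ord + 1  # even order -> odd tap count (type I)
  ord
}

.firFilterMatrix <- function(x, fs, edges, type, transitionHz) {
  ord <- .firOrder(fs, transitionHz, ncol(x))
  b <- signal::fir1(ord, edges / (fs / 2), type = type)
  t(apply(x, 1, function(ch) signal::filtfilt(filt = b, x = ch)))
}

#' Preprocess an EEG recording
#'
#' Applies the standard chain: (1) reduce to the 19 standard 10-20 channels
#' (extras such as A1/A2 are dropped); (2) resample to `targetRate`; (3)
#' detect channels whose absolute amplitude exceeds
#' `amplitudeThresholdUV` on more than `badFraction` of samples; (4) apply
#' the band-stop then the band-pass zero-phase FIR filters; (5) replace the
#' flagged channels by spherical-spline interpolation from the remaining
#' (filtered) channels; (6) average reference. Bad channels are detected
#' before filtering because filtering attenuates the very excursions the
#' amplitude rule targets; the reference is applied last so every sample's
#' channel mean is exactly zero.
#'
#' @param rec an [EEGRecording-class] containing at least the 19 standard
#'   channels.
#' @param config a [preprocessConfig()] list.
#' @return the preprocessed [EEGRecording-class] (19 channels, `targetRate`).
#' @export
preprocessEEG <- function(rec, config = preprocessConfig()) {
  stopifnot(is(rec, "EEGRecording"))
  want <- config$channels
  idx <- match(want, channelLabels(rec))
  if (anyNA(idx))
    stop("montage error: recording lacks channel(s) ",
         paste(want[is.na(idx)], collapse = ", "))
  x <- recordingData(rec)[idx, , drop = FALSE]
  pos <- standardPositions1020(want)
  fs <- sampleRate(rec)
  # resample
  if (abs(fs - config$targetRate) > 1e-9) {
    if (fs < config$targetRate - 1e-9)
      warning("upsampling from ", fs, " Hz to ", config$targetRate, " Hz")
    fr <- .rational(config$targetRate / fs)
    x <- t(apply(x, 1, function(ch)
      signal::resample(ch, p = fr[1], q = fr[2])))
    fs <- config$targetRate
  }
  # bad-channel detection on the resampled, unfiltered data
  badFrac <- rowMeans(abs(x) > config$amplitudeThresholdUV)
  bad <- which(badFrac > config$badFraction)
  if (length(bad) == nrow(x))
    stop("unrecoverable data: every channel exceeds the amplitude threshold")
  # band-stop before band-pass (order immaterial for LTI filters, fixed for
  # reproducibility)
  x <- .firFilterMatrix(x, fs, config$bandstop, "stop", config$transitionHz)
  x <- .firFilterMatrix(x, fs, config$bandpass, "pass", config$transitionHz)
  if (length(bad)) {
    good <- setdiff(seq_len(nrow(x)), bad)
    x[bad, ] <- sphericalSplineInterpolate(pos[good, , drop = FALSE],
                                           x[good, , drop = FALSE],
                                           pos[bad, , drop = FALSE])
    message("interpolated ", length(bad), " bad channel(s): ",
            paste(want[bad], collapse = ", "))
  }
  # average reference
  x <- sweep(x, 2, colMeans(x))
  ann <- annotations(rec)
  EEGRecording(x, sampleRate = fs, channelLabels = want,
               channelPositions = pos, annotations = ann)
}

# small-denominator rational approximation for resampling ratios
.rational <- function(r, maxDen = 1000) {
  for (q in seq_len(maxDen)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", r, " as a small rational")
}

#' Cut a recording into fixed-length labelled epochs
#'
#' Each annotated interval is cut independently into non-overlapping,
#' contiguous epochs of `epochLengthS` seconds; the trailing partial window
#' of each interval is discarded. Samples outside any annotation are
#' excluded and the dropped-duration count is reported via a message.
#' Sample indexing is 0-based with half-open intervals.
#'
#' @param rec an [EEGRecording-class] with annotations.
#' @param epochLengthS epoch length in seconds.
#' @param labels optional character vector restricting which annotation
#'   labels become epochs.
#' @return an [EpochSet-class]; zero epochs (with a warning) when no interval
#'   is long enough.
#' @export
segmentEpochs <- function(rec, epochLengthS = 3, labels = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- sampleRate(rec)
  x <- recordingData(rec)
  nSamp <- ncol(x)
  L <- as.integer(round(epochLengthS * fs))
  ann <- annotations(rec)
  if (!is.null(labels)) ann <- ann[ann$label %in% labels, , drop = FALSE]
  chunks <- list(); labs <- character()
  covered <- 0
  if (nrow(ann)) for (i in seq_len(nrow(ann))) {
    s0 <- as.integer(floor(ann$onset[i] * fs))            # 0-based
    s1 <- min(as.integer(floor((ann$onset[i] + ann$duration[i]) * fs)), nSamp)
    if (s1 <= s0) next
    covered <- covered + (s1 - s0)
    nEp <- (s1 - s0) %/% L
    if (nEp < 1) next
    for (e in seq_len(nEp)) {
      a <- s0 + (e - 1L) * L
      chunks[[length(chunks) + 1L]] <- x[, (a + 1L):(a + L), drop = FALSE]
      labs <- c(labs, ann$label[i])
    }
  }
  dropped <- (nSamp - covered) / fs
  if (dropped > 1 / fs)
    message(sprintf("segmentEpochs: %.1f s outside annotations excluded", dropped))
  if (!length(chunks)) {
    warning("no interval long enough for a ", epochLengthS, " s epoch")
    arr <- array(0, dim = c(nrow(x), L, 0))
    return(EpochSet(arr, labels = factor(character(0)),
                    epochLengthS = epochLengthS, sampleRate = fs,
                    channelLabels = channelLabels(rec),
                    channelPositions = channelPositions(rec)))
  }
  arr <- array(unlist(chunks), dim = c(nrow(x), L, length(chunks)))
  EpochSet(arr, labels = labs, epochLengthS = epochLengthS, sampleRate = fs,
           channelLabels = channelLabels(rec),
           channelPositions = channelPositions(rec))
}

#' Balance epoch counts across the two states
#'
#' Keeps the chronologically first `n` epochs of each state, where `n` is the
#' size of the smaller class — the per-subject balancing rule used when
#' interictal segments outnumber preictal ones.
#'
#' @param epochs an [EpochSet-class].
#' @return a balanced [EpochSet-class].
#' @export
balanceEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  tab <- table(epochLabels(epochs))
  n <- min(tab)
  keep <- unlist(lapply(names(tab), function(l)
    head(which(epochLabels(epochs) == l), n)))
  keep <- sort(keep)
  EpochSet(epochs@data[, , keep, drop = FALSE],
           labels = droplevels(epochLabels(epochs)[keep]),
           epochLengthS = epochs@epochLengthS, sampleRate = sampleRate(epochs),
           channelLabels = channelLabels(epochs),
           channelPositions = channelPositions(epochs))
}

#' Export an EpochSet as per-epoch CSV files
#'
#' Writes one `epoch_<i>_<label>.csv` per epoch (channels in columns, samples
#' in rows) plus an `epochs_index.csv` manifest.
#'
#' @param epochs an [EpochSet-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
exportEpochsCSV <- function(epochs, dir) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- as.character(epochLabels(epochs))
  files <- character(nEpochs(epochs))
  for (i in seq_len(nEpochs(epochs))) {
    files[i] <- file.path(dir, sprintf("epoch_%04d_%s.csv", i, labs[i]))
    m <- t(epochData(epochs, i))
    colnames(m) <- channelLabels(epochs)
    write.csv(m, files[i], row.names = FALSE)
  }
  manifest <- file.path(dir, "epochs_index.csv")
  write.csv(data.frame(epoch = seq_along(files), label = labs,
                       file = basename(files)), manifest, row.names = FALSE)
  invisible(manifest)
}
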