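#' @include classes.R
NULL

#' Canonical EEG frequency bands
#'
#' Half-open bands `[low, high)` in Hz: delta `[1, 4)`, theta `[4, 8)`,
#' alpha `[8, 12)`, beta `[12, 30)`. Half-open edges guarantee every
#' frequency bin is counted exactly once.
#'
#' @return named list of length-2 numeric vectors.
#' @export
defaultBands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

# one-sided periodogram scaled so that the sum over all bins equals the mean
# squared amplitude of the (windowed) signal
.periodogram <- function(x) {
  n <- length(x)
  X <- fft(x)
  p <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  idx <- seq_len(half + 1)               # DC .. Nyquist (or near)
  pow <- p[idx]
  dbl <- 2:(if (n %% 2 == 0) half else half + 1)
  pow[dbl] <- 2 * pow[dbl]
  pow
}

.welchPSD <- function(x, fs, segLengthS = 1, overlap = 0.5) {
  n <- length(x)
  L <- max(8, round(segLengthS * fs))
  if (L > n) L <- n
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))  # Hamming
  wnorm <- mean(win^2)
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * win
    p <- .periodogram(seg) / wnorm
    acc <- if (is.null(acc)) p else acc + p
  }
  list(power = acc / length(starts), freq = (seq_along(acc) - 1) * fs / L)
}

#' Absolute band power and theta/beta ratio of an epoch
#'
#' Computes a one-sided periodogram per channel (rectangular window over the
#' full epoch by default, Welch-averaged 1-s Hamming segments as an
#' alternative estimator), sums bin powers inside each half-open frequency
#' band, and forms the theta/beta ratio (TBR). The periodogram is scaled so
#' the summed bin power equals the mean squared amplitude of the signal
#' (Parseval), so band powers are in microvolts squared.
#'
#' @param epoch channels x samples matrix (at least 1 s of samples).
#' @param rate sampling rate in Hz.
#' @param bands named list of `[low, high)` band edges; see [defaultBands()].
#' @param method "periodogram" (rectangular window) or "welch".
#' @return list with `perChannel` (channels x bands+TBR matrix) and
#'   `average` (named vector of channel means).
#' @export
bandPowers <- function(epoch, rate, bands = defaultBands(),
                       method = c("periodogram", "welch")) {
  method <- match.arg(method)
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n < rate) stop("epoch shorter than 1 s of samples")
  bn <- names(bands)
  out <- matrix(0, nrow(epoch), length(bands) + 1,
                dimnames = list(rownames(epoch), c(bn, "TBR")))
  for (ch in seq_len(nrow(epoch))) {
    if (method == "periodogram") {
      pow <- .periodogram(epoch[ch, ])
      freq <- (seq_along(pow) - 1) * rate / n
    } else {
      w <- .welchPSD(epoch[ch, ], rate)
      pow <- w$power; freq <- w$freq
    }
    for (b in seq_along(bands))
      out[ch, b] <- sum(pow[freq >= bands[[b]][1] & freq < bands[[b]][2]])
    if (out[ch, "beta"] == 0)
      stop("TBR undefined: beta-band power is zero")
    out[ch, "TBR"] <- out[ch, "theta"] / out[ch, "beta"]
  }
  avg <- colMeans(out[, bn, drop = FALSE])
  avg <- c(avg, TBR = unname(avg["theta"] / avg["beta"]))
  list(perChannel = out, average = avg)
}

#' Group x subject power tables
#'
#' Builds the two summary arrays used for spectral statistics: a band-level
#' table (group x subject x bands+TBR, averaged over channels and epochs)
#' and a channel-level table for one chosen band (group x subject x
#' channel). Both state groups must be present for every subject.
#'
#' @param epochSets named list of [EpochSet-class] objects, one per subject,
#'   each containing epochs of both states.
#' @param groups the two state labels, in group-axis order.
#' @param channelBand band name for the channel-level table.
#' @param bands band definition list.
#' @return list with arrays `bandTable` and `channelTable`.
#' @export
powerTables <- function(epochSets, groups = c("interictal", "preictal"),
                        channelBand = "delta", bands = defaultBands()) {
  stopifnot(length(groups) == 2)
  subjects <- names(epochSets)
  if (is.null(subjects)) subjects <- paste0("S", seq_along(epochSets))
  nb <- length(bands) + 1
  nch <- nChannels(epochSets[[1]])
  bandTable <- array(0, dim = c(2, length(subjects), nb),
                     dimnames = list(groups, subjects,
                                     c(names(bands), "TBR")))
  channelTable <- array(0, dim = c(2, length(subjects), nch),
                        dimnames = list(groups, subjects,
                                        channelLabels(epochSets[[1]])))
  for (s in seq_along(epochSets)) {
    es <- epochSets[[s]]
    labs <- as.character(epochLabels(es))
    for (g in 1:2) {
      idx <- which(labs == groups[g])
      if (!length(idx))
        stop("data-completeness error: subject ", subjects[s],
             " has no '", groups[g], "' epochs")
      accA <- 0; accC <- 0
      for (i in idx) {
        bp <- bandPowers(epochData(es, i), sampleRate(es), bands = bands)
        accA <- accA + bp$average
        accC <- accC + bp$perChannel[, channelBand]
      }
      bandTable[g, s, ] <- accA / length(idx)
      channelTable[g, s, ] <- accC / length(idx)
    }
  }
  list(bandTable = bandTable, channelTable = channelTable,
       channelBand = channelBand)
}
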