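#' @include classes.R
NULL

# smooth random scalp patterns: random coefficients on low-order polynomial
# functions of the electrode coordinates, centred, then orthonormalized so
# pairwise spatial correlations are exactly zero (identifiable templates)
.makeTemplates <- function(k, positions) {
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  basis <- cbind(x, y, z, x * y, x * z, y * z, x^2 - y^2, 2 * z^2 - x^2 - y^2)
  raw <- basis %*% matrix(rnorm(ncol(basis) * k), ncol(basis), k)
  raw <- sweep(raw, 2, colMeans(raw))
  q <- qr.Q(qr(raw))                # orthonormal columns, still zero-mean
  t(q)                              # k x channels, unit norm
}

#' Specification for synthetic EEG with planted microstate structure
#'
#' Defines the generative model every module can be validated against: `k`
#' orthogonal zero-mean scalp templates driven by a semi-Markov state
#' sequence (class dwell times geometric or lognormal with planted means), a
#' global oscillatory carrier giving the rendered maps their GFP peak
#' structure, band-limited oscillatory background activity, white noise at a
#' controlled SNR, and class-conditional effects that make the "preictal"
#' state differ from the "interictal" one in the directions reported for
#' epilepsy: longer class-A and shorter class-C dwellings, reduced
#' delta-band power, raised theta, and more regular (hence less complex)
#' state transitions.
#'
#' @param nChannels number of electrodes (the 19-channel 10-20 template).
#' @param sampleRate sampling rate in Hz.
#' @param k number of microstate classes.
#' @param templates optional k x channels template matrix; smooth random
#'   orthogonal maps are generated when omitted.
#' @param transitionMatrix k x k matrix of between-state transition
#'   probabilities (zero diagonal, rows sum to 1); uniform by default.
#' @param meanDwellMs planted mean dwell time per class, milliseconds.
#' @param dwellDistribution "geometric" (memoryless, analytic mean) or
#'   "lognormal" (tight dwell distribution with few very short segments).
#' @param dwellSdLog log-sd of the lognormal dwell option.
#' @param carrierHz frequency of the global amplitude carrier; its rectified
#'   waveform produces the GFP peaks.
#' @param amplitudeUV peak scalp amplitude of the microstate signal.
#' @param oscillations data.frame(freqHz, amplitudeUV) of background
#'   oscillatory components, each with its own fixed random topography.
#' @param snrDb ratio of microstate-signal power to white-noise power, dB;
#'   `Inf` disables noise.
#' @param classEffects list of preictal effects: `dwellMultipliers`
#'   (per-class factors on mean dwell), `deltaAmpFactor` / `thetaAmpFactor`
#'   (scaling of background components below 4 Hz / in 4-8 Hz),
#'   `transitionRegularity` (0 = interictal-like random transitions, ->1 =
#'   deterministic cycle, lowering sequence complexity), `labelNoiseRate`
#'   (fraction of epochs with flipped class label).
#' @param seed RNG seed; a fixed seed makes every generated object
#'   reproducible byte for byte.
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nChannels = 19, sampleRate = 250, k = 4,
                          templates = NULL, transitionMatrix = NULL,
                          meanDwellMs = rep(80, k),
                          dwellDistribution = c("geometric", "lognormal"),
                          dwellSdLog = 0.25,
                          carrierHz = 10, amplitudeUV = 30,
                          oscillations = data.frame(
                            freqHz = c(2, 6, 22),
                            amplitudeUV = c(8, 5, 3)),
                          snrDb = 10,
                          classEffects = list(
                            dwellMultipliers = c(1.5, 1, 1 / 1.5, 1),
                            deltaAmpFactor = 0.6,
                            thetaAmpFactor = 1.3,
                            transitionRegularity = 0.5,
                            labelNoiseRate = 0),
                          seed = 1L) {
  dwellDistribution <- match.arg(dwellDistribution)
  if (is.null(transitionMatrix)) {
    transitionMatrix <- matrix(1 / (k - 1), k, k)
    diag(transitionMatrix) <- 0
  }
  if (any(abs(rowSums(transitionMatrix) - 1) > 1e-9) ||
      any(transitionMatrix < 0))
    stop("spec error: transition matrix rows must be non-negative and sum to 1")
  if (any(meanDwellMs <= 0)) stop("spec error: mean dwells must be positive")
  labels <- standardChannels1020()[seq_len(min(nChannels, 19))]
  if (nChannels > 19) labels <- c(labels, paste0("X", seq_len(nChannels - 19)))
  positions <- suppressWarnings(standardPositions1020(labels))
  if (anyNA(positions)) {
    # spread any extra electrodes deterministically on the upper sphere
    miss <- which(is.na(positions[, 1]))
    ang <- seq(0, 2 * pi, length.out = length(miss) + 1)[seq_along(miss)]
    positions[miss, ] <- cbind(sin(ang) * 0.9, cos(ang) * 0.9,
                               rep(sqrt(1 - 0.81), length(miss)))
  }
  if (is.null(templates)) {
    set.seed(seed)
    templates <- .makeTemplates(k, positions)
  }
  ce <- classEffects
  if (length(ce$dwellMultipliers %||% numeric(0)) != k)
    ce$dwellMultipliers <- rep(1, k)
  structure(list(nChannels = nChannels, sampleRate = sampleRate, k = k,
                 templates = templates, transitionMatrix = transitionMatrix,
                 meanDwellMs = meanDwellMs,
                 dwellDistribution = dwellDistribution,
                 dwellSdLog = dwellSdLog, carrierHz = carrierHz,
                 amplitudeUV = amplitudeUV, oscillations = oscillations,
                 snrDb = snrDb, classEffects = ce, seed = as.integer(seed),
                 channelLabels = labels, positions = positions),
            class = "SyntheticSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# preictal variant of a spec: apply the class-conditional effects
.applyClassEffects <- function(spec, state) {
  if (state != "preictal") return(spec)
  ce <- spec$classEffects
  spec$meanDwellMs <- spec$meanDwellMs * ce$dwellMultipliers
  reg <- ce$transitionRegularity %||% 0
  if (reg > 0) {
    k <- spec$k
    cycle <- matrix(0, k, k)
    cycle[cbind(seq_len(k), c(2:k, 1))] <- 1
    spec$transitionMatrix <- (1 - reg) * spec$transitionMatrix + reg * cycle
  }
  osc <- spec$oscillations
  if (nrow(osc)) {
    osc$amplitudeUV[osc$freqHz < 4] <-
      osc$amplitudeUV[osc$freqHz < 4] * (ce$deltaAmpFactor %||% 1)
    osc$amplitudeUV[osc$freqHz >= 4 & osc$freqHz < 8] <-
      osc$amplitudeUV[osc$freqHz >= 4 & osc$freqHz < 8] * (ce$thetaAmpFactor %||% 1)
  }
  spec$oscillations <- osc
  spec
}

# semi-Markov label sequence using the current RNG state
.simulateLabels <- function(spec, durationS) {
  N <- as.integer(round(durationS * spec$sampleRate))
  mu <- spec$meanDwellMs * spec$sampleRate / 1000   # mean dwell in samples
  lab <- integer(N)
  filled <- 0L
  state <- sample.int(spec$k, 1)
  while (filled < N) {
    d <- if (spec$dwellDistribution == "geometric") {
      1L + rgeom(1, prob = min(1, 1 / mu[state]))
    } else {
      max(1L, as.integer(round(rlnorm(1,
        meanlog = log(mu[state]) - spec$dwellSdLog^2 / 2,
        sdlog = spec$dwellSdLog))))
    }
    d <- min(d, N - filled)
    lab[(filled + 1L):(filled + d)] <- state
    filled <- filled + d
    p <- spec$transitionMatrix[state, ]
    if (sum(p) <= 0) next                      # absorbing state
    state <- sample.int(spec$k, 1, prob = p)
  }
  lab
}

#' Simulate a planted microstate label sequence
#'
#' Draws a semi-Markov state sequence: successive classes follow the spec's
#' transition matrix and each visit dwells for a geometric (or lognormal)
#' duration with the planted mean. Fully reproducible from the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @param durationS duration in seconds.
#' @return list with `labels` (integer per-sample sequence) and `truth`
#'   (planted templates, dwell means, transition matrix).
#' @export
simulateSequence <- function(spec, durationS) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  lab <- .simulateLabels(spec, durationS)
  list(labels = lab,
       truth = list(templates = spec$templates,
                    meanDwellMs = spec$meanDwellMs,
                    transitionMatrix = spec$transitionMatrix))
}

# deterministic background component i (independent of the flowing RNG)
.oscComponent <- function(spec, i) {
  saved <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
  })
  set.seed((spec$seed + 7919L * i) %% .Machine$integer.max)
  list(pattern = .makeTemplates(1, spec$positions)[1, ],
       phase = runif(1, 0, 2 * pi))
}

# render labels into channel data with the current RNG state
.renderData <- function(labels, spec) {
  N <- length(labels)
  fs <- spec$sampleRate
  tt <- (seq_len(N) - 1) / fs
  carrier <- sin(2 * pi * spec$carrierHz * tt) * spec$amplitudeUV
  X <- t(spec$templates)[, labels, drop = FALSE] *
    matrix(carrier, spec$nChannels, N, byrow = TRUE)
  sigPower <- mean(X^2)
  osc <- spec$oscillations
  if (nrow(osc)) for (i in seq_len(nrow(osc))) {
    # topography and phase are functions of the spec seed alone, so both
    # state classes share the same background up to the planted amplitude
    # effects (a topography difference would fake a class effect)
    bg <- .oscComponent(spec, i)
    X <- X + outer(bg$pattern, sin(2 * pi * osc$freqHz[i] * tt + bg$phase) *
                     osc$amplitudeUV[i])
  }
  if (is.finite(spec$snrDb)) {
    noise <- matrix(rnorm(spec$nChannels * N), spec$nChannels, N)
    noise <- sweep(noise, 2, colMeans(noise))        # average-referenced
    target <- sigPower / 10^(spec$snrDb / 10)
    noise <- noise * sqrt(target / mean(noise^2))    # exact empirical SNR
    X <- X + noise
  }
  sweep(X, 2, colMeans(X))
}

#' Render a label sequence into synthetic scalp EEG
#'
#' Each sample is the active class's template scaled by a global sinusoidal
#' carrier (whose rectified waveform produces GFP peaks, and whose sign
#' changes exercise polarity invariance), plus oscillatory background
#' components with fixed random topographies, plus average-referenced white
#' noise scaled so the empirical microstate-signal-to-noise ratio equals
#' `snrDb` exactly. The output is average-referenced.
#'
#' @param labels integer label sequence in `1..k`.
#' @param spec a [syntheticSpec()].
#' @return an [EEGRecording-class].
#' @export
renderEEG <- function(labels, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (any(labels < 1L | labels > spec$k)) stop("labels must lie in 1..k")
  set.seed(spec$seed + 1L)
  X <- .renderData(labels, spec)
  EEGRecording(X, sampleRate = spec$sampleRate,
               channelLabels = spec$channelLabels,
               channelPositions = spec$positions)
}

#' Generate a balanced two-state synthetic dataset
#'
#' Simulates and renders a balanced interictal/preictal epoch set with the
#' spec's class-conditional effects planted in the preictal state, plus the
#' ground truth needed to score recovery. The same seed yields a
#' byte-identical dataset.
#'
#' @param spec a [syntheticSpec()].
#' @param nEpochsPerClass epochs per state.
#' @param epochLengthS epoch length in seconds.
#' @return list with `epochs` (an [EpochSet-class]), and `truth` (per-epoch
#'   planted label sequences, templates, per-state dwell means and the
#'   applied class effects).
#' @export
generateDataset <- function(spec, nEpochsPerClass, epochLengthS = 3) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (nEpochsPerClass < 1) stop("spec error: request at least one epoch per class")
  set.seed(spec$seed)
  L <- as.integer(round(epochLengthS * spec$sampleRate))
  states <- c("interictal", "preictal")
  arr <- array(0, dim = c(spec$nChannels, L, 2L * nEpochsPerClass))
  seqTruth <- vector("list", 2L * nEpochsPerClass)
  labs <- character(2L * nEpochsPerClass)
  dwellTruth <- list()
  i <- 0L
  for (st in states) {
    cspec <- .applyClassEffects(spec, st)
    dwellTruth[[st]] <- cspec$meanDwellMs
    lab <- .simulateLabels(cspec, nEpochsPerClass * epochLengthS)
    X <- .renderData(lab, cspec)
    for (e in seq_len(nEpochsPerClass)) {
      i <- i + 1L
      idx <- ((e - 1L) * L + 1L):(e * L)
      arr[, , i] <- X[, idx]
      seqTruth[[i]] <- lab[idx]
      labs[i] <- st
    }
  }
  noiseRate <- spec$classEffects$labelNoiseRate %||% 0
  if (noiseRate > 0) {
    flip <- runif(length(labs)) < noiseRate
    labs[flip] <- ifelse(labs[flip] == "interictal", "preictal", "interictal")
  }
  epochs <- EpochSet(arr, labels = factor(labs, levels = states),
                     epochLengthS = epochLengthS,
                     sampleRate = spec$sampleRate,
                     channelLabels = spec$channelLabels,
                     channelPositions = spec$positions)
  list(epochs = epochs,
       truth = list(labelSequences = seqTruth,
                    templates = spec$templates,
                    meanDwellMs = dwellTruth,
                    classEffects = spec$classEffects))
}
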