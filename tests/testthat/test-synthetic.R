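test_that("simulation is fully reproducible from the spec seed", {
  spec <- quietSpec(seed = 51)
  expect_identical(simulateSequence(spec, 20)$labels,
                   simulateSequence(spec, 20)$labels)
  ds1 <- generateDataset(spec, 5)
  ds2 <- generateDataset(spec, 5)
  expect_identical(ds1$epochs@data, ds2$epochs@data)
  expect_identical(ds1$truth$labelSequences, ds2$truth$labelSequences)
})

test_that("empirical dwell means track the planted values", {
  spec <- quietSpec(seed = 52, meanDwellMs = rep(80, 4))
  lab <- simulateSequence(spec, 600)$labels
  emp <- mean(rle(lab)$lengths) * 1000 / 250
  expect_lt(abs(emp - 80) / 80, 0.05)
})

test_that("degenerate transition structure keeps a single class forever", {
  spec <- quietSpec(seed = 53, k = 3, meanDwellMs = rep(40, 3))
  spec$transitionMatrix <- diag(3)
  lab <- simulateSequence(spec, 10)$labels
  expect_length(unique(lab), 1)
  expect_error(syntheticSpec(transitionMatrix = matrix(2, 4, 4)),
               "transition matrix")
})

test_that("noise-free rendering correlates perfectly with the templates", {
  spec <- quietSpec(seed = 54, snrDb = Inf)
  sim <- simulateSequence(spec, 4)
  x <- recordingData(renderEEG(sim$labels, spec))
  # away from carrier zero crossings every sample matches its template
  g <- computeGFP(x)
  idx <- which(g > 0.1 * max(g))
  rs <- vapply(idx, function(i)
    spatialCorrelation(x[, i], spec$templates[sim$labels[i], ])$absR,
    numeric(1))
  expect_true(all(rs > 1 - 1e-9))
  expect_lt(max(abs(colMeans(x))), 1e-9)   # average referenced
})

test_that("rendered noise hits the requested SNR within 1 dB", {
  specN <- quietSpec(seed = 55, snrDb = 10)
  specI <- specN; specI$snrDb <- Inf
  lab <- simulateSequence(specN, 20)$labels
  clean <- recordingData(renderEEG(lab, specI))
  noisy <- recordingData(renderEEG(lab, specN))
  noise <- noisy - clean
  snr <- 10 * log10(mean(clean^2) / mean(noise^2))
  expect_lt(abs(snr - 10), 1)
})

test_that("datasets are balanced with the requested epoch counts", {
  spec <- quietSpec(seed = 56)
  ds <- generateDataset(spec, 30)
  expect_equal(as.vector(table(epochLabels(ds$epochs))), c(30, 30))
  expect_error(generateDataset(spec, 0), "at least one epoch")
})

test_that("the planted dwell multiplier shifts class-A durations upward", {
  # sign of the planted effect from the ground-truth label sequences
  hits <- 0
  for (s in 1:20) {
    spec <- quietSpec(seed = 600 + s)
    ds <- generateDataset(spec, 10)
    labs <- as.character(epochLabels(ds$epochs))
    durA <- function(state) {
      seqs <- ds$truth$labelSequences[labs == state]
      runs <- unlist(lapply(seqs, function(s) {
        r <- rle(s); r$lengths[r$values == 1]
      }))
      mean(runs)
    }
    hits <- hits + (durA("preictal") > durA("interictal"))
  }
  expect_gte(hits, 19)
})

test_that("class effects propagate into separable features and vanish
           when the effects are turned off", {
  # full default conditions: dwell, regularity and spectral effects planted
  spec <- syntheticSpec(seed = 57)
  tpl <- MicrostateTemplates(spec$templates,
                             channelLabels = spec$channelLabels)
  proto <- predictionProtocol(nRepetitions = 3, seeds = 0:2)
  ds <- generateDataset(spec, 40)
  feats <- extractFeatures(ds$epochs, tpl)
  rep1 <- runPrediction(assembleFeatures(feats, "fusion"), protocol = proto)
  expect_gte(mean(rep1$perRepetition$auc), 0.9)
  # null effects: dwell multipliers 1, no spectral or regularity shift
  spec0 <- syntheticSpec(seed = 58,
                         classEffects = list(dwellMultipliers = rep(1, 4),
                                             deltaAmpFactor = 1,
                                             thetaAmpFactor = 1,
                                             transitionRegularity = 0,
                                             labelNoiseRate = 0))
  ds0 <- generateDataset(spec0, 25)
  feats0 <- extractFeatures(ds0$epochs, tpl)
  rep0 <- runPrediction(assembleFeatures(feats0, "fusion"), protocol = proto)
  expect_lt(abs(mean(rep0$perRepetition$auc) - 0.5), 0.25)
})
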