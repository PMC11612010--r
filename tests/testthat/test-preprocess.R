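test_that("a common-mode signal vanishes under the average reference", {
  common <- sin(2 * pi * 7 * (0:2499) / 250) * 40
  rec <- EEGRecording(matrix(common, 19, 2500, byrow = TRUE), 250,
                      standardChannels1020())
  out <- preprocessEEG(rec)
  expect_lt(max(abs(recordingData(out))), 1e-9)
})

test_that("preprocessed output is average referenced to machine precision", {
  spec <- quietSpec(seed = 31, snrDb = 10)
  rec <- renderEEG(simulateSequence(spec, 8)$labels, spec)
  out <- preprocessEEG(rec)
  expect_lt(max(abs(colMeans(recordingData(out)))), 1e-9)
  expect_equal(nChannels(out), 19)
  expect_equal(sampleRate(out), 250)
})

test_that("the filter chain attenuates 50 Hz by at least 20 dB", {
  binPower <- function(v, f, fs) {
    P <- Mod(fft(v))^2
    P[round(f * length(v) / fs) + 1]
  }
  s50 <- sin(2 * pi * 50 * (0:4999) / 250)
  rec <- EEGRecording(outer(1:19, s50), 250, standardChannels1020())
  out <- preprocessEEG(rec)
  atten <- 10 * log10(binPower(recordingData(rec)[2, ], 50, 250) /
                      binPower(recordingData(out)[2, ], 50, 250))
  expect_gte(atten, 20)
})

test_that("a spiking channel is replaced by spherical-spline interpolation", {
  spec <- quietSpec(seed = 9, snrDb = Inf)
  rec <- renderEEG(simulateSequence(spec, 20)$labels, spec)
  clean <- recordingData(rec)
  dirty <- clean
  set.seed(2)
  spikes <- sample(ncol(dirty), round(0.3 * ncol(dirty)))
  dirty[5, spikes] <- 200 * sign(rnorm(length(spikes)))
  recD <- rec; recD@data <- dirty
  expect_message(outD <- preprocessEEG(recD), "interpolated")
  outC <- preprocessEEG(rec)
  expect_gt(cor(recordingData(outD)[5, ], recordingData(outC)[5, ]), 0.9)
})

test_that("preprocessing is idempotent up to filter transients", {
  spec <- quietSpec(seed = 4, snrDb = 10)
  rec <- renderEEG(simulateSequence(spec, 12)$labels, spec)
  once <- preprocessEEG(rec)
  twice <- preprocessEEG(once)
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(abs(rms(recordingData(twice)) - rms(recordingData(once))) /
              rms(recordingData(once)), 0.01)
})

test_that("a montage lacking standard channels is rejected", {
  rec <- EEGRecording(matrix(rnorm(10 * 500), 10, 500), 250,
                      standardChannels1020()[1:10])
  expect_error(preprocessEEG(rec), "montage")
})

test_that("segmentation yields floor(duration/L) epochs per interval", {
  mk <- function(durS) {
    n <- durS * 250
    EEGRecording(matrix(rnorm(19 * n), 19, n), 250, standardChannels1020(),
                 annotations = data.frame(onset = 0, duration = durS,
                                          label = "interictal"))
  }
  expect_equal(nEpochs(segmentEpochs(mk(180), 3)), 60)
  expect_equal(suppressMessages(nEpochs(segmentEpochs(mk(181), 3))), 60)
  expect_warning(empty <- segmentEpochs(mk(2), 3), "long enough")
  expect_equal(nEpochs(empty), 0)
})

test_that("epochs inherit interval labels and unlabeled spans are dropped", {
  n <- 30 * 250
  rec <- EEGRecording(matrix(rnorm(19 * n), 19, n), 250,
                      standardChannels1020(),
                      annotations = data.frame(
                        onset = c(0, 18), duration = c(9, 12),
                        label = c("interictal", "preictal")))
  expect_message(ep <- segmentEpochs(rec, 3), "excluded")
  expect_equal(as.vector(table(epochLabels(ep))[c("interictal", "preictal")]),
               c(3, 4))
})

test_that("balancing keeps the chronologically first epochs of each state", {
  n <- 30 * 250
  rec <- EEGRecording(matrix(rnorm(19 * n), 19, n), 250,
                      standardChannels1020(),
                      annotations = data.frame(
                        onset = c(0, 18), duration = c(18, 12),
                        label = c("interictal", "preictal")))
  ep <- segmentEpochs(rec, 3)
  bal <- balanceEpochs(ep)
  expect_equal(as.vector(table(epochLabels(bal))), c(4, 4))
})
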