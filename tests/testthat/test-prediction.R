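mkGaussianFeatures <- function(n, p = 5, shift = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = shift), n, p))
  list(x = x, labels = rep(c("interictal", "preictal"), each = n))
}

test_that("feature assembly selects the documented column families", {
  spec <- quietSpec(seed = 41, snrDb = 15)
  ds <- generateDataset(spec, 4)
  tpl <- MicrostateTemplates(spec$templates,
                             channelLabels = spec$channelLabels)
  feats <- extractFeatures(ds$epochs, tpl)
  expect_equal(ncol(assembleFeatures(feats, "fusion")$x), 23)
  expect_equal(ncol(assembleFeatures(feats, "microstate")$x), 12)
  expect_equal(ncol(assembleFeatures(feats, "nonlinear")$x), 6)
  expect_equal(ncol(assembleFeatures(feats, "spectrum")$x), 5)
  expect_false(anyNA(assembleFeatures(feats, "fusion")$x))
  feats$mPermEn <- NULL
  expect_error(assembleFeatures(feats, "fusion"), "mPermEn")
})

test_that("well-separated classes are classified almost perfectly", {
  fm <- mkGaussianFeatures(60, shift = 3, seed = 2)
  rep <- runPrediction(fm, protocol = predictionProtocol(nRepetitions = 3,
                                                         seeds = 0:2))
  expect_gte(mean(rep$perRepetition$accuracy), 95)
  expect_gte(mean(rep$perRepetition$auc), 0.98)
})

test_that("the protocol sizes the splits as 90/10 stratified", {
  labels <- rep(c("interictal", "preictal"), each = 300)
  sp <- stratifiedSplit(labels, 0.1, seed = 0)
  expect_length(sp$test, 60)
  expect_length(sp$train, 540)
  expect_equal(sum(labels[sp$test] == "preictal"), 30)
  expect_error(stratifiedSplit(c("a", "b"), 0.1, 0), "stratification")
})

test_that("reports are bitwise reproducible given the protocol seeds", {
  fm <- mkGaussianFeatures(30, shift = 1, seed = 3)
  proto <- predictionProtocol(nRepetitions = 2, seeds = 4:5)
  r1 <- runPrediction(fm, protocol = proto)
  r2 <- runPrediction(fm, protocol = proto)
  expect_identical(r1$perRepetition, r2$perRepetition)
})

test_that("held-out information cannot leak into training or tuning", {
  # canary: a feature equal to the class label on the (predetermined) test
  # rows and pure noise elsewhere. A leak-free pipeline gains nothing from
  # it, so performance stays near chance on otherwise uninformative data.
  n <- 60
  fm <- mkGaussianFeatures(n, shift = 0, seed = 6)
  sp <- stratifiedSplit(fm$labels, 0.1, seed = 0)
  canary <- rnorm(2 * n)
  canary[sp$test] <- as.numeric(fm$labels[sp$test] == "preictal")
  fm$x <- cbind(fm$x, canary = canary)
  rep <- runPrediction(fm, protocol = predictionProtocol(nRepetitions = 1,
                                                         seeds = 0))
  expect_lt(rep$perRepetition$accuracy, 85)
})

test_that("metrics match their defining formulas", {
  truth <- c(rep("preictal", 30), rep("interictal", 10))
  pred <- c(rep("preictal", 28), rep("interictal", 2), rep("interictal", 10))
  m <- computeMetrics(truth, pred, scores = NULL, interictalHours = 1)
  expect_equal(m$sensitivity, 100 * 28 / 30, tolerance = 1e-9)
  expect_equal(m$fprPerHour, 0)
  # all correct: FPR 0/h, kappa 100
  m2 <- computeMetrics(truth, truth,
                       scores = c(rep(1, 30), rep(-1, 10)),
                       interictalHours = 2)
  expect_equal(m2$kappa, 100)
  expect_equal(m2$fprPerHour, 0)
  expect_equal(m2$auc, 1)
  # 2 false positives over 2 h of interictal data
  pred3 <- truth; pred3[31:32] <- "preictal"
  m3 <- computeMetrics(truth, pred3, NULL, interictalHours = 2)
  expect_equal(m3$fprPerHour, 1.0)
  expect_error(computeMetrics(rep("preictal", 5), rep("preictal", 5),
                              scores = rnorm(5), interictalHours = 1),
               "single class")
})

test_that("swapping the class labels exchanges sensitivity and specificity", {
  set.seed(7)
  truth <- sample(c("interictal", "preictal"), 50, replace = TRUE)
  pred <- sample(c("interictal", "preictal"), 50, replace = TRUE)
  m <- computeMetrics(truth, pred, NULL, 1)
  swap <- c(interictal = "preictal", preictal = "interictal")
  mSwap <- computeMetrics(swap[truth], swap[pred], NULL, 1)
  expect_equal(m$sensitivity, mSwap$specificity)
  expect_equal(m$specificity, mSwap$sensitivity)
})

test_that("event-merged FPR counts consecutive alarms once", {
  truth <- rep("interictal", 10)
  pred <- c("preictal", "preictal", "preictal", rep("interictal", 4),
            "preictal", "interictal", "interictal")
  m <- computeMetrics(truth, pred, NULL, interictalHours = 1,
                      eventMerged = TRUE)
  expect_equal(m$fprPerHour, 2)
  m2 <- computeMetrics(truth, pred, NULL, interictalHours = 1)
  expect_equal(m2$fprPerHour, 4)
})
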