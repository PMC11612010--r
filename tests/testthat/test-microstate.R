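test_that("GFP is the population spatial standard deviation", {
  expect_equal(computeGFP(matrix(c(5, 5, 5, 5), ncol = 1)), 0)
  expect_equal(computeGFP(matrix(c(1, -1), ncol = 1)), 1)
  expect_equal(computeGFP(matrix(c(2, 0, -2, 0), ncol = 1)), sqrt(2))
  expect_error(computeGFP(matrix(1:5, nrow = 1)), "single channel")
})

test_that("GFP peaks are strict interior local maxima", {
  expect_identical(findGFPPeaks(1:10), integer(0))
  expect_identical(findGFPPeaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  # rectified 10 Hz sinusoid at 250 Hz: peaks every half period (12.5 samples)
  g <- abs(sin(2 * pi * 10 * (0:999) / 250))
  pk <- findGFPPeaks(g)
  expect_equal(mean(diff(pk)), 12.5, tolerance = 0.01)
})

test_that("spatial correlation is Pearson on centred maps, |r| polarity-free", {
  m <- c(3, -1, 2, 0)
  expect_equal(spatialCorrelation(m, m)$absR, 1)
  expect_equal(spatialCorrelation(m, -m)$absR, 1)
  expect_equal(spatialCorrelation(m, -m)$r, -1)
  # orthogonal zero-mean maps
  expect_equal(spatialCorrelation(c(1, -1, 0, 0), c(0, 0, 1, -1))$r, 0)
  expect_error(spatialCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("T-AAHC recovers orthogonal templates and ignores polarity", {
  set.seed(5)
  tpl <- .makeOrthoTemplates(4)
  mapsIn <- tpl[rep(1:4, each = 50), ]
  fit <- taahcCluster(mapsIn, 4)
  mt <- matchTemplates(fit, tpl)
  expect_true(all(mt$absR > 1 - 1e-9))
  # flip half the copies: identical clusters
  flip <- rep(c(1, -1), 100)
  fit2 <- taahcCluster(mapsIn * flip, 4)
  mt2 <- matchTemplates(fit2, fit)
  expect_true(all(mt2$absR > 1 - 1e-9))
  expect_equal(gev(fit2), gev(fit), tolerance = 1e-12)
  expect_error(taahcCluster(mapsIn, 0), "parameter")
  expect_error(taahcCluster(mapsIn, 500), "parameter")
})

test_that("T-AAHC centroids match planted templates under 20 dB noise", {
  spec <- quietSpec(seed = 13, snrDb = 20)
  rec <- renderEEG(simulateSequence(spec, 30)$labels, spec)
  pm <- peakMaps(recordingData(rec), 300)
  fit <- taahcCluster(pm$maps, 4, gfp = pm$gfp)
  expect_gte(min(matchTemplates(fit, spec$templates)$absR), 0.95)
})

test_that("clustering results are invariant to sign flips of any subset", {
  set.seed(17)
  spec <- quietSpec(seed = 17, snrDb = 15)
  rec <- renderEEG(simulateSequence(spec, 10)$labels, spec)
  pm <- peakMaps(recordingData(rec), 120)
  flip <- sample(c(-1, 1), nrow(pm$maps), replace = TRUE)
  a <- taahcCluster(pm$maps, 4, gfp = pm$gfp)
  b <- taahcCluster(pm$maps * flip, 4, gfp = pm$gfp)
  expect_equal(gev(a), gev(b), tolerance = 1e-12)
  expect_true(all(matchTemplates(a, b)$absR > 1 - 1e-9))
  expect_identical(attr(a, "assignments"), attr(b, "assignments"))
})

test_that("GEV is non-decreasing in the number of classes", {
  spec <- quietSpec(seed = 23, snrDb = 10)
  rec <- renderEEG(simulateSequence(spec, 15)$labels, spec)
  pm <- peakMaps(recordingData(rec), 200)
  gevs <- vapply(2:7, function(k)
    gev(taahcCluster(pm$maps, k, gfp = pm$gfp)), numeric(1))
  expect_true(all(diff(gevs) > -1e-9))
})

test_that("backfitting a noise-free rendering recovers the planted labels", {
  spec <- quietSpec(seed = 7, snrDb = Inf)
  sim <- simulateSequence(spec, 10)
  rec <- renderEEG(sim$labels, spec)
  tpl <- MicrostateTemplates(spec$templates,
                             channelLabels = spec$channelLabels)
  sq <- backfit(tpl, recordingData(rec), sampleRate = 250)
  est <- stateLabels(sq)
  assigned <- est > 0L
  expect_gt(mean(assigned), 0.95)       # only carrier zero crossings drop out
  expect_true(all(est[assigned] == sim$labels[assigned]))
  # sign-flipped rendering: identical labels
  sq2 <- backfit(tpl, -recordingData(rec), sampleRate = 250)
  expect_identical(stateLabels(sq2), est)
})

test_that("samples orthogonal to every template stay unassigned", {
  set.seed(11)
  tplM <- .makeOrthoTemplates(4, nChannels = 19)
  # build a vector orthogonal to the 4 templates (and zero-mean)
  basis <- rbind(tplM, 1)
  v <- rnorm(19)
  v <- v - t(basis) %*% solve(tcrossprod(basis), basis %*% v)
  tpl <- MicrostateTemplates(tplM)
  sq <- backfit(tpl, matrix(v, ncol = 1), sampleRate = 250)
  expect_identical(stateLabels(sq), 0L)
  expect_error(backfit(tpl, matrix(rnorm(10), 10, 1), 250), "montage")
})

test_that("short segments are halved into their neighbours", {
  # 8-sample floor at 250 Hz; 6-sample run: 3 to each side
  s <- smoothSequence(mkSeq(c(rep(1, 20), rep(2, 6), rep(3, 20))))
  r <- rle(stateLabels(s))
  expect_identical(r$values, c(1L, 3L))
  expect_identical(r$lengths, c(23L, 23L))
  # 5-sample run: ceil half (3) to the preceding, 2 to the following
  s <- smoothSequence(mkSeq(c(rep(1, 20), rep(2, 5), rep(3, 20))))
  r <- rle(stateLabels(s))
  expect_identical(r$lengths, c(23L, 22L))
  # all runs at or above the floor: unchanged
  lab <- c(rep(1L, 8), rep(2L, 8), rep(1L, 8))
  expect_identical(stateLabels(smoothSequence(mkSeq(lab))), lab)
  # boundary short run goes wholly to its single neighbour
  s <- smoothSequence(mkSeq(c(rep(2, 4), rep(1, 20))))
  expect_identical(unique(stateLabels(s)), 1L)
})

test_that("smoothing never invents labels and unassigned cannot absorb", {
  set.seed(3)
  for (i in 1:20) {
    lab <- sample(0:3, 200, replace = TRUE, prob = c(0.1, 0.3, 0.3, 0.3))
    sm <- stateLabels(smoothSequence(mkSeq(lab, k = 3)))
    expect_true(all(sm %in% unique(lab)))
  }
  # a short class run between unassigned stretches goes to the class side only
  lab <- c(rep(0L, 20), rep(1L, 4), rep(2L, 20))
  sm <- stateLabels(smoothSequence(mkSeq(lab, k = 2)))
  expect_identical(sm, c(rep(0L, 20), rep(2L, 24)))
})

test_that("microstate parameters satisfy their accounting identities", {
  p <- microstateParameters(mkSeq(rep(1, 750), k = 1))
  expect_equal(p$meanDurationMs, 3000)
  expect_equal(p$coverage, 1)
  expect_equal(p$occurrencePerS, 1 / 3)
  p <- microstateParameters(mkSeq(rep(c(rep(1, 25), rep(2, 25)), 15), k = 2))
  expect_equal(p$meanDurationMs, c(100, 100))
  expect_equal(p$coverage, c(0.5, 0.5))
  expect_equal(p$occurrencePerS, c(5, 5))
  # coverage sums to 1 and occurrence x duration = coverage x 1000
  set.seed(4)
  lab <- sample(0:4, 5000, replace = TRUE)
  p <- microstateParameters(mkSeq(lab, k = 4))
  expect_equal(sum(p$coverage) + attr(p, "unassignedCoverage"), 1,
               tolerance = 1e-9)
  expect_equal(p$occurrencePerS * p$meanDurationMs, p$coverage * 1000,
               tolerance = 1e-9)
  # absent classes flagged as zeros
  p <- microstateParameters(mkSeq(rep(1L, 100), k = 4))
  expect_identical(attr(p, "absentClasses"), 2:4)
  expect_equal(p$meanDurationMs[2:4], rep(0, 3))
})

test_that("identical maps trigger the degenerate k-selection path", {
  m <- matrix(rep(c(1, -1, 2, 0, -2), 40), 40, 5, byrow = TRUE)
  expect_warning(sel <- selectOptimalK(m, kRange = 3:5), "degenerate")
  expect_equal(sel$k, 3)
})

test_that("group clustering pools individual templates at fixed k", {
  set.seed(19)
  base <- .makeOrthoTemplates(4)
  indiv <- lapply(1:3, function(i)
    MicrostateTemplates(base + matrix(rnorm(4 * 19, sd = 0.05), 4, 19)))
  grp <- groupTemplates(indiv, k = 4)
  expect_equal(grp@level, "group")
  expect_gte(min(matchTemplates(grp, base)$absR), 0.95)
})
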