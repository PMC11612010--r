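test_that("binarization follows the >= threshold convention", {
  expect_identical(binarizeSignal(c(1, 2, 3, 4), "mean"), c(0L, 0L, 1L, 1L))
  expect_identical(binarizeSignal(c(1, 2, 3, 100), "mid_p"), c(0L, 0L, 0L, 1L))
  expect_identical(binarizeSignal(c(7, 7, 7), "mean"), c(1L, 1L, 1L))
  expect_identical(binarizeSignal(c(7, 7, 7), "mid_p"), c(1L, 1L, 1L))
  expect_error(binarizeSignal(5), "short")
})

test_that("LZ76 counts match the exhaustive-parsing oracle on samples", {
  # exhaustive length-7 binary plus random longer draws
  g <- allSequences(0:1, 7)
  for (i in seq_len(nrow(g)))
    expect_identical(lzComplexity(g[i, ])$patternCount, lz76Naive(g[i, ]))
  set.seed(1)
  for (i in 1:50) {
    s <- sample(0:1, sample(20:120, 1), replace = TRUE)
    expect_identical(lzComplexity(s)$patternCount, lz76Naive(s))
  }
  # the classic worked example, normalization N / log2 N with N = 16
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  cw <- lz76Naive(s)
  res <- lzComplexity(s)
  expect_identical(res$patternCount, cw)
  expect_equal(res$normalized, cw * 4 / 16)
})

test_that("a constant sequence is minimally complex at its length", {
  # no length-8 sequence parses into fewer words than the constant one
  # (some, e.g. 0000ABC1, tie it at two words)
  cwConst <- lzComplexity(rep(0L, 8))$patternCount
  g <- allSequences(0:1, 8)
  mixed <- g[rowSums(g) %in% 1:7, , drop = FALSE]
  cws <- apply(mixed, 1, function(s) lzComplexity(s)$patternCount)
  expect_true(all(cws >= cwConst))
  expect_gt(mean(cws), cwConst)
})

test_that("normalized LZC does not grow under constant extension", {
  set.seed(2)
  for (i in 1:20) {
    s <- sample(0:1, 40, replace = TRUE)
    ext <- c(s, rep(s[40], 20))
    expect_gte(lzComplexity(s)$normalized, lzComplexity(ext)$normalized)
  }
})

test_that("mLZC parses the 4-letter alphabet with alphabet-base scaling", {
  expect_error(mStateLZC(c(1, 0, 2)), "unassigned")
  set.seed(3)
  for (i in 1:50) {
    s <- sample(1:4, sample(8:60, 1), replace = TRUE)
    r <- mStateLZC(s)
    expect_identical(r$patternCount, lz76Naive(s))
    expect_equal(r$normalized,
                 r$patternCount / (length(s) / log(length(s), 4)))
  }
  # periodic vs random at equal length: periodic strictly simpler
  periodic <- rep(1:4, 50)
  set.seed(4)
  rand <- sample(1:4, 200, replace = TRUE)
  expect_lt(mStateLZC(periodic)$patternCount, mStateLZC(rand)$patternCount)
  # log2 option reproduces the binary-alphabet literal form
  # (log2 N = 2 log4 N, so the value doubles)
  expect_equal(mStateLZC(periodic, logBase = 2)$normalized,
               2 * mStateLZC(periodic)$normalized)
})

test_that("permutation entropy matches hand enumeration and analytics", {
  expect_equal(permutationEntropy(1:50, ordinalConfig(3, 1)), 0)
  expect_equal(permutationEntropy(seq(0, 1, length.out = 30),
                                  ordinalConfig(4, 2)), 0)
  # 7-point example, m = 2: 4 ascents, 2 descents among the 6 pairs
  pe <- permutationEntropy(c(4, 7, 9, 10, 6, 11, 3), ordinalConfig(2, 1))
  expect_equal(pe, (-(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)) / log(2),
               tolerance = 1e-12)
  expect_error(permutationEntropy(c(1, 2), ordinalConfig(4, 1)), "length")
})

test_that("permutation entropy is invariant under monotone transforms", {
  set.seed(5)
  x <- rnorm(500)
  for (f in list(function(v) 3 * v + 2, exp, function(v) v^3)) {
    expect_equal(permutationEntropy(f(x), ordinalConfig(3, 1)),
                 permutationEntropy(x, ordinalConfig(3, 1)))
  }
})

test_that("adjacent deduplication drops repeats and is idempotent", {
  expect_identical(dedupAdjacent(c(1, 1, 2, 2, 3)), c(1L, 2L, 3L))
  expect_identical(dedupAdjacent(c(1, 2, 1, 2)), c(1L, 2L, 1L, 2L))
  expect_identical(dedupAdjacent(c(2, 2, 2)), 2L)
  set.seed(6)
  s <- sample(1:4, 300, replace = TRUE)
  expect_identical(dedupAdjacent(dedupAdjacent(s)), dedupAdjacent(s))
})

test_that("the state-pattern matrix enumerates all m-tuples once", {
  expect_identical(statePatternMatrix(2),
                   matrix(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L), 4, 2))
  for (m in 2:4) {
    X <- statePatternMatrix(m)
    expect_identical(dim(X), as.integer(c(m^m, m)))
    expect_equal(nrow(unique(X)), m^m)
    expect_true(all(X >= 1 & X <= m))
  }
})

test_that("mPermEn reproduces the alternating-sequence hand enumeration", {
  # alternating 1,2 with an even embedded-window count: the two tuples
  # (1,2,1,2) and (2,1,2,1) are exactly equiprobable, H = ln 2
  v <- mStatePermEn(rep_len(c(1L, 2L), 199), m = 4, tau = 1)
  expect_equal(attr(v, "entropy"), log(2), tolerance = 1e-12)
  expect_equal(as.numeric(v), log(2) / log(256), tolerance = 1e-12)
  # a constant sequence collapses to length 1 under dedup
  expect_error(mStatePermEn(rep(2L, 50), m = 4), "length")
  # factorial normalization option
  vf <- mStatePermEn(rep_len(c(1L, 2L), 199), m = 4,
                     normalization = "factorial")
  expect_equal(as.numeric(vf), log(2) / log(24), tolerance = 1e-12)
})

test_that("mPermEn of uniform random labels approaches ln(108)/ln(256)", {
  # after dedup the first state is free (4 ways) and each later one avoids
  # its predecessor (3 ways): 4 * 3^3 = 108 equiprobable reachable tuples
  set.seed(8)
  lab <- sample.int(4, 1e5, replace = TRUE)
  v <- as.numeric(mStatePermEn(lab, m = 4, tau = 1))
  expect_equal(v, log(108) / log(256), tolerance = 0.005)
})

test_that("mPermEn is invariant under relabeling of the classes", {
  set.seed(9)
  for (i in 1:20) {
    s <- sample(1:4, 150, replace = TRUE)
    perm <- sample(4)
    expect_equal(as.numeric(mStatePermEn(perm[s], m = 4)),
                 as.numeric(mStatePermEn(s, m = 4)), tolerance = 1e-12)
  }
})

test_that("normalized complexity values stay in the unit interval", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(400)
    expect_gte(permutationEntropy(x, ordinalConfig(3, 1)), 0)
    expect_lte(permutationEntropy(x, ordinalConfig(3, 1)), 1)
    s <- sample(1:4, 400, replace = TRUE)
    v <- as.numeric(mStatePermEn(s, m = 4))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})
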