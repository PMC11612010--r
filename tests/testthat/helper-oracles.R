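# Independent oracles and small fixture builders used across the suite.

# Brute-force LZ76 exhaustive parsing: a component ends as soon as the
# current word stops being a substring of everything before its last symbol.
# Character/substring based, fully independent of the compiled counter.
lz76Naive <- function(s) {
  chr <- paste(letters[s - min(s) + 1L], collapse = "")
  n <- nchar(chr)
  cw <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n &&
           grepl(substr(chr, l, l + k - 1L), substr(chr, 1, l + k - 2L),
                 fixed = TRUE))
      k <- k + 1L
    cw <- cw + 1L
    l <- l + k
  }
  cw
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (no ties/zeros assumed).
wilcoxonExactOracle <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% rk
  min(1, 2 * min(mean(Vs <= v), mean(Vs >= v)))
}

# all sequences over `alphabet` of length n, one per row
allSequences <- function(alphabet, n)
  as.matrix(expand.grid(rep(list(alphabet), n)))

mkSeq <- function(labels, rate = 250, k = max(labels, 1L))
  MicrostateSequence(labels, sampleRate = rate, k = k)

# quiet spec without background oscillations (template signal + noise only)
quietSpec <- function(seed, snrDb = 20, k = 4, ...)
  syntheticSpec(seed = seed, snrDb = snrDb, k = k,
                oscillations = data.frame(freqHz = numeric(0),
                                          amplitudeUV = numeric(0)), ...)

# orthonormal zero-mean topographies (independent of the generator's basis)
.makeOrthoTemplates <- function(k, nChannels = 19) {
  m <- matrix(rnorm(k * nChannels), k, nChannels)
  m <- m - rowMeans(m)
  t(qr.Q(qr(t(m)))[, seq_len(k)])
}

# GFP-peak maps of a recording, subsampled to at most nMax
peakMaps <- function(x, nMax = 500) {
  g <- computeGFP(x)
  pk <- findGFPPeaks(g)
  pk <- pk[round(seq(1, length(pk), length.out = min(nMax, length(pk))))]
  list(maps = t(x[, pk, drop = FALSE]), gfp = g[pk])
}
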