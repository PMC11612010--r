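#' @include classes.R
NULL

#' Binarize a signal around a threshold
#'
#' Symbols are `1` where the sample is greater than or equal to the
#' threshold and `0` below it. Thresholds: `mean`, `median`, or `mid_p`
#' (the mean of the signal minimum and maximum). A constant signal yields
#' all ones under any threshold (the >= convention).
#'
#' @param x numeric signal (length >= 2).
#' @param threshold one of "mean", "median", "mid_p".
#' @return integer vector of 0/1 symbols.
#' @examples
#' binarizeSignal(c(1, 2, 3, 4), "mean")   # 0 0 1 1
#' @export
binarizeSignal <- function(x, threshold = c("mean", "median", "mid_p")) {
  threshold <- match.arg(threshold)
  if (length(x) < 2) stop("signal too short to binarize")
  td <- switch(threshold,
               mean = mean(x),
               median = median(x),
               mid_p = mean(c(min(x), max(x))))
  as.integer(x >= td)
}

#' Lempel-Ziv complexity of a symbol sequence
#'
#' Counts the incompressible words `C_w` of the LZ76 exhaustive parsing
#' (the trailing incomplete word counts as one) and normalizes by the
#' asymptotic count of a random sequence: `LZC = C_w / (N / log_b N)` with
#' `b` the alphabet size. Lower values mean more repetitive structure.
#'
#' @param symbols integer symbol vector (any finite alphabet after 0-based
#'   or 1-based coding; only equality matters).
#' @param alphabetSize alphabet size; 2 for binarized EEG.
#' @param logBase base of the normalizing logarithm; defaults to the
#'   alphabet size.
#' @return list with `patternCount` (C_w), `sequenceLength` (N) and
#'   `normalized`.
#' @export
lzComplexity <- function(symbols, alphabetSize = 2, logBase = alphabetSize) {
  symbols <- as.integer(symbols)
  n <- length(symbols)
  if (n < 2) stop("length error: need at least 2 symbols")
  cw <- .lz76Count(symbols)
  list(patternCount = cw, sequenceLength = n,
       normalized = cw / (n / log(n, base = logBase)))
}

#' Microstate-based Lempel-Ziv complexity (mLZC)
#'
#' LZ76 complexity of the microstate label sequence over its 4-letter (in
#' general k-letter) alphabet, quantifying the repeatability of the
#' succession of cognitive states rather than of voltage values. The
#' normalization uses the alphabet-size logarithm by default (`logBase =
#' k`); set `logBase = 2` for the binary-alphabet literal form.
#'
#' @param seq a [MicrostateSequence-class] or an integer label vector in
#'   `1..k`. Unassigned samples (label 0) are a precondition violation:
#'   drop or fill them first (see [extractFeatures()]).
#' @param k alphabet size (number of microstate classes).
#' @param logBase normalizing logarithm base.
#' @return list as in [lzComplexity()].
#' @export
mStateLZC <- function(seq, k = 4, logBase = k) {
  lab <- if (is(seq, "MicrostateSequence")) stateLabels(seq) else as.integer(seq)
  if (any(lab < 1L | lab > k))
    stop("precondition error: labels must lie in 1..", k,
         " (drop unassigned samples first)")
  lzComplexity(lab, alphabetSize = k, logBase = logBase)
}

#' Ordinal-pattern configuration
#' @param m embedding dimension (>= 2).
#' @param tau time delay (>= 1).
#' @return list of class `OrdinalConfig`.
#' @export
ordinalConfig <- function(m = 4, tau = 1) {
  if (m < 2) stop("embedding dimension m must be >= 2")
  if (tau < 1) stop("time delay tau must be >= 1")
  structure(list(m = as.integer(m), tau = as.integer(tau)),
            class = "OrdinalConfig")
}

# ordinal pattern keys of the delay embedding, vectorized: each window is
# encoded by its pairwise comparison bits (x_j < x_i for i < j), which
# uniquely identify the ascending-order permutation under the stable
# (earlier-index-first) tie rule. Keys are arbitrary but bijective with
# patterns, which is all a pattern distribution needs.
.ordinalKeys <- function(x, m, tau) {
  n <- length(x)
  K <- n - (m - 1L) * tau
  if (K < 1) stop("length error: signal too short for m = ", m,
                  ", tau = ", tau, " (length ", n, ")")
  cols <- lapply(seq_len(m) - 1L, function(j) x[(1L + j * tau):(K + j * tau)])
  key <- numeric(K)
  b <- 1
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    key <- key + b * (cols[[j]] < cols[[i]])
    b <- b * 2
  }
  key
}

.patternEntropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal (rank-order) patterns of
#' the delay embedding, normalized by `ln(m!)` so the value lies in
#' `[0, 1]`. Ties are broken by time order (stable sort), and monotone
#' transformations of the signal leave the value unchanged.
#'
#' @param x numeric signal.
#' @param config an [ordinalConfig()]; EEG default m = 4, tau = 1.
#' @return normalized permutation entropy in `[0, 1]`.
#' @examples
#' permutationEntropy(1:100, ordinalConfig(3, 1))  # 0: a single pattern
#' @export
permutationEntropy <- function(x, config = ordinalConfig()) {
  m <- config$m; tau <- config$tau
  keys <- .ordinalKeys(as.numeric(x), m, tau)
  H <- .patternEntropy(table(keys))
  H / log(factorial(m))
}

#' Collapse adjacent repeats of a microstate sequence
#'
#' Removes consecutive samples belonging to the same microstate class,
#' leaving the sequence of visited states (`ms(u) != ms(u+1)`). Idempotent.
#'
#' @param seq a [MicrostateSequence-class] or integer label vector.
#' @return integer vector of deduplicated labels.
#' @examples
#' dedupAdjacent(c(1, 1, 2, 2, 3))  # 1 2 3
#' @export
dedupAdjacent <- function(seq) {
  lab <- if (is(seq, "MicrostateSequence")) stateLabels(seq) else as.integer(seq)
  if (!length(lab)) return(integer(0))
  lab[c(TRUE, diff(lab) != 0L)]
}

#' State-pattern matrix for microstate permutation entropy
#'
#' Enumerates all `m^m` ordered m-tuples over the alphabet `{1..m}` as the
#' rows of an `m^m x m` matrix, row j given by
#' `a_jh = ceiling(j / m^(m-h)) mod m` with 0 remapped to m. Every embedded
#' window of a microstate sequence matches exactly one row.
#'
#' @param m number of microstate classes (>= 2).
#' @return integer matrix `m^m x m`.
#' @export
statePatternMatrix <- function(m) {
  if (m < 2) stop("m must be >= 2")
  j <- seq_len(m^m)
  X <- vapply(seq_len(m), function(h) {
    a <- ceiling(j / m^(m - h)) %% m
    a[a == 0] <- m
    as.integer(a)
  }, integer(m^m))
  X
}

# row index of each embedded m-tuple in the state-pattern matrix
.statePatternIndex <- function(tuples, m) {
  # tuples: K x m matrix of labels in 1..m; positional code inverse of
  # statePatternMatrix's formula
  pow <- m^((m - 1L):0L)
  as.integer((tuples - 1L) %*% pow + 1L)
}

#' Microstate-based permutation entropy (mPermEn)
#'
#' Entropy of the distribution of state patterns in the deduplicated
#' microstate sequence: adjacent repeats are removed (see
#' [dedupAdjacent()]), the sequence is delay-embedded with `m` equal to the
#' number of classes, each embedded tuple is matched to its row of the
#' state-pattern matrix, and the Shannon entropy of the resulting index
#' distribution is normalized. The default normalization is `ln(m^m)` (the
#' size of the state-pattern space, so the value cannot exceed 1);
#' `normalization = "factorial"` divides by `ln(m!)` instead.
#'
#' @param seq a [MicrostateSequence-class] or integer label vector in
#'   `1..m`.
#' @param m number of microstate classes (embedding dimension).
#' @param tau time delay.
#' @param normalization "power" for `ln(m^m)` or "factorial" for `ln(m!)`.
#' @return normalized entropy; the unnormalized Shannon entropy and the
#'   pattern counts are attached as attributes `entropy` and `counts`.
#' @export
mStatePermEn <- function(seq, m = 4, tau = 1,
                         normalization = c("power", "factorial")) {
  normalization <- match.arg(normalization)
  lab <- dedupAdjacent(seq)
  if (any(lab < 1L | lab > m))
    stop("labels must lie in 1..", m, " (drop unassigned samples first)")
  U <- length(lab)
  K <- U - (m - 1L) * tau
  if (K < 1)
    stop("length error: deduplicated sequence too short (length ", U,
         ", need at least ", m + (m - 1L) * tau, ")")
  tuples <- vapply(seq_len(m) - 1L,
                   function(h) lab[(1L + h * tau):(K + h * tau)],
                   integer(K))
  if (K == 1) tuples <- matrix(tuples, nrow = 1)
  idx <- .statePatternIndex(tuples, m)
  counts <- table(idx)
  H <- .patternEntropy(counts)
  denom <- if (normalization == "power") log(m^m) else log(factorial(m))
  structure(H / denom, entropy = H, counts = counts)
}

#' Per-epoch nonlinear feature set
#'
#' The six nonlinear features of one epoch: three EEG-based Lempel-Ziv
#' complexities (mean, median and mid-range thresholds) and the EEG-based
#' permutation entropy, each computed per channel and averaged across
#' channels; plus the microstate-based mLZC and mPermEn computed on the
#' epoch's microstate sequence (unassigned samples dropped).
#'
#' @param epoch channels x samples matrix.
#' @param seq the epoch's [MicrostateSequence-class].
#' @param config ordinal configuration for the EEG permutation entropy.
#' @param k number of microstate classes.
#' @return named numeric vector `LZC_mean`, `LZC_median`, `LZC_mid_p`,
#'   `mLZC`, `PermEn`, `mPermEn`.
#' @export
complexityFeatures <- function(epoch, seq, config = ordinalConfig(4, 1),
                               k = nStates(seq)) {
  epoch <- as.matrix(epoch)
  perCh <- function(f) mean(apply(epoch, 1, f))
  lzc <- function(kind) perCh(function(ch)
    lzComplexity(binarizeSignal(ch, kind))$normalized)
  lab <- stateLabels(seq)
  lab <- lab[lab > 0L]
  if (!length(lab)) stop("no assigned samples in the microstate sequence")
  c(LZC_mean = lzc("mean"),
    LZC_median = lzc("median"),
    LZC_mid_p = lzc("mid_p"),
    mLZC = mStateLZC(lab, k = k)$normalized,
    PermEn = perCh(function(ch) permutationEntropy(ch, config)),
    mPermEn = as.numeric(mStatePermEn(lab, m = k, tau = config$tau)))
}
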