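#' @include classes.R
NULL

#' Global field power
#'
#' The per-sample spatial standard deviation across electrodes,
#' `GFP(x) = sqrt( sum_i (V_i - Vbar)^2 / n )` with `n` channels. GFP peaks
#' mark moments of high topographic signal-to-noise and supply the maps used
#' for microstate clustering.
#'
#' @param epoch channels x samples numeric matrix.
#' @return numeric vector of per-sample GFP values (same length as the
#'   sample count).
#' @examples
#' computeGFP(matrix(c(2, 0, -2, 0), ncol = 1))  # sqrt(2)
#' @export
computeGFP <- function(epoch) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 2)
    stop("GFP is undefined for a single channel (no spatial variance)")
  mu <- colMeans(epoch)
  sqrt(colMeans(sweep(epoch, 2, mu)^2))
}

#' Find GFP peaks
#'
#' Strict local maxima of a GFP series: samples greater than both immediate
#' neighbours. Endpoints are never peaks.
#'
#' @param gfp numeric GFP series (length >= 3 for any peak to exist).
#' @return integer vector of peak positions (1-based indices); possibly
#'   empty.
#' @export
findGFPPeaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[gfp[i] > gfp[i - 1] & gfp[i] > gfp[i + 1]]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the average-referenced maps. The
#' polarity-invariant similarity used throughout microstate analysis is the
#' absolute value `absR`.
#'
#' @param mapA,mapB numeric vectors of equal length (>= 2 channels).
#' @return list with components `r` (signed) and `absR`.
#' @export
spatialCorrelation <- function(mapA, mapB) {
  if (length(mapA) != length(mapB))
    stop("maps must have the same channel count")
  if (length(mapA) < 2) stop("need at least 2 channels")
  a <- mapA - mean(mapA); b <- mapB - mean(mapB)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined correlation: zero-variance map")
  r <- sum(a * b) / (na * nb)
  list(r = r, absR = abs(r))
}

# centre rows, drop zero-variance maps, return unit-norm maps + map GFP
.normalizeMaps <- function(maps) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  keep <- nrm > 0
  list(maps = maps[keep, , drop = FALSE] / nrm[keep],
       gfp = nrm[keep] / sqrt(ncol(maps)), keep = keep)
}

# T-AAHC engine. Starts from singleton clusters; repeatedly atomizes the
# cluster contributing least GEV and reassigns each freed map to the cluster
# whose centroid it correlates with best (polarity-invariant). Centroids are
# the dominant eigenvector of the member outer-product sum, so every result
# is invariant to sign flips of any subset of input maps. Snapshots of the
# clustering state are recorded at each requested k.
.taahcEngine <- function(maps, gfp = NULL, kSnapshots) {
  nm <- .normalizeMaps(maps)
  M <- nm$maps
  if (is.null(gfp)) gfp <- nm$gfp else gfp <- gfp[nm$keep]
  n <- nrow(M)
  w <- gfp^2
  totW <- sum(w)
  kSnapshots <- sort(unique(pmin(pmax(kSnapshots, 1L), n)))
  assign <- seq_len(n)
  active <- rep(TRUE, n)
  scatter <- lapply(seq_len(n), function(i) tcrossprod(M[i, ]))
  centroid <- t(M)                      # channels x clusterId
  r <- rep(1, n)                        # |corr| of map to its centroid
  contrib <- w                          # per-cluster GEV contribution
  snapshots <- list()
  snap <- function() {
    ids <- which(active)
    list(clusterIds = ids, assign = assign,
         centroids = centroid[, ids, drop = FALSE],
         r = r, gev = sum(w * r^2) / totW, W = sum(w * (1 - r^2)))
  }
  nAct <- n
  if (nAct %in% kSnapshots) snapshots[[as.character(nAct)]] <- snap()
  while (nAct > min(kSnapshots)) {
    ids <- which(active)
    victim <- ids[which.min(contrib[ids])]      # ties: lowest index
    active[victim] <- FALSE
    nAct <- nAct - 1L
    members <- which(assign == victim)
    ids <- which(active)
    Rm <- abs(crossprod(centroid[, ids, drop = FALSE],
                        t(M[members, , drop = FALSE])))   # k x m
    best <- ids[max.col(t(Rm), ties.method = "first")]
    assign[members] <- best
    for (cid in unique(best)) {
      newM <- members[best == cid]
      scatter[[cid]] <- scatter[[cid]] + crossprod(M[newM, , drop = FALSE])
      centroid[, cid] <- eigen(scatter[[cid]], symmetric = TRUE)$vectors[, 1]
      mem <- which(assign == cid)
      r[mem] <- abs(M[mem, , drop = FALSE] %*% centroid[, cid])
      contrib[cid] <- sum(w[mem] * r[mem]^2)
    }
    if (nAct %in% kSnapshots) snapshots[[as.character(nAct)]] <- snap()
  }
  list(snapshots = snapshots, maps = M, gfp = gfp, w = w, totW = totW)
}

.templatesFromSnapshot <- function(sn, channelLabels, level) {
  tpl <- MicrostateTemplates(t(sn$centroids), gev = sn$gev, level = level,
                             channelLabels = channelLabels)
  attr(tpl, "assignments") <- match(sn$assign, sn$clusterIds)
  tpl
}

#' Topographic atomize & agglomerate hierarchical clustering (T-AAHC)
#'
#' Clusters a set of scalp topographies (typically maps at GFP peaks) into
#' `k` polarity-free microstate classes. Starting from singleton clusters,
#' the cluster contributing least to the global explained variance (GEV) is
#' dissolved and each of its maps is reassigned to the cluster with which it
#' has the highest absolute spatial correlation; this repeats until `k`
#' clusters remain. Cluster centroids are the dominant eigenvector of the
#' member outer-product sum, which makes the whole procedure invariant to
#' the polarity of the input maps. GEV is weighted by the squared GFP of
#' each map.
#'
#' @param peakMaps n_maps x n_channels matrix of topographies.
#' @param k target number of classes (1 <= k <= n_maps).
#' @param gfp optional per-map GFP weights; defaults to each map's own GFP.
#' @param level "individual" or "group" (bookkeeping only).
#' @return a [MicrostateTemplates-class]; the attribute `assignments` holds
#'   the cluster index (1..k) of every input map.
#' @export
taahcCluster <- function(peakMaps, k, gfp = NULL, level = "individual") {
  peakMaps <- as.matrix(peakMaps)
  if (k < 1 || k > nrow(peakMaps))
    stop("parameter error: k must lie in 1..", nrow(peakMaps))
  eng <- .taahcEngine(peakMaps, gfp, kSnapshots = k)
  sn <- eng$snapshots[[as.character(k)]]
  labs <- colnames(peakMaps)
  if (is.null(labs)) labs <- paste0("ch", seq_len(ncol(peakMaps)))
  .templatesFromSnapshot(sn, labs, level)
}

# mean silhouette width with the polarity-invariant distance d = 1 - |r|
.meanSilhouette <- function(D, cl) {
  ids <- unique(cl)
  if (length(ids) < 2) return(0)
  s <- numeric(length(cl))
  for (i in seq_along(cl)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ids, cl[i]),
                    function(cid) mean(D[i, cl == cid]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the optimal number of microstate classes
#'
#' Fits T-AAHC for every `k` in `kRange` (one agglomeration pass yields them
#' all) and picks the `k` with the best median rank across three normalized
#' criteria: the GEV elbow (negative second difference of the GEV curve),
#' the polarity-invariant mean silhouette with distance `1 - |r|`, and a
#' Krzanowski-Lai-style ratio of successive dispersion differences. One k on
#' each side of `kRange` is fitted internally so the elbow and ratio are
#' defined at the range boundaries. Ties favour the higher silhouette, then
#' the smaller k.
#'
#' @param peakMaps n_maps x n_channels matrix of topographies.
#' @param kRange integer range of candidate class counts.
#' @param gfp optional per-map GFP weights.
#' @param maxSilhouetteMaps subsample cap for the silhouette distance matrix.
#' @return list with `k` (chosen), `templates` (fit at the chosen k),
#'   `perK` (templates for each k in `kRange`) and `criteria` (a data.frame
#'   of the per-k criterion values and ranks).
#' @export
selectOptimalK <- function(peakMaps, kRange = 3:8, gfp = NULL,
                           maxSilhouetteMaps = 300) {
  peakMaps <- as.matrix(peakMaps)
  kRange <- sort(unique(as.integer(kRange)))
  nm <- .normalizeMaps(peakMaps)
  n <- nrow(nm$maps)
  if (max(kRange) > n) stop("not enough maps for k = ", max(kRange))
  # degenerate data: every map equal (up to sign) to the first
  r1 <- abs(nm$maps %*% nm$maps[1, ])
  if (all(r1 > 1 - 1e-9)) {
    warning("degenerate data: all maps identical; returning k = ", min(kRange))
    k <- min(kRange)
    return(list(k = k, templates = taahcCluster(peakMaps, k, gfp),
                perK = NULL, criteria = NULL))
  }
  kFit <- (min(kRange) - 1L):(max(kRange) + 1L)
  kFit <- kFit[kFit >= 2 & kFit <= n - 1]
  eng <- .taahcEngine(peakMaps, gfp, kSnapshots = kFit)
  gevK <- vapply(kFit, function(k) eng$snapshots[[as.character(k)]]$gev, numeric(1))
  WK <- vapply(kFit, function(k) eng$snapshots[[as.character(k)]]$W, numeric(1))
  names(gevK) <- names(WK) <- kFit
  # silhouette on a subsample
  sub <- if (n > maxSilhouetteMaps)
    round(seq(1, n, length.out = maxSilhouetteMaps)) else seq_len(n)
  D <- 1 - abs(tcrossprod(eng$maps[sub, , drop = FALSE]))
  getv <- function(vec, k) if (as.character(k) %in% names(vec)) vec[[as.character(k)]] else NA_real_
  p <- ncol(peakMaps)
  crit <- data.frame(k = kRange)
  crit$gev <- vapply(kRange, function(k) getv(gevK, k), numeric(1))
  crit$elbow <- vapply(kRange, function(k) {
    g0 <- getv(gevK, k - 1); g1 <- getv(gevK, k); g2 <- getv(gevK, k + 1)
    -(g2 + g0 - 2 * g1)
  }, numeric(1))
  crit$silhouette <- vapply(kRange, function(k) {
    sn <- eng$snapshots[[as.character(k)]]
    cl <- match(sn$assign, sn$clusterIds)[sub]
    .meanSilhouette(D, cl)
  }, numeric(1))
  crit$kl <- vapply(kRange, function(k) {
    dif <- function(kk) {
      w0 <- getv(WK, kk - 1); w1 <- getv(WK, kk)
      (kk - 1)^(2 / p) * w0 - kk^(2 / p) * w1
    }
    d1 <- dif(k); d2 <- dif(k + 1)
    if (is.na(d1) || is.na(d2) || abs(d2) < .Machine$double.eps) NA_real_
    else abs(d1) / abs(d2)
  }, numeric(1))
  rk <- function(x) {
    r <- rank(-x, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- length(x)
    r
  }
  ranks <- cbind(rk(crit$elbow), rk(crit$silhouette), rk(crit$kl))
  crit$medianRank <- apply(ranks, 1, median)
  ord <- order(crit$medianRank, -crit$silhouette, crit$k)
  kBest <- crit$k[ord[1]]
  labs <- colnames(peakMaps)
  if (is.null(labs)) labs <- paste0("ch", seq_len(ncol(peakMaps)))
  perK <- lapply(kRange, function(k)
    .templatesFromSnapshot(eng$snapshots[[as.character(k)]], labs, "individual"))
  names(perK) <- kRange
  list(k = kBest, templates = perK[[as.character(kBest)]],
       perK = perK, criteria = crit)
}

#' Group-level microstate templates
#'
#' Pools the optimal individual-level template maps and clusters them with
#' T-AAHC at a fixed `k` (4 by default, the canonical resting-state class
#' count), yielding group-level microstate maps.
#'
#' @param templatesList list of [MicrostateTemplates-class] (one per subject)
#'   or a single maps matrix.
#' @param k number of group classes.
#' @return a [MicrostateTemplates-class] with `level = "group"`.
#' @export
groupTemplates <- function(templatesList, k = 4) {
  if (is(templatesList, "MicrostateTemplates"))
    templatesList <- list(templatesList)
  stacked <- do.call(rbind, lapply(templatesList, function(t) {
    if (is(t, "MicrostateTemplates")) maps(t) else as.matrix(t)
  }))
  taahcCluster(stacked, k, level = "group")
}

#' Backfit microstate templates to an epoch
#'
#' Labels every sample of an epoch with the template of highest absolute
#' spatial correlation. The epoch is first normalized by the median GFP at
#' its GFP peaks (a scalp-conductivity normalization; labels are unaffected
#' because correlation is scale-free). Samples whose best `|r|` falls below
#' `minCorr`, or which have zero spatial variance, are left unassigned
#' (label 0).
#'
#' @param templates a [MicrostateTemplates-class].
#' @param epoch channels x samples matrix in the template channel order.
#' @param sampleRate sampling rate of the epoch in Hz.
#' @param minCorr minimum absolute correlation for assignment.
#' @return a [MicrostateSequence-class].
#' @export
backfit <- function(templates, epoch, sampleRate, minCorr = 0.5) {
  stopifnot(is(templates, "MicrostateTemplates"))
  epoch <- as.matrix(epoch)
  M <- maps(templates)
  if (ncol(M) != nrow(epoch))
    stop("montage error: epoch has ", nrow(epoch),
         " channels, templates have ", ncol(M))
  g <- computeGFP(epoch)
  pk <- findGFPPeaks(g)
  med <- if (length(pk)) median(g[pk]) else median(g)
  if (is.finite(med) && med > 0) epoch <- epoch / med
  Xc <- sweep(epoch, 2, colMeans(epoch))
  nrm <- sqrt(colSums(Xc^2))
  R <- abs(M %*% Xc)                      # k x samples (maps are unit norm)
  ok <- nrm > 0
  R[, ok] <- sweep(R[, ok, drop = FALSE], 2, nrm[ok], "/")
  R[, !ok] <- 0
  best <- max.col(t(R), ties.method = "first")
  bestR <- R[cbind(best, seq_len(ncol(R)))]
  lab <- ifelse(ok & bestR >= minCorr, best, 0L)
  MicrostateSequence(lab, sampleRate = sampleRate, k = nrow(M),
                     correlations = bestR)
}

#' Temporal smoothing of a microstate sequence
#'
#' Removes segments shorter than `minDurationMs` by halving them: the first
#' half (the larger half for odd lengths) is relabelled as the preceding
#' segment's class, the second half as the following segment's class. A
#' short segment at the sequence boundary goes wholly to its single
#' neighbour. Unassigned stretches count as segments — so short unassigned
#' blips are themselves smoothed away — but never absorb samples from their
#' neighbours. The rule is applied left to right until no removable short
#' segment remains.
#'
#' @param seq a [MicrostateSequence-class].
#' @param minDurationMs minimum segment duration in milliseconds.
#' @return the smoothed [MicrostateSequence-class].
#' @export
smoothSequence <- function(seq, minDurationMs = 32) {
  stopifnot(is(seq, "MicrostateSequence"))
  lab <- stateLabels(seq)
  minLen <- round(minDurationMs * sampleRate(seq) / 1000)
  repeat {
    r <- rle(lab)
    nr <- length(r$lengths)
    if (nr <= 1) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    actedOn <- FALSE
    for (i in seq_len(nr)) {
      if (r$lengths[i] >= minLen) next
      prevOK <- i > 1 && r$values[i - 1] > 0L
      nextOK <- i < nr && r$values[i + 1] > 0L
      if (!prevOK && !nextOK) next               # nothing can absorb it
      idx <- starts[i]:ends[i]
      if (prevOK && nextOK) {
        nFirst <- ceiling(length(idx) / 2)
        lab[idx[seq_len(nFirst)]] <- r$values[i - 1]
        if (nFirst < length(idx))
          lab[idx[(nFirst + 1):length(idx)]] <- r$values[i + 1]
      } else if (prevOK) {
        lab[idx] <- r$values[i - 1]
      } else {
        lab[idx] <- r$values[i + 1]
      }
      actedOn <- TRUE
      break                                      # re-derive runs and rescan
    }
    if (!actedOn) break
  }
  MicrostateSequence(lab, sampleRate = sampleRate(seq), k = seq@k,
                     correlations = stateCorrelations(seq))
}

#' Temporal microstate parameters
#'
#' Per-class summary of a microstate sequence: mean segment duration in
#' milliseconds (neuronal stability), time coverage as a fraction of samples
#' (dominance) and occurrence in segments per second (activation tendency).
#' Coverages over all classes plus the unassigned fraction sum to one.
#'
#' @param seq a [MicrostateSequence-class].
#' @return data.frame with columns `class` (A, B, ...), `meanDurationMs`,
#'   `coverage`, `occurrencePerS`; the unassigned coverage is attached as
#'   attribute `unassignedCoverage` and absent classes (reported as zeros)
#'   as attribute `absentClasses`.
#' @export
microstateParameters <- function(seq) {
  stopifnot(is(seq, "MicrostateSequence"))
  lab <- stateLabels(seq)
  if (!length(lab)) stop("empty microstate sequence")
  k <- seq@k
  fs <- sampleRate(seq)
  N <- length(lab)
  r <- rle(lab)
  out <- data.frame(class = LETTERS[seq_len(k)],
                    meanDurationMs = 0, coverage = 0, occurrencePerS = 0,
                    stringsAsFactors = FALSE)
  for (c in seq_len(k)) {
    runs <- r$lengths[r$values == c]
    if (length(runs)) {
      out$meanDurationMs[c] <- mean(runs) * 1000 / fs
      out$coverage[c] <- sum(runs) / N
      out$occurrencePerS[c] <- length(runs) / (N / fs)
    }
  }
  attr(out, "unassignedCoverage") <- sum(lab == 0L) / N
  attr(out, "absentClasses") <- setdiff(seq_len(k), unique(lab))
  out
}

#' Match estimated templates to reference templates
#'
#' Finds the one-to-one assignment of estimated to reference maps that
#' maximizes the summed absolute spatial correlation (exhaustive over
#' permutations; intended for small k).
#'
#' @param estimated,reference [MicrostateTemplates-class] objects or maps
#'   matrices with equal row counts.
#' @return list with `perm` (reference index for each estimated map),
#'   `absR` (per-pair absolute correlation) and `meanAbsR`.
#' @export
matchTemplates <- function(estimated, reference) {
  A <- if (is(estimated, "MicrostateTemplates")) maps(estimated) else
    .normalizeMaps(estimated)$maps
  B <- if (is(reference, "MicrostateTemplates")) maps(reference) else
    .normalizeMaps(reference)$maps
  k <- nrow(A)
  stopifnot(nrow(B) == k, k <= 8)
  R <- abs(tcrossprod(A, B))
  perms <- .permutations(k)
  score <- apply(perms, 1, function(p) sum(R[cbind(seq_len(k), p)]))
  best <- perms[which.max(score), ]
  list(perm = best, absR = R[cbind(seq_len(k), best)],
       meanAbsR = mean(R[cbind(seq_len(k), best)]))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}
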