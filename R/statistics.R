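#' @include classes.R
NULL

#' Cohen's d for paired data
#'
#' Standardized mean difference of paired observations: mean of the
#' differences divided by their standard deviation. The sign flips when the
#' groups are swapped.
#'
#' @param x,y paired numeric vectors.
#' @return Cohen's d (0 when every difference is zero).
#' @export
cohensD <- function(x, y) {
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s == 0) return(0)
  mean(d) / s
}

#' Paired interictal-vs-preictal comparison with normality routing
#'
#' Runs a Shapiro-Wilk test on the paired differences; if they look normal
#' (p > `shapiroAlpha`) a paired t-test is used, otherwise the Wilcoxon
#' signed-rank test (exact when the sample permits). Significance uses the
#' dual criterion `p < alpha` and `|d| > dThreshold` (set `dThreshold = 0`
#' to use the p-value alone). With large epoch counts the conventional 0.05
#' level flags negligible differences, hence the small default `alpha`
#' typically used for these comparisons.
#'
#' @param x,y paired numeric vectors (interictal, preictal), length >= 5.
#' @param alpha significance level.
#' @param dThreshold minimum absolute Cohen's d for the significance flag.
#' @param shapiroAlpha level of the normality pre-test.
#' @param feature feature name recorded in the result.
#' @return one-row data.frame: `feature`, `test` ("paired-t", "wilcoxon" or
#'   "degenerate"), `statistic`, `p`, `d`, `alpha`, `significant`.
#' @export
pairedCompare <- function(x, y, alpha = 5e-4, dThreshold = 0.3,
                          shapiroAlpha = 0.05, feature = "feature") {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  if (all(d == 0)) {
    res <- data.frame(feature = feature, test = "degenerate", statistic = 0,
                      p = 1, d = 0, alpha = alpha, significant = FALSE,
                      stringsAsFactors = FALSE)
    return(res)
  }
  swp <- shapiro.test(if (length(d) > 5000) sample(d, 5000) else d)$p.value
  if (swp > shapiroAlpha) {
    tt <- t.test(x, y, paired = TRUE)
    test <- "paired-t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- wilcox.test(x, y, paired = TRUE)
    test <- "wilcoxon"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  dd <- cohensD(x, y)
  data.frame(feature = feature, test = test, statistic = stat, p = p,
             d = dd, alpha = alpha,
             significant = (p < alpha) && (abs(dd) > dThreshold),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of per-subject map statistics
#'
#' Rank-based two-group comparison (per microstate class) of per-subject
#' map statistics, e.g. the spatial correlation of each subject's map to
#' the group template. Returns the H statistic and p-value for each class
#' column; all-tied inputs yield the degenerate `H = 0, p = 1`.
#'
#' @param groupA,groupB numeric vectors (one class) or matrices/data.frames
#'   with one column per microstate class; at least 3 values per group.
#' @return data.frame with `class`, `H`, `p`.
#' @export
kruskalWallisMaps <- function(groupA, groupB) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (ncol(A) != ncol(B)) stop("groups must have the same class columns")
  if (nrow(A) < 3 || nrow(B) < 3) stop("need at least 3 values per group")
  cls <- colnames(A)
  if (is.null(cls)) cls <- LETTERS[seq_len(ncol(A))]
  out <- data.frame(class = cls, H = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(A))) {
    a <- A[, j]; b <- B[, j]
    if (var(c(a, b)) == 0) {
      out$H[j] <- 0; out$p[j] <- 1
    } else {
      kw <- kruskal.test(list(a, b))
      out$H[j] <- unname(kw$statistic)
      out$p[j] <- kw$p.value
    }
  }
  out
}

#' Run the paired statistical battery over a feature table
#'
#' Applies [pairedCompare()] to every feature column of an extracted
#' feature table, pairing interictal and preictal epochs by order within
#' class (the balanced design gives equal counts).
#'
#' @param features data.frame from [extractFeatures()].
#' @param alpha significance level (0.0005 is typical for microstate and
#'   nonlinear features, 0.05 for spectral ones).
#' @param dThreshold minimum `|d|` for the significance flag.
#' @param groups the two state labels (interictal first).
#' @return data.frame with one row per feature.
#' @export
compareFeatureTable <- function(features, alpha = 5e-4, dThreshold = 0.3,
                                groups = c("interictal", "preictal")) {
  fcols <- setdiff(names(features), "label")
  ia <- features$label == groups[1]
  pa <- features$label == groups[2]
  n <- min(sum(ia), sum(pa))
  if (n < 5) stop("need at least 5 epochs per state")
  do.call(rbind, lapply(fcols, function(f)
    pairedCompare(features[[f]][which(ia)[seq_len(n)]],
                  features[[f]][which(pa)[seq_len(n)]],
                  alpha = alpha, dThreshold = dThreshold, feature = f)))
}
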