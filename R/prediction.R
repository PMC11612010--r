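#' @include classes.R
NULL

#' Prediction protocol settings
#'
#' The individual-level protocol: in each of `nRepetitions` repetitions a
#' stratified 10% of the epochs is held out as the test set; on the
#' remaining 90% a grid search over the RBF-SVM hyperparameters is scored by
#' stratified `nFolds`-fold cross-validated accuracy; the winning model is
#' refit on the full training portion and evaluated once on the held-out
#' 10%. Feature z-scoring parameters are estimated on the training portion
#' only.
#'
#' @param nRepetitions number of repetitions.
#' @param testFraction held-out fraction.
#' @param nFolds cross-validation folds.
#' @param costGrid,gammaGrid RBF-SVM grids (powers of two spanning
#'   `2^-3..2^7` and `2^-7..2^3`).
#' @param seeds one RNG seed per repetition.
#' @param epochLengthS epoch length in seconds (needed for the per-hour
#'   false-positive rate).
#' @param positive the positive (preictal) class label.
#' @param eventMergedFPR merge consecutive false-positive epochs into one
#'   alarm event when counting the FPR.
#' @return list of class `PredictionProtocol`.
#' @export
predictionProtocol <- function(nRepetitions = 10, testFraction = 0.1,
                               nFolds = 5,
                               costGrid = 2^seq(-3, 7, by = 2),
                               gammaGrid = 2^seq(-7, 3, by = 2),
                               seeds = 0:(nRepetitions - 1),
                               epochLengthS = 3,
                               positive = "preictal",
                               eventMergedFPR = FALSE) {
  stopifnot(length(seeds) == nRepetitions)
  structure(list(nRepetitions = nRepetitions, testFraction = testFraction,
                 nFolds = nFolds, costGrid = costGrid, gammaGrid = gammaGrid,
                 seeds = seeds, epochLengthS = epochLengthS,
                 positive = positive, eventMergedFPR = eventMergedFPR),
            class = "PredictionProtocol")
}

#' Stratified train/test split
#'
#' Deterministic given the seed: within each class the indices are shuffled
#' and `fraction` of them (at least one) is assigned to the test set.
#'
#' @param labels class label vector.
#' @param fraction test fraction.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, fraction, seed) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2)
      stop("stratification error: class '", cl, "' has fewer than 2 epochs")
    nTest <- max(1L, round(length(idx) * fraction))
    test <- c(test, sample(idx, nTest))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

.stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

# decision scores oriented so larger = more "positive"
.svmScores <- function(model, x, positive) {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (grepl(paste0("^", positive, "/"), colnames(dv)[1])) 1 else -1
  list(pred = as.character(pr), score = sgn * dv[, 1])
}

#' Classification metrics for seizure prediction
#'
#' Sensitivity `TP/(TP+FN)` (preictal = positive), specificity, accuracy and
#' Cohen's kappa as percentages; AUC from the continuous scores; and the
#' false-positive rate per hour: the number of interictal epochs wrongly
#' flagged preictal divided by the hours of interictal data evaluated
#' (optionally with consecutive false-positive epochs merged into single
#' alarm events).
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param scores continuous scores (larger = more preictal) for the AUC.
#' @param interictalHours hours of interictal data behind `truth`.
#' @param positive positive class label.
#' @param eventMerged merge consecutive false-positive epochs when counting.
#' @return named list: `accuracy`, `sensitivity`, `specificity`, `kappa`
#'   (percent), `auc`, `fprPerHour`.
#' @export
computeMetrics <- function(truth, pred, scores = NULL, interictalHours,
                           positive = "preictal", eventMerged = FALSE) {
  stopifnot(length(truth) == length(pred))
  if (interictalHours <= 0) stop("interictalHours must be positive")
  truth <- as.character(truth); pred <- as.character(pred)
  pos <- truth == positive
  tp <- sum(pos & pred == positive); fn <- sum(pos & pred != positive)
  fp <- sum(!pos & pred == positive); tn <- sum(!pos & pred != positive)
  n <- length(truth)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2)
      stop("AUC undefined: truth contains a single class")
    r <- pROC::roc(response = factor(truth, levels = c(setdiff(unique(truth),
                                                               positive),
                                                       positive)),
                   predictor = as.numeric(scores), quiet = TRUE,
                   direction = "<")
    auc <- as.numeric(pROC::auc(r))
  }
  fpCount <- if (eventMerged && fp > 0) {
    idx <- which(!pos & pred == positive)
    sum(diff(c(-10L, idx)) > 1L)                 # merge consecutive epochs
  } else fp
  list(accuracy = 100 * acc, sensitivity = 100 * sens,
       specificity = 100 * spec, kappa = 100 * kappa, auc = auc,
       fprPerHour = fpCount / interictalHours)
}

#' Run the repeated SVM prediction protocol
#'
#' Executes the full individual-level protocol (see [predictionProtocol()])
#' on a feature matrix and returns per-repetition and summary metrics.
#' Reports are bitwise reproducible given the protocol seeds.
#'
#' @param features list from [assembleFeatures()], or a numeric matrix.
#' @param labels class labels (required when `features` is a matrix).
#' @param protocol a [predictionProtocol()].
#' @return list of class `ClassifierReport`: `perRepetition` (data.frame of
#'   metrics and chosen hyperparameters), `summary` (means and SDs) and
#'   `protocol`.
#' @export
runPrediction <- function(features, labels = NULL,
                          protocol = predictionProtocol()) {
  if (is.list(features) && !is.null(features$x)) {
    labels <- features$labels
    features <- features$x
  }
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (min(table(labels)) < 2)
    stop("stratification error: need at least 2 epochs per class")
  pos <- protocol$positive
  neg <- setdiff(unique(labels), pos)
  grid <- expand.grid(cost = protocol$costGrid, gamma = protocol$gammaGrid)
  rows <- vector("list", protocol$nRepetitions)
  for (rep in seq_len(protocol$nRepetitions)) {
    seed <- protocol$seeds[rep]
    sp <- stratifiedSplit(labels, protocol$testFraction, seed)
    xtr <- x[sp$train, , drop = FALSE]; ytr <- labels[sp$train]
    xte <- x[sp$test, , drop = FALSE];  yte <- labels[sp$test]
    # z-score with training statistics only
    mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xtr <- scale(xtr, center = mu, scale = sdv)
    xte <- scale(xte, center = mu, scale = sdv)
    set.seed(seed)
    fold <- .stratifiedFolds(ytr, protocol$nFolds)
    cvAcc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(protocol$nFolds)) {
        tr <- fold != f
        m <- e1071::svm(xtr[tr, , drop = FALSE], factor(ytr[tr]),
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
        p <- predict(m, xtr[!tr, , drop = FALSE])
        correct <- correct + sum(as.character(p) == ytr[!tr])
      }
      cvAcc[g] <- correct / length(ytr)
    }
    best <- which.max(cvAcc)                    # ties: first in grid order
    model <- e1071::svm(xtr, factor(ytr), kernel = "radial",
                        cost = grid$cost[best], gamma = grid$gamma[best],
                        scale = FALSE)
    sc <- .svmScores(model, xte, pos)
    interictalHours <- sum(yte != pos) * protocol$epochLengthS / 3600
    met <- computeMetrics(yte, sc$pred, sc$score, interictalHours,
                          positive = pos,
                          eventMerged = protocol$eventMergedFPR)
    rows[[rep]] <- data.frame(repetition = rep, seed = seed,
                              cost = grid$cost[best],
                              gamma = grid$gamma[best],
                              cvAccuracy = 100 * cvAcc[best],
                              accuracy = met$accuracy,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity,
                              kappa = met$kappa, auc = met$auc,
                              fprPerHour = met$fprPerHour)
  }
  per <- do.call(rbind, rows)
  mcols <- c("accuracy", "sensitivity", "specificity", "kappa", "auc",
             "fprPerHour")
  summary <- data.frame(metric = mcols,
                        mean = vapply(mcols, function(c) mean(per[[c]]),
                                      numeric(1)),
                        sd = vapply(mcols, function(c) sd(per[[c]]),
                                    numeric(1)))
  structure(list(perRepetition = per, summary = summary,
                 protocol = protocol),
            class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat("ClassifierReport:", nrow(x$perRepetition), "repetitions\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %8.3f (sd %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write a ClassifierReport as JSON
#' @param report a `ClassifierReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(list(perRepetition = report$perRepetition,
                            summary = report$summary),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
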