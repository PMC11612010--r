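#' @include classes.R
NULL

#' Write microstate templates as CSV
#'
#' Rows are classes (A, B, ...), columns are channel labels.
#'
#' @param templates a [MicrostateTemplates-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTemplatesCSV <- function(templates, path) {
  stopifnot(is(templates, "MicrostateTemplates"))
  m <- maps(templates)
  write.csv(data.frame(class = rownames(m), m, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Read microstate templates from CSV
#' @param path CSV written by [writeTemplatesCSV()].
#' @param level "individual" or "group".
#' @return a [MicrostateTemplates-class].
#' @export
readTemplatesCSV <- function(path, level = "group") {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  MicrostateTemplates(m, level = level, channelLabels = colnames(m))
}

#' Write a microstate sequence as CSV
#'
#' Columns: `sample_index` (0-based), `label` (0 = unassigned),
#' `correlation`.
#'
#' @param seq a [MicrostateSequence-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSequenceCSV <- function(seq, path) {
  stopifnot(is(seq, "MicrostateSequence"))
  write.csv(data.frame(sample_index = seq_along(stateLabels(seq)) - 1L,
                       label = stateLabels(seq),
                       correlation = stateCorrelations(seq)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write microstate parameters as tidy CSV
#'
#' Long format with columns `subject`, `epoch`, `class`, `metric`, `value`.
#'
#' @param params data.frame from [microstateParameters()], or a list of them
#'   (one per epoch).
#' @param path output path.
#' @param subject subject identifier.
#' @return `path`, invisibly.
#' @export
writeParametersCSV <- function(params, path, subject = "S1") {
  if (is.data.frame(params)) params <- list(params)
  long <- do.call(rbind, lapply(seq_along(params), function(e) {
    p <- params[[e]]
    do.call(rbind, lapply(c("meanDurationMs", "coverage", "occurrencePerS"),
                          function(m)
      data.frame(subject = subject, epoch = e, class = p$class, metric = m,
                 value = p[[m]], stringsAsFactors = FALSE)))
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write statistical test results as tidy CSV
#'
#' @param results data.frame from [compareFeatureTable()] or
#'   [pairedCompare()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStatsCSV <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
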