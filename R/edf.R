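#' @include classes.R
NULL

# fixed-width ASCII field helpers for the EDF header
.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}
.edfNum <- function(x, width) .edfPad(format(x, trim = TRUE, scientific = FALSE), width)

#' Read an EDF / EDF+ recording
#'
#' Parses the 16-bit European Data Format used for clinical EEG. Ordinary
#' signals are returned in physical units (microvolts for EEG); an
#' "EDF Annotations" signal, when present, is decoded from its time-stamped
#' annotation lists into the recording's annotation table. All channels are
#' preserved; montage selection happens later in [preprocessEEG()].
#'
#' @param path path to the EDF file.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256)
    stop("corrupt or truncated EDF header in ", path)
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  nrec <- as.integer(fld(237, 8))
  recDur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header (signal count) in ", path)
  sigHdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sigHdr, type = "bytes") < 256 * ns)
    stop("corrupt or truncated EDF signal header in ", path)
  # field offsets within the signal header, in bytes per signal
  off <- c(label = 0, transducer = 16, dim = 96, physMin = 104, physMax = 112,
           digMin = 120, digMax = 128, prefilter = 136, spr = 216, reserved = 296)
  blockAt <- function(name, width) {
    start <- off[[name]] * ns
    vapply(seq_len(ns) - 1L,
           function(i) trimws(substr(sigHdr, start + i * width + 1,
                                     start + (i + 1) * width)),
           character(1))
  }
  labels  <- blockAt("label", 16)
  physMin <- as.numeric(blockAt("physMin", 8))
  physMax <- as.numeric(blockAt("physMax", 8))
  digMin  <- as.numeric(blockAt("digMin", 8))
  digMax  <- as.numeric(blockAt("digMax", 8))
  spr     <- as.integer(blockAt("spr", 8))
  if (anyNA(spr) || any(spr < 1)) stop("corrupt EDF signal header in ", path)
  recLen <- sum(spr)
  if (is.na(nrec) || nrec < 0) {
    dataBytes <- file.size(path) - (256 + 256 * ns)
    nrec <- as.integer(dataBytes %/% (2 * recLen))
  }
  vals <- readBin(con, "integer", n = nrec * recLen, size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) < nrec * recLen)
    stop("truncated EDF data section in ", path)
  dim(vals) <- c(recLen, nrec)
  isAnn <- labels == "EDF Annotations"
  starts <- cumsum(c(0L, spr))[seq_len(ns)]
  ann <- emptyAnnotations()
  if (any(isAnn)) {
    for (s in which(isAnn)) {
      ints <- as.vector(vals[(starts[s] + 1):(starts[s] + spr[s]), , drop = FALSE])
      raw <- writeBin(as.integer(ints), raw(), size = 2, endian = "little")
      ann <- rbind(ann, .parseTALs(raw))
    }
  }
  keep <- which(!isAnn)
  if (!length(keep)) stop("EDF file contains no data signals: ", path)
  fs <- spr[keep] / recDur
  if (length(unique(fs)) > 1)
    stop("mixed per-signal sampling rates are not supported (", path, ")")
  data <- matrix(0, length(keep), spr[keep[1]] * nrec)
  for (j in seq_along(keep)) {
    s <- keep[j]
    dig <- as.numeric(vals[(starts[s] + 1):(starts[s] + spr[s]), , drop = FALSE])
    scale <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
    if (!is.finite(scale)) scale <- 1
    data[j, ] <- (dig - digMin[s]) * scale + physMin[s]
  }
  EEGRecording(data, sampleRate = fs[1], channelLabels = labels[keep],
               annotations = ann)
}

# decode EDF+ time-stamped annotation lists (TALs) from raw bytes
.parseTALs <- function(raw) {
  out <- emptyAnnotations()
  # TALs are separated by 0x00; fields inside a TAL by 0x14; onset and
  # duration by 0x15
  ends <- which(raw == as.raw(0))
  start <- 1L
  for (e in ends) {
    if (e > start) {
      tal <- rawToChar(raw[start:(e - 1L)])
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) >= 2 && nzchar(parts[1])) {
        od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
        onset <- suppressWarnings(as.numeric(od[1]))
        dur <- if (length(od) > 1) suppressWarnings(as.numeric(od[2])) else 0
        texts <- parts[-1][nzchar(parts[-1])]
        for (tx in texts)
          out <- rbind(out, data.frame(onset = onset, duration = dur,
                                       label = tx, stringsAsFactors = FALSE))
      }
    }
    start <- e + 1L
  }
  out
}

#' Write an EEGRecording to EDF / EDF+
#'
#' Writes 1-second data records with 16-bit samples; the physical range is
#' set per channel from the data. When the recording carries annotations an
#' "EDF Annotations" signal is added (EDF+C). The final record is
#' zero-padded, so recordings are padded to a whole number of seconds on a
#' round trip.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- sampleRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEDF requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- recordingData(rec)
  nch <- nrow(x)
  nrec <- as.integer(ceiling(ncol(x) / fs))
  padded <- matrix(0, nch, nrec * fs)
  padded[, seq_len(ncol(x))] <- x
  ann <- annotations(rec)
  hasAnn <- nrow(ann) > 0
  # digital encoding
  physMax <- pmax(apply(abs(padded), 1, max), 1)
  physMin <- -physMax
  digMax <- 32767; digMin <- -32768
  digital <- matrix(0L, nch, ncol(padded))
  for (i in seq_len(nch))
    digital[i, ] <- as.integer(round((padded[i, ] - physMin[i]) /
                                     (physMax[i] - physMin[i]) *
                                     (digMax - digMin) + digMin))
  # annotation TAL strings per record
  annChunks <- NULL
  sprAnn <- 0L
  if (hasAnn) {
    annChunks <- lapply(seq_len(nrec) - 1L, function(r) {
      # one 0x00-terminated TAL per entry, after the record timestamp TAL
      tal <- paste0("+", r, "\x14\x14\x01")
      sel <- ann$onset >= r & ann$onset < r + 1
      for (i in which(sel))
        tal <- paste0(tal, "+", format(ann$onset[i], trim = TRUE),
                      "\x15", format(ann$duration[i], trim = TRUE),
                      "\x14", ann$label[i], "\x14\x01")
      raw <- charToRaw(tal)
      raw[raw == as.raw(1)] <- as.raw(0)
      raw
    })
    maxBytes <- max(vapply(annChunks, length, integer(1))) + 2L
    sprAnn <- as.integer(ceiling(maxBytes / 2))
  }
  ns <- nch + as.integer(hasAnn)
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wc(.edfPad("0", 8))                                   # version
  wc(.edfPad("epimstate recording", 80))                # patient id
  wc(.edfPad("epimstate", 80))                          # recording id
  wc(.edfPad("01.01.00", 8)); wc(.edfPad("00.00.00", 8))
  wc(.edfNum(256 * (ns + 1), 8))                        # header bytes
  wc(.edfPad(if (hasAnn) "EDF+C" else "", 44))
  wc(.edfNum(nrec, 8)); wc(.edfNum(1, 8)); wc(.edfNum(ns, 4))
  labs <- c(channelLabels(rec), if (hasAnn) "EDF Annotations")
  for (l in labs) wc(.edfPad(l, 16))
  for (l in labs) wc(.edfPad("", 80))                   # transducer
  for (l in seq_len(ns)) wc(.edfPad(if (l <= nch) "uV" else "", 8))
  for (i in seq_len(ns)) wc(.edfNum(if (i <= nch) signif(physMin[i], 6) else -1, 8))
  for (i in seq_len(ns)) wc(.edfNum(if (i <= nch) signif(physMax[i], 6) else 1, 8))
  for (i in seq_len(ns)) wc(.edfNum(digMin, 8))
  for (i in seq_len(ns)) wc(.edfNum(digMax, 8))
  for (l in seq_len(ns)) wc(.edfPad("", 80))            # prefilter
  for (i in seq_len(ns)) wc(.edfNum(if (i <= nch) fs else sprAnn, 8))
  for (l in seq_len(ns)) wc(.edfPad("", 32))            # reserved
  # recompute physical scaling exactly as written (6 significant digits)
  pmn <- signif(physMin, 6); pmx <- signif(physMax, 6)
  for (i in seq_len(nch))
    digital[i, ] <- as.integer(round((padded[i, ] - pmn[i]) /
                                     (pmx[i] - pmn[i]) *
                                     (digMax - digMin) + digMin))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch))
      writeBin(digital[i, idx], con, size = 2, endian = "little")
    if (hasAnn) {
      chunk <- annChunks[[r]]
      chunk <- c(chunk, raw(2L * sprAnn - length(chunk)))
      writeBin(chunk, con)
    }
  }
  invisible(path)
}
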