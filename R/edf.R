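# Minimal EDF (European Data Format) reader/writer: 16-bit integer signals,
# fixed-length 1-s data records, ASCII headers. Covers the plain-EDF subset
# produced by clinical EEG exports; no annotations, no discontinuous files.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) stop("EDF numeric field does not fit: ", s)
  edf_pad(s, width)
}

#' Write a recording as an EDF file
#'
#' Signals are quantized to 16-bit integers over a symmetric physical range
#' per channel (so the round-trip error is at most half a quantization step,
#' range/65534). Data records are 1 s long; the recording must contain a
#' whole number of seconds. Header dates are fixed (not wall-clock) so that
#' identical inputs produce byte-identical files.
#'
#' @param rec an [eeg_recording()] with integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n <- ncol(rec$data)
  if (n %% fs != 0) stop("EDF writer requires a whole number of 1-s records")
  n_rec <- n %/% fs
  ns <- nrow(rec$data)
  pmax <- pmax(ceiling(apply(abs(rec$data), 1, max)), 1)
  dmin <- -32768; dmax <- 32767
  head1 <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("plihub export", 80),
    "01.01.01", "00.00.00",
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  labels <- as.character(rec$montage)
  head2 <- paste0(
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  # digitize: phys = (dig - dmin) * (pmax - pmin)/(dmax - dmin) + pmin
  dig <- matrix(0L, ns, n)
  for (c in seq_len(ns)) {
    scale <- (dmax - dmin) / (2 * pmax[c])
    d <- round((rec$data[c, ] + pmax[c]) * scale + dmin)
    dig[c, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(head1, head2), con, eos = NULL, useBytes = TRUE)
  # records: for each 1-s record, all samples of signal 1, then signal 2, ...
  idx <- matrix(seq_len(n), nrow = fs)  # samples x records
  for (r in seq_len(n_rec)) {
    writeBin(as.integer(t(dig[, idx[, r], drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path an EDF file written by [write_edf()] or any plain EDF file
#'   with 16-bit signals and a constant record layout.
#' @param subject_id optional identifier; defaults to the EDF patient field.
#' @return An [eeg_recording()] with channels in file order.
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not an EDF file (bad signal count): ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8))
  fld(32)
  if (length(unique(nsamp)) != 1) {
    stop("EDF reader supports a single sampling rate across signals")
  }
  per_rec <- nsamp[1]
  fs <- per_rec / rec_dur
  raw <- readBin(con, "integer", n = n_rec * ns * per_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * ns * per_rec) stop("EDF file truncated: ", path)
  # raw layout: record-major, signal-major within record
  arr <- array(raw, dim = c(per_rec, ns, n_rec))
  data <- matrix(0, ns, per_rec * n_rec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (c in seq_len(ns)) {
    data[c, ] <- as.vector(arr[, c, ]) * scale[c] + pmin[c] - dmin[c] * scale[c]
  }
  eeg_recording(data, fs = fs, montage = montage(labels),
                subject_id = if (is.null(subject_id)) patient else subject_id)
}
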