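# Delimited-text I/O: labeled matrices, recordings, metadata tables.
# Numbers are printed with 17 significant digits so that read(write(x)) == x
# bit-exactly for doubles.

fmt_full <- function(x) {
  s <- sprintf("%.17g", x)
  s[!is.finite(x)] <- as.character(x[!is.finite(x)])
  s
}

#' Write and read labeled numeric matrices as TSV
#'
#' The written file has a header row of column labels and a leading label
#' column; values carry 17 significant digits, so the round trip through
#' [read_matrix_tsv()] reproduces the input exactly.
#'
#' @param m numeric matrix.
#' @param row_labels,col_labels character vectors matching `dim(m)`.
#' @param path output path.
#' @return `path` invisibly; for the reader, a matrix with dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_matrix_tsv(matrix(1:4 / 7, 2), c("a", "b"), c("x", "y"), f)
#' read_matrix_tsv(f)
#' @export
write_matrix_tsv <- function(m, row_labels, col_labels, path) {
  m <- as.matrix(m)
  if (nrow(m) != length(row_labels)) {
    stop("matrix has ", nrow(m), " rows but ", length(row_labels),
         " row labels")
  }
  if (ncol(m) != length(col_labels)) {
    stop("matrix has ", ncol(m), " columns but ", length(col_labels),
         " column labels")
  }
  lines <- c(paste(c("", col_labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(row_labels[i], fmt_full(m[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write and read recordings as delimited text
#'
#' Plain-text recording format used for small fixtures: a `# fs: <Hz>`
#' comment line, then a TSV with one column per channel (header = channel
#' labels) and one row per sample.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  lines <- c(paste0("# fs: ", fmt_full(rec$fs)),
             paste(as.character(rec$montage), collapse = "\t"),
             vapply(seq_len(ncol(rec$data)), function(j) {
               paste(fmt_full(rec$data[, j]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

read_recording_tsv <- function(path, subject_id = "subj") {
  first <- readLines(path, n = 1)
  fs <- NA_real_
  if (grepl("^#\\s*fs\\s*:", first)) {
    fs <- as.numeric(sub("^#\\s*fs\\s*:\\s*", "", first))
  }
  df <- read.csv(path, sep = "\t", comment.char = "#", check.names = FALSE)
  if (ncol(df) < 1 || !all(vapply(df, is.numeric, TRUE))) {
    stop("not a numeric recording matrix with a channel-label header: ", path)
  }
  list(data = t(as.matrix(df)), labels = colnames(df), fs = fs,
       subject_id = subject_id)
}

#' Read a recording from EDF or delimited text
#'
#' Dispatches on file extension (`.edf` vs anything else). Channels are
#' reordered to `expected_montage` (case-insensitive label matching); a
#' missing channel is an error naming it. The sampling rate is taken from
#' the file metadata when present; if `fs` is also supplied and disagrees,
#' an error is raised.
#'
#' @param path input file.
#' @param expected_montage target channel set and order.
#' @param fs expected sampling rate in Hz; required for text files without
#'   an `# fs:` line.
#' @param subject_id identifier for the returned recording.
#' @return An [eeg_recording()] with rows in `expected_montage` order.
#' @export
read_recording <- function(path, expected_montage = default_montage(),
                           fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path, subject_id = subject_id)
  } else {
    r <- read_recording_tsv(path,
                            subject_id = if (is.null(subject_id)) "subj"
                                         else subject_id)
    file_fs <- r$fs
    if (is.na(file_fs) && is.null(fs)) {
      stop("text recording has no '# fs:' line; supply fs explicitly")
    }
    rec <- eeg_recording(r$data, fs = if (is.na(file_fs)) fs else file_fs,
                         montage = montage(r$labels),
                         subject_id = r$subject_id)
  }
  if (!is.null(fs) && !isTRUE(all.equal(fs, rec$fs))) {
    stop("sampling rate mismatch: file says ", rec$fs,
         " Hz, config says ", fs, " Hz")
  }
  reorder_channels(rec, expected_montage)
}

#' Read or write the subject metadata table
#'
#' CSV with columns `subject_id, group, session, bprs, age`; validated by
#' [subject_meta()].
#'
#' @param path CSV path.
#' @param df metadata data.frame.
#' @export
read_subject_meta <- function(path) {
  subject_meta(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_subject_meta
#' @export
write_subject_meta <- function(df, path) {
  df <- subject_meta(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
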