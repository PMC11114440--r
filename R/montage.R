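#' Electrode montages and EEG recordings
#'
#' A montage is an ordered set of unique channel labels. The default montage
#' is the 16-site subset of the International 10-20 system used throughout
#' this package: Fp1, Fp2, F3, F4, Fz, F7, F8, C3, C4, P3, P4, Pz, T5, T6,
#' O1, O2 (in this order).
#'
#' @param labels character vector of unique, non-empty channel names.
#' @return A `montage` object (a classed character vector).
#' @examples
#' default_montage()
#' montage(c("Cz", "Pz"))
#' @export
montage <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("montage needs at least one channel label")
  if (any(!nzchar(trimws(labels)))) stop("montage labels must be non-empty")
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  structure(labels, class = "montage")
}

#' @rdname montage
#' @export
default_montage <- function() {
  montage(c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8", "C3",
            "C4", "P3", "P4", "Pz", "T5", "T6", "O1", "O2"))
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x), " channels: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# case-insensitive, whitespace-stripped label matching (EDF pads labels)
match_channels <- function(have, want) {
  norm <- function(x) tolower(trimws(x))
  idx <- match(norm(want), norm(have))
  if (anyNA(idx)) {
    stop("channel(s) missing from recording: ",
         paste(want[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Construct a multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts; all values
#'   must be finite. Row count must equal the montage length.
#' @param fs sampling rate in Hz (default 200).
#' @param montage a [montage()]; defaults to [default_montage()].
#' @param subject_id identifier string.
#' @return An `eeg_recording` object: list with elements `data`, `fs`,
#'   `montage`, `subject_id`.
#' @examples
#' rec <- eeg_recording(matrix(0, 16, 400), fs = 200)
#' rec
#' @export
eeg_recording <- function(data, fs = 200, montage = default_montage(),
                          subject_id = "subj") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (!all(is.finite(data))) stop("data contains non-finite samples")
  if (!inherits(montage, "montage")) montage <- montage(montage)
  if (nrow(data) != length(montage)) {
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage), " channels")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  rownames(data) <- as.character(montage)
  structure(list(data = data, fs = fs, montage = montage,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' Reorder recording channels to a target montage
#'
#' A pure permutation: the multiset of channel rows is unchanged. Matching is
#' case-insensitive with surrounding whitespace stripped.
#'
#' @param rec an [eeg_recording()].
#' @param target a [montage()] whose channels must all be present in `rec`.
#' @return The recording with rows in `target` order.
#' @export
reorder_channels <- function(rec, target = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match_channels(as.character(rec$montage), as.character(target))
  eeg_recording(rec$data[idx, , drop = FALSE], fs = rec$fs,
                montage = target, subject_id = rec$subject_id)
}

#' Subject metadata tables
#'
#' Validates a per-subject metadata table with columns `subject_id`, `group`
#' (control/patient), `session` (pre/post/none), and optional `bprs`
#' (nonnegative symptom score) and `age` (years).
#'
#' @param df data.frame with at least `subject_id` and `group`.
#' @return The validated data.frame with `group` and `session` as factors
#'   with canonical levels.
#' @export
subject_meta <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!"session" %in% names(df)) df$session <- "none"
  if (!"bprs" %in% names(df)) df$bprs <- NA_real_
  if (!"age" %in% names(df)) df$age <- NA_real_
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df[c("subject_id", "session")])) {
    stop("duplicate (subject_id, session) rows in metadata")
  }
  if (!all(df$group %in% c("control", "patient"))) {
    stop("group must be 'control' or 'patient'")
  }
  if (!all(df$session %in% c("pre", "post", "none"))) {
    stop("session must be 'pre', 'post' or 'none'")
  }
  df$group <- factor(df$group, levels = c("control", "patient"))
  df$session <- factor(df$session, levels = c("pre", "post", "none"))
  df$bprs <- as.numeric(df$bprs)
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$bprs) & df$bprs < 0)) stop("bprs must be nonnegative")
  df[c("subject_id", "group", "session", "bprs", "age")]
}
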