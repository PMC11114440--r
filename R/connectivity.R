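#' Instantaneous phase of band-limited epochs
#'
#' For each epoch and channel, the analytic signal is computed over that
#' epoch (FFT method) and its argument taken as the instantaneous phase,
#' in (-pi, pi]. Input should be narrowband (the output of the band
#' filters); an all-zero epoch has no defined phase and raises an error.
#'
#' @param bep a `band_epochs` object from [segment_epochs()].
#' @return A `phase_epochs` object: list with `phases` (samples x channels x
#'   epochs array of radians), `fs`, `band`, `montage`, `subject_id`.
#' @export
instantaneous_phase <- function(bep) {
  stopifnot(inherits(bep, "band_epochs"))
  d <- dim(bep$epochs)
  S <- d[1]; C <- d[2]; E <- d[3]
  flat <- matrix(aperm(bep$epochs, c(1, 3, 2)), S * E, C)
  seg_energy <- matrix(0, E, C)
  for (e in seq_len(E)) {
    seg_energy[e, ] <- colSums(abs(bep$epochs[, , e, drop = FALSE][, , 1,
                                                                   drop = FALSE]))
  }
  if (any(seg_energy == 0)) {
    bad <- which(seg_energy == 0, arr.ind = TRUE)[1, ]
    stop("all-zero epoch: channel ", as.character(bep$montage)[bad[2]],
         ", epoch ", bad[1], " (phase undefined)")
  }
  ph <- cpp_epoch_phase(flat, S, as.integer(S * (seq_len(E) - 1)))
  structure(list(phases = ph, fs = bep$fs, band = bep$band,
                 montage = bep$montage, subject_id = bep$subject_id),
            class = "phase_epochs")
}

#' Phase lag index of one phase-series pair
#'
#' The PLI over one epoch is `| (1/T) * sum_k sign(dphi(t_k)) |` with the
#' phase difference wrapped to (-pi, pi] and `sign(0) = 0`. It lies in
#' \[0, 1], is symmetric in its arguments, and is 0 for strictly zero-lag
#' (or pi-lag) coupling -- the property that discounts volume conduction.
#'
#' @param phase_a,phase_b numeric vectors of instantaneous phase (radians),
#'   equal length T >= 1.
#' @return PLI value in \[0, 1].
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' pli_epoch(2 * pi * 10 * t, 2 * pi * 10 * t - pi / 2)  # constant lag: 1
#' @export
pli_epoch <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series differ in length (", length(phase_a), " vs ",
         length(phase_b), ")")
  }
  if (length(phase_a) < 1) stop("need at least one sample")
  d <- wrap_phase(phase_a - phase_b)
  abs(mean(sign(d)))
}

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- x %% (2 * pi)        # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Subject-level PLI connectivity matrix
#'
#' PLI is computed for every unordered electrode pair in every epoch, then
#' averaged across epochs into one symmetric matrix per subject and band
#' (diagonal fixed at 0). Set `per_epoch = TRUE` to retrieve the unaveraged
#' per-epoch matrices instead.
#'
#' @param pe a `phase_epochs` object.
#' @param per_epoch return the channels x channels x epochs array of
#'   per-epoch PLI values rather than their mean.
#' @return A `connectivity_matrix` (symmetric numeric matrix with electrode
#'   dimnames and attributes `subject_id` and `band`), or a 3-d array when
#'   `per_epoch = TRUE`.
#' @export
subject_connectivity <- function(pe, per_epoch = FALSE) {
  stopifnot(inherits(pe, "phase_epochs"))
  cube <- cpp_pli_epochs(pe$phases)
  labs <- as.character(pe$montage)
  if (per_epoch) {
    dimnames(cube) <- list(labs, labs, NULL)
    return(cube)
  }
  m <- apply(cube, c(1, 2), mean)
  connectivity_matrix(m, labels = labs, subject_id = pe$subject_id,
                      band = if (!is.null(pe$band)) pe$band$name else NA)
}

#' @rdname subject_connectivity
#' @param values symmetric matrix of PLI values in \[0, 1], zero diagonal.
#' @param labels electrode labels.
#' @param subject_id,band identifiers carried as attributes.
#' @export
connectivity_matrix <- function(values, labels = rownames(values),
                                subject_id = "subj", band = NA) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (any(values < 0 | values > 1)) stop("PLI values must lie in [0, 1]")
  if (max(abs(values - t(values))) > 1e-12) {
    stop("connectivity matrix must be symmetric")
  }
  if (any(diag(values) != 0)) stop("connectivity diagonal must be 0")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = subject_id, band = band)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", attr(x, "subject_id"), " / ",
      attr(x, "band"), ": ", nrow(x), " electrodes, mean PLI ",
      signif(mean(x[upper.tri(x)]), 3), "\n", sep = "")
  invisible(x)
}
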