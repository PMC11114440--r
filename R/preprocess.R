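#' Frequency band definitions
#'
#' The canonical analysis bands: delta 2-4, theta 4-8, alpha 8-13, beta
#' 13-30, gamma 30-60 Hz. All edges must satisfy 0 < low < high < fs/2;
#' at the default 200 Hz sampling rate the gamma upper edge (60 Hz) sits
#' below the 100 Hz Nyquist frequency.
#'
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz.
#' @return `band_spec`: a named list; `band_specs()` returns the named list
#'   of all five canonical bands.
#' @examples
#' band_specs()$beta
#' @export
band_spec <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz (got ", low_hz, ", ", high_hz, ")")
  }
  structure(list(name = as.character(name), low_hz = low_hz,
                 high_hz = high_hz), class = "band_spec")
}

#' @rdname band_spec
#' @export
band_specs <- function() {
  list(delta = band_spec("delta", 2, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 13, 30),
       gamma = band_spec("gamma", 30, 60))
}

#' Design a linear-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) design via [signal::fir1()]. The returned
#' coefficient vector has odd length `order + 1` and is exactly symmetric
#' (type-I linear phase), so the group delay is `order/2` samples at every
#' frequency. The default order of 4000 gives a transition width of about
#' 0.16 Hz at fs = 200 Hz with >50 dB stopband attenuation.
#'
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz; band edges must lie below `fs/2`.
#' @param order filter order (taps - 1); must be even.
#' @param window taper name; only "hamming" is offered.
#' @return Numeric coefficient vector of length `order + 1` with attributes
#'   `band` and `fs`.
#' @export
design_bandpass <- function(band, fs = 200, order = 4000,
                            window = "hamming") {
  stopifnot(inherits(band, "band_spec"))
  if (band$high_hz >= fs / 2) {
    stop("band edge ", band$high_hz, " Hz is not below Nyquist (",
         fs / 2, " Hz)")
  }
  if (order %% 2 != 0) stop("order must be even (type-I linear phase)")
  window <- match.arg(window, "hamming")
  key <- paste("bp", band$name, band$low_hz, band$high_hz, fs, order,
               window, sep = "_")
  h <- get0(key, envir = .design_cache)
  if (is.null(h)) {
    h <- as.numeric(signal::fir1(order,
                                 c(band$low_hz, band$high_hz) / (fs / 2),
                                 type = "pass",
                                 window = signal::hamming(order + 1)))
    h <- (h + rev(h)) / 2   # enforce exact type-I symmetry
    assign(key, h, envir = .design_cache)
  }
  structure(h, band = band, fs = fs)
}

#' Design a 60 Hz band-stop (notch) filter
#'
#' Optional mains-interference notch (58-62 Hz stop band by default),
#' applied before band filtering when enabled. Off by default: synthetic
#' data carries no line noise.
#'
#' @inheritParams design_bandpass
#' @param low_hz,high_hz stop-band edges in Hz.
#' @export
design_bandstop <- function(fs = 200, order = 4000, low_hz = 58,
                            high_hz = 62) {
  if (high_hz >= fs / 2) stop("stop-band edge must be below Nyquist")
  if (order %% 2 != 0) stop("order must be even")
  h <- as.numeric(signal::fir1(order, c(low_hz, high_hz) / (fs / 2),
                               type = "stop",
                               window = signal::hamming(order + 1)))
  h <- (h + rev(h)) / 2   # enforce exact type-I symmetry
  structure(h, band = band_spec("notch60", low_hz, high_hz), fs = fs)
}

#' Frequency response of an FIR filter
#'
#' @param coeffs FIR coefficient vector.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return Complex response at `f`.
#' @export
freq_response <- function(coeffs, f, fs = 200) {
  k <- seq_along(coeffs) - 1
  vapply(f, function(fi) {
    sum(coeffs * exp(-2i * pi * fi / fs * k))
  }, complex(1))
}

# caches: designed filters by spec; frequency responses by (nfft, coeffs)
.design_cache <- new.env(parent = emptyenv())
.resp_cache <- new.env(parent = emptyenv())

# symmetric reflection padding for FFT filtering: at least `min_pad` per
# side (so the circular wrap stays off the retained samples), widened to a
# power-of-two transform length when possible
choose_fft_pad <- function(n, min_pad) {
  m <- 2^ceiling(log2(n + 2 * min_pad))
  delta <- m - n - 2 * min_pad
  pad <- if (delta %% 2 == 0) min_pad + delta %/% 2 else min_pad
  if (pad > n - 2) pad <- min_pad
  pad
}

filter_bank_responses <- function(filters, m) {
  lapply(filters, function(h) {
    key <- paste0("M", m, "_", length(h), "_",
                  format(sum(h * seq_along(h)), digits = 17), "_",
                  format(h[1], digits = 17))
    got <- get0(key, envir = .resp_cache)
    if (!is.null(got)) return(got)
    H <- stats::fft(c(h, rep(0, m - length(h))))
    assign(key, H, envir = .resp_cache)
    H
  })
}

#' Apply FIR filters to a recording
#'
#' Filters every channel by FFT convolution with reflection padding, then
#' removes the `order/2`-sample group delay so the output is time-aligned
#' with the input and of equal length. `apply_filter_bank()` filters with
#' several FIRs of the same length while reusing one forward transform per
#' channel (the per-band work is a spectrum multiply and inverse transform).
#'
#' @param rec an [eeg_recording()]; must be longer than the filter.
#' @param coeffs coefficients from [design_bandpass()].
#' @param filters named list of coefficient vectors of equal length.
#' @return A filtered [eeg_recording()]; for the bank version, a named list
#'   of recordings.
#' @export
apply_filter <- function(rec, coeffs) {
  apply_filter_bank(rec, list(band = coeffs))[[1]]
}

#' @rdname apply_filter
#' @export
apply_filter_bank <- function(rec, filters) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- unique(vapply(filters, length, 1L))
  if (length(L) != 1) stop("all filters in a bank must share one length")
  if ((L - 1) %% 2 != 0) stop("filter length must be odd (even order)")
  n <- ncol(rec$data)
  if (n <= L) {
    stop("record (", n, " samples) must be longer than the filter (",
         L, " taps)")
  }
  delay <- (L - 1) %/% 2
  pad <- choose_fft_pad(n, delay)  # pad + delay >= L - 1: wrap stays clear
  m <- n + 2 * pad
  H <- filter_bank_responses(filters, m)
  out <- cpp_filter_bank(t(rec$data), H, pad, delay)
  names(out) <- names(filters)
  lapply(out, function(Y) {
    eeg_recording(t(Y), fs = rec$fs, montage = rec$montage,
                  subject_id = rec$subject_id)
  })
}

#' Cut a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping `epoch_len_s`-second windows in temporal
#' order; a trailing partial window is discarded. With `drop_edges` the
#' first and last epochs are removed (they absorb residual filter-edge
#' transients), so a 600-s record yields 118 analyzed 5-s epochs.
#'
#' @param rec an [eeg_recording()] (typically band-filtered).
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param drop_edges drop the first and last epoch (default TRUE).
#' @return A `band_epochs` object: list with `epochs` (samples x channels x
#'   epochs array), `fs`, `epoch_len_s`, `montage`, `band` (NULL when the
#'   recording carries no band tag).
#' @examples
#' rec <- eeg_recording(matrix(rnorm(16 * 3000), 16), fs = 200)
#' dim(segment_epochs(rec)$epochs)  # 1000 x 16 x 1
#' @export
segment_epochs <- function(rec, epoch_len_s = 5, drop_edges = TRUE,
                           band = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  S <- round(epoch_len_s * rec$fs)
  n_tot <- ncol(rec$data) %/% S
  need <- if (drop_edges) 3L else 1L
  if (n_tot < need) {
    stop("record too short: ", n_tot, " whole epoch(s) of ", epoch_len_s,
         " s, need at least ", need,
         if (drop_edges) " (first and last are dropped)" else "")
  }
  keep <- if (drop_edges) seq.int(2L, n_tot - 1L) else seq_len(n_tot)
  ep <- array(0, dim = c(S, nrow(rec$data), length(keep)))
  for (i in seq_along(keep)) {
    cols <- ((keep[i] - 1L) * S + 1L):(keep[i] * S)
    ep[, , i] <- t(rec$data[, cols, drop = FALSE])
  }
  structure(list(epochs = ep, fs = rec$fs, epoch_len_s = epoch_len_s,
                 montage = rec$montage, band = band,
                 subject_id = rec$subject_id),
            class = "band_epochs")
}

#' @export
print.band_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat("<band_epochs> ", if (!is.null(x$band)) paste0(x$band$name, ": "),
      d[3], " epochs x ", d[2], " channels x ", d[1], " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}
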