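# Zero-phase filtering. Band-passes use windowed-sinc (Hamming) FIR
# filters applied forward and backward via FFT convolution, so the
# passband is flat, the phase is zero and stopband attenuation is the
# square of the single-pass response. The notch is a second-order
# Butterworth band-stop run through signal::filtfilt.

# FIR length from transition bandwidth (Hamming: ~3.3 / normalized bw)
fir_ntaps <- function(trans_hz, srate) {
  n <- ceiling(3.3 / (trans_hz / srate))
  if (n %% 2 == 0) n <- n + 1
  n
}

design_bandpass <- function(low, high, srate) {
  nyq <- srate / 2
  if (!(low < high && high < nyq)) {
    stop("need low < high < srate/2 (Nyquist)", call. = FALSE)
  }
  trans <- min(low, 2)
  n <- fir_ntaps(trans, srate)
  signal::fir1(n - 1, c(low, high) / nyq, type = "pass")
}

design_notch <- function(notch, srate, width = 3) {
  nyq <- srate / 2
  n <- fir_ntaps(width / 2, srate)
  signal::fir1(n - 1, c(notch - width / 2, notch + width / 2) / nyq,
               type = "stop")
}

# Zero-phase FIR application along rows of a channels x samples matrix.
# The taps from fir1 are symmetric (linear phase), so a single FFT
# convolution with group-delay compensation has exactly zero phase.
# Edges are padded by odd reflection to limit transients.
fir_zerophase <- function(x, b) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nb <- length(b)
  n <- ncol(x)
  npad <- min(nb, n - 1)
  left <- x[, npad:1 + 1, drop = FALSE]          # reflected interior points
  right <- x[, n - (1:npad), drop = FALSE]
  xp <- cbind(2 * x[, 1] - left, x, 2 * x[, n] - right)
  np <- ncol(xp)

  nfft <- stats::nextn(np + nb - 1, 2)
  B <- fft(c(b, rep(0, nfft - nb)))
  X <- mvfft(t(cbind(xp, matrix(0, nrow(xp), nfft - np))))
  y <- Re(mvfft(X * B, inverse = TRUE)) / nfft   # linear convolution
  d <- (nb - 1) / 2                              # group delay of symmetric FIR
  y <- t(y)[, d + seq_len(np), drop = FALSE]
  y[, npad + seq_len(n), drop = FALSE]
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase windowed-sinc FIR band-pass plus an FIR band-stop at the
#' line frequency; the two symmetric tap vectors are convolved so both
#' apply in a single zero-phase pass. Applied to continuous data
#' (filter before epoching where possible).
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (`low < high < srate/2`).
#' @param notch Line frequency in Hz, or `NULL` to skip the notch.
#' @return The filtered recording.
#' @export
bandpass_and_notch <- function(rec, low = 0.5, high = 80, notch = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  b <- design_bandpass(low, high, rec$srate)
  if (!is.null(notch) && notch < rec$srate / 2 && notch > low &&
      notch < high) {
    b <- stats::convolve(b, rev(design_notch(notch, rec$srate)),
                         type = "open")
  }
  out <- rec
  out$data <- fir_zerophase(rec$data, b)
  rownames(out$data) <- rec$labels
  out
}

#' Microstate-band filter (2-20 Hz)
#'
#' Zero-phase FIR band-pass applied before segmentation, preserving the
#' epoch structure. By default the concatenated signal is filtered in
#' one pass -- retained epochs are contiguous 2 s blocks of the same
#' recording, so this avoids the edge transients that per-epoch
#' filtering re-introduces at every epoch boundary; `per_epoch = TRUE`
#' filters each epoch independently with reflection padding instead.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param per_epoch Filter each epoch independently.
#' @return The filtered recording.
#' @export
microstate_band <- function(rec, low = 2, high = 20, per_epoch = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  b <- design_bandpass(low, high, rec$srate)
  out <- rec
  if (per_epoch && !is.null(rec$epochs)) {
    for (idx in epoch_indices(rec)) {
      out$data[, idx] <- fir_zerophase(rec$data[, idx, drop = FALSE], b)
    }
  } else {
    out$data <- fir_zerophase(rec$data, b)
  }
  rownames(out$data) <- rec$labels
  out
}
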