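#' Segment a continuous recording into fixed-length epochs
#'
#' @param rec A continuous [eeg_recording()].
#' @param length_s Epoch length in seconds (default 2 s).
#' @return The recording with `epochs` set; the trailing remainder is
#'   dropped.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(rec$epochs)) stop("recording is already epoched", call. = FALSE)
  len <- round(length_s * rec$srate)
  n_ep <- floor(n_samples(rec) / len)
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  out <- rec
  out$data <- rec$data[, seq_len(n_ep * len), drop = FALSE]
  out$epochs <- tibble::tibble(
    start = (seq_len(n_ep) - 1L) * len + 1L,
    end = seq_len(n_ep) * len
  )
  out
}

#' Reject epochs by amplitude criterion
#'
#' An epoch is removed iff strictly more than `max_bad_channels`
#' channels contain any sample with absolute amplitude above `amp_uv`
#' (absolute voltage by default; set `peak_to_peak = TRUE` to use the
#' within-epoch peak-to-peak range instead).
#'
#' @param rec An epoched [eeg_recording()].
#' @param amp_uv Amplitude threshold in microvolts.
#' @param max_bad_channels Largest tolerated number of offending
#'   channels per epoch.
#' @param peak_to_peak Use peak-to-peak amplitude instead of absolute.
#' @return List with `recording` (retained epochs, re-concatenated) and
#'   `qc` (one-row tibble: total, rejected and retained epoch counts and
#'   retained seconds).
#' @export
reject_bad_epochs <- function(rec, amp_uv = 80, max_bad_channels = 10,
                              peak_to_peak = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"), !is.null(rec$epochs))
  idx <- epoch_indices(rec)
  bad_count <- vapply(idx, function(i) {
    seg <- rec$data[, i, drop = FALSE]
    per_ch <- if (peak_to_peak) {
      apply(seg, 1, function(v) diff(range(v)))
    } else {
      apply(abs(seg), 1, max)
    }
    sum(per_ch > amp_uv)
  }, numeric(1))
  keep <- bad_count <= max_bad_channels
  len <- rec$epochs$end - rec$epochs$start + 1L
  out <- rec
  out$data <- rec$data[, unlist(idx[keep]), drop = FALSE]
  ends <- cumsum(len[keep])
  out$epochs <- tibble::tibble(start = ends - len[keep] + 1L, end = ends)
  qc <- tibble::tibble(
    total_epochs = length(idx),
    rejected_epochs = sum(!keep),
    retained_epochs = sum(keep),
    retained_seconds = sum(len[keep]) / rec$srate
  )
  list(recording = out, qc = qc)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample;
#' idempotent.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced recording (`reference = "average"`).
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out$reference <- "average"
  out
}

#' Run the preprocessing chain
#'
#' Fixed order: broadband band-pass + notch on the continuous signal,
#' epoching, bad-channel spherical-spline interpolation, amplitude-based
#' epoch rejection, an optional external artifact-removal hook (e.g. an
#' ICA-based cleaner), average referencing, then the microstate band
#' filter per epoch.
#'
#' @param rec Continuous [eeg_recording()].
#' @param band Broadband edges in Hz.
#' @param notch Line frequency (Hz) or `NULL`.
#' @param epoch_s Epoch length (s).
#' @param bad_channels Channel labels to interpolate (may be empty).
#' @param amp_uv,max_bad_channels Epoch-rejection settings.
#' @param ms_band Microstate band edges in Hz.
#' @param min_retained_s Minimum retained data for inclusion (s).
#' @param artifact_hook Optional `function(rec) rec` applied after epoch
#'   rejection, before average referencing.
#' @return List with `recording` (cleaned, average-referenced, 2-20 Hz)
#'   and `qc` (one-row tibble, includes interpolated-channel info and an
#'   `included` flag).
#' @export
preprocess_recording <- function(rec, band = c(0.5, 80), notch = 50,
                                 epoch_s = 2, bad_channels = character(),
                                 amp_uv = 80, max_bad_channels = 10,
                                 ms_band = c(2, 20),
                                 min_retained_s = 180,
                                 artifact_hook = NULL) {
  out <- bandpass_and_notch(rec, band[1], band[2], notch)
  out <- epoch_recording(out, epoch_s)
  if (length(bad_channels) > 0) {
    out <- interpolate_channels(out, bad_channels)
  }
  rej <- reject_bad_epochs(out, amp_uv, max_bad_channels)
  out <- rej$recording
  if (!is.null(artifact_hook)) out <- artifact_hook(out)
  out <- average_reference(out)
  out <- microstate_band(out, ms_band[1], ms_band[2])
  qc <- dplyr::mutate(
    rej$qc,
    interpolated_n = length(bad_channels),
    interpolated_channels = paste(bad_channels, collapse = ","),
    included = .data$retained_seconds >= min_retained_s
  )
  list(recording = out, qc = qc)
}
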