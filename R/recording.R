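#' EEG recording container
#'
#' A light S3 container for multichannel EEG: a channels x samples
#' matrix in microvolts plus sampling rate, channel labels, sensor
#' positions, optional epoch boundaries and the reference state.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param srate Sampling rate in Hz.
#' @param labels Channel labels (defaults to rownames of `data`).
#' @param positions Tibble of sensor positions as returned by
#'   [montage_positions()], matched to `labels`.
#' @param epochs Optional tibble with integer columns `start`, `end`
#'   (inclusive sample indices); `NULL` means continuous.
#' @param reference `"original"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, labels = rownames(data),
                          positions = NULL, epochs = NULL,
                          reference = c("original", "average")) {
  reference <- match.arg(reference)
  stopifnot(is.matrix(data), is.numeric(data), srate > 0)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("labels must match the number of channels", call. = FALSE)
  }
  rownames(data) <- labels
  if (!is.null(epochs)) {
    epochs <- tibble::as_tibble(epochs)
    stopifnot(all(c("start", "end") %in% names(epochs)))
    if (any(epochs$start > epochs$end) ||
        any(epochs$end > ncol(data)) || any(epochs$start < 1)) {
      stop("invalid epoch bounds", call. = FALSE)
    }
  }
  structure(
    list(data = data, srate = srate, labels = labels,
         positions = positions, epochs = epochs, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz (", round(ncol(x$data) / x$srate, 1),
      " s), reference: ", x$reference, sep = "")
  if (!is.null(x$epochs)) cat(", ", nrow(x$epochs), " epochs", sep = "")
  cat("\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

# list of sample-index vectors, one per epoch (whole recording if unepoched)
epoch_indices <- function(rec) {
  if (is.null(rec$epochs)) return(list(seq_len(n_samples(rec))))
  purrr::map2(rec$epochs$start, rec$epochs$end, seq.int)
}

# epoch id per sample (NA outside any epoch)
epoch_of_sample <- function(rec) {
  out <- rep(NA_integer_, n_samples(rec))
  idx <- epoch_indices(rec)
  for (i in seq_along(idx)) out[idx[[i]]] <- i
  out
}

#' Convert a recording to a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `time_s`, `channel`, `value`.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_len(n_samples(x)), each = n_channels(x)),
    time_s = rep((seq_len(n_samples(x)) - 1) / x$srate, each = n_channels(x)),
    channel = rep(x$labels, times = n_samples(x)),
    value = as.vector(x$data)
  )
}
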