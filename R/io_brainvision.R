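# Minimal BrainVision I/O: text .vhdr header, text .vmrk markers and a
# float32 multiplexed .eeg payload. Covers what the pipeline needs
# (labels, sampling rate, data); amplifier-specific header fields are
# not modeled.

#' Write a recording as a BrainVision file triplet
#'
#' @param rec An [eeg_recording()].
#' @param basename Path without extension; `.vhdr`, `.vmrk` and `.eeg`
#'   are created next to each other.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  stem <- basename(basename)
  nch <- n_channels(rec)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$labels)
  )
  writeLines(hdr, vhdr)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", stem, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4)  # multiplexed: channels fast
  invisible(basename)
}

#' Read a BrainVision file triplet
#'
#' Supports the subset written by [write_brainvision()]: binary
#' IEEE_FLOAT_32 or INT_16 payloads in multiplexed orientation.
#'
#' @param vhdr Path to the `.vhdr` header.
#' @param positions Optional positions tibble to attach (matched by
#'   label).
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr, positions = NULL) {
  lines <- readLines(vhdr, warn = FALSE)
  grab <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop("missing header key: ", key, call. = FALSE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  nch <- as.integer(grab("NumberOfChannels"))
  srate <- 1e6 / as.numeric(grab("SamplingInterval"))
  fmt <- grab("BinaryFormat")
  orient <- grab("DataOrientation")
  if (orient != "MULTIPLEXED") {
    stop("unsupported orientation: ", orient, call. = FALSE)
  }
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(ch_lines, function(l) {
    strsplit(sub("^Ch[0-9]+=", "", l), ",")[[1]][1]
  }, "", USE.NAMES = FALSE)
  stopifnot(length(labels) == nch)
  eeg_path <- file.path(dirname(vhdr), grab("DataFile"))
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = sz / 4, size = 4)
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE)
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  data <- matrix(raw_vals, nrow = nch)
  eeg_recording(data, srate, labels = labels, positions = positions)
}
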