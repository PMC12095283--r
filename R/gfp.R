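#' Global field power
#'
#' GFP at sample t is the spatial standard deviation of the
#' instantaneous scalp map across channels (with average reference this
#' equals the map's RMS). Requires an average-referenced recording.
#'
#' @param rec An average-referenced [eeg_recording()].
#' @return Tibble with columns `sample`, `epoch`, `gfp`; sampling rate
#'   kept in attribute `"srate"`.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "average") {
    stop("GFP requires an average-referenced recording", call. = FALSE)
  }
  x <- sweep(rec$data, 2, colMeans(rec$data))  # numerically exact centering
  g <- sqrt(colMeans(x^2))
  out <- tibble::tibble(
    sample = seq_len(n_samples(rec)),
    epoch = epoch_of_sample(rec),
    gfp = g
  )
  attr(out, "srate") <- rec$srate
  out
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series within each epoch, excluding
#' epoch boundaries, thinned so consecutive peaks are at least
#' `min_separation_ms` apart (on a conflict the larger peak wins; equal
#' peaks keep the earlier).
#'
#' @param gfp Tibble from [compute_gfp()].
#' @param min_separation_ms Minimum peak spacing in ms.
#' @return The peak rows of `gfp` (columns `sample`, `epoch`, `gfp`).
#' @export
find_gfp_peaks <- function(gfp, min_separation_ms = 10) {
  srate <- attr(gfp, "srate")
  if (is.null(srate)) stop("gfp must come from compute_gfp()", call. = FALSE)
  min_gap <- max(1L, round(min_separation_ms * srate / 1000))
  pick <- function(d) {
    g <- d$gfp
    n <- length(g)
    if (n < 3) return(d[0, ])
    i <- 2:(n - 1)
    is_pk <- g[i] > g[i - 1] & g[i] > g[i + 1]
    cand <- i[is_pk]
    if (length(cand) == 0) return(d[0, ])
    ord <- cand[order(-g[cand], cand)]      # by height, earlier first on ties
    keep <- logical(n)
    blocked <- logical(n)
    for (p in ord) {
      if (!blocked[p]) {
        keep[p] <- TRUE
        lo <- max(1, p - min_gap + 1); hi <- min(n, p + min_gap - 1)
        blocked[lo:hi] <- TRUE
      }
    }
    d[keep, ]
  }
  out <- dplyr::bind_rows(lapply(split(gfp, gfp$epoch), pick))
  out <- dplyr::arrange(out, .data$sample)
  attr(out, "srate") <- srate
  out
}

#' Extract scalp maps at GFP peaks
#'
#' @param rec The recording the peaks were computed from.
#' @param peaks Tibble from [find_gfp_peaks()].
#' @param max_maps Optional cap: a seeded random subsample of peaks used
#'   to bound clustering cost (`NULL` keeps all).
#' @param seed Seed for the subsample.
#' @return Matrix (n_peaks x channels) of raw peak maps; peak GFP in
#'   attribute `"gfp"`.
#' @export
peak_maps <- function(rec, peaks, max_maps = NULL, seed = 1L) {
  if (!is.null(max_maps) && nrow(peaks) > max_maps) {
    set.seed(seed)
    peaks <- peaks[sort(sample.int(nrow(peaks), max_maps)), ]
  }
  m <- t(rec$data[, peaks$sample, drop = FALSE])
  attr(m, "gfp") <- peaks$gfp
  m
}
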