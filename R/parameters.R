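#' Microstate temporal parameters
#'
#' Computes the canonical per-state summary of a cleaned label
#' sequence:
#' \itemize{
#'   \item duration: mean length (ms) of that state's interior segments
#'     (segments truncated by epoch boundaries are excluded, since their
#'     dwell is censored);
#'   \item occurrence: interior segments per analyzed second (Hz);
#'   \item coverage: percentage of assigned samples carrying the state
#'     (edge segments included); coverages sum to 100;
#'   \item GEV: GFP-weighted squared spatial correlation between each
#'     sample and its assigned template, normalized by total squared
#'     GFP;
#'   \item transition probabilities: ordered within-epoch segment
#'     adjacencies x -> y, pooled over all off-diagonal pairs (the K(K-1)
#'     cells sum to 1).
#' }
#'
#' @param labels `ms_labels` (after smoothing / short-segment cleanup).
#' @param rec,templates Recording and template set (for GEV).
#' @param include_edge_in_duration Also count boundary-truncated
#'   segments in duration/occurrence (off by default).
#' @return Object of class `ms_params`: list with `params` (tibble:
#'   state, duration_ms, occurrence_hz, coverage_pct), `gev`,
#'   `transitions` (tibble: from, to, n, probability), `analyzed_s`.
#' @export
microstate_parameters <- function(labels, rec, templates,
                                  include_edge_in_duration = FALSE) {
  stopifnot(inherits(labels, "ms_labels"))
  tm <- if (inherits(templates, "ms_templates")) templates$maps else templates
  k <- nrow(tm)
  state_names <- rownames(tm)
  if (is.null(state_names)) state_names <- paste0("M", seq_len(k))
  segs <- segment_table(labels)
  segs <- segs[!is.na(segs$state), ]
  analyzed_s <- sum(!is.na(labels$epoch)) / labels$srate
  assigned <- sum(!is.na(labels$states) & !is.na(labels$epoch))

  per_state <- lapply(seq_len(k), function(j) {
    sj <- segs[segs$state == j, ]
    interior <- if (include_edge_in_duration) sj else sj[!sj$edge, ]
    n_samp <- sum(labels$states == j & !is.na(labels$epoch), na.rm = TRUE)
    tibble::tibble(
      state = state_names[j],
      duration_ms = if (nrow(interior) > 0) mean(interior$duration_ms)
                    else NA_real_,
      occurrence_hz = nrow(interior) / analyzed_s,
      coverage_pct = if (assigned > 0) 100 * n_samp / assigned else 0
    )
  })
  params <- dplyr::bind_rows(per_state)

  gev <- gev_of_assignment(t(rec$data), tm, labels$states,
                           weights = labels$gfp)

  # ordered segment adjacencies within epochs, pooled normalization
  trans_counts <- matrix(0L, k, k)
  for (e in unique(segs$epoch)) {
    s <- segs$state[segs$epoch == e]
    if (length(s) >= 2) {
      for (i in seq_len(length(s) - 1)) {
        if (s[i] != s[i + 1]) {
          trans_counts[s[i], s[i + 1]] <- trans_counts[s[i], s[i + 1]] + 1L
        }
      }
    }
  }
  total <- sum(trans_counts)
  grid <- expand.grid(from = seq_len(k), to = seq_len(k))
  grid <- grid[grid$from != grid$to, ]
  transitions <- tibble::tibble(
    from = state_names[grid$from],
    to = state_names[grid$to],
    n = trans_counts[cbind(grid$from, grid$to)],
    probability = if (total > 0) trans_counts[cbind(grid$from, grid$to)] / total
                  else 0
  )
  transitions <- dplyr::arrange(transitions, .data$from, .data$to)

  structure(
    list(params = params, gev = gev, transitions = transitions,
         analyzed_s = analyzed_s, k = k),
    class = "ms_params"
  )
}

#' @export
print.ms_params <- function(x, ...) {
  cat("<ms_params> ", x$k, " states over ", round(x$analyzed_s, 1),
      " s; GEV = ", sprintf("%.3f", x$gev), "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @rdname microstate_parameters
#' @param x An `ms_params` object.
#' @param ... Unused.
#' @return `tidy()`: the per-state parameter tibble with `gev` attached.
#' @method tidy ms_params
#' @export
tidy.ms_params <- function(x, ...) {
  dplyr::mutate(x$params, gev = x$gev)
}
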