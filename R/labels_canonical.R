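#' Assign canonical A-D labels to a template set
#'
#' Matches each fitted template to the built-in archetype maps by
#' absolute spatial correlation and finds the one-to-one assignment
#' maximizing the total correlation (exhaustive over permutations,
#' optimal for K <= 7). With K = 4 the canonical letters A-D are
#' applied; otherwise templates keep generic labels M1..MK with a
#' warning. Label assignment is invariant to template polarity.
#'
#' @param ts An `ms_templates` object whose channel names match the
#'   built-in montage.
#' @param archetypes Optional reference `ms_templates` (defaults to
#'   [make_templates()] on the matching channels).
#' @return `ts` with rows reordered to canonical order, labels set, and
#'   the correlation matrix stored in `provenance$label_corr`.
#' @export
canonical_labels <- function(ts, archetypes = NULL) {
  stopifnot(inherits(ts, "ms_templates"))
  k <- nrow(ts$maps)
  if (k != 4 && is.null(archetypes)) {
    warning("canonical A-D labeling defined for K = 4; keeping M labels")
    ts$labels <- paste0("M", seq_len(k))
    rownames(ts$maps) <- ts$labels
    return(ts)
  }
  if (is.null(archetypes)) {
    chans <- colnames(ts$maps)
    arch_full <- make_templates(64, 4)
    if (is.null(chans) || !all(chans %in% colnames(arch_full$maps))) {
      stop("template channels do not match the built-in montage",
           call. = FALSE)
    }
    am <- normalize_maps(arch_full$maps[, chans, drop = FALSE])
    rownames(am) <- rownames(arch_full$maps)
    archetypes <- new_ms_templates(am, positions = arch_full$positions)
  }
  ka <- nrow(archetypes$maps)
  stopifnot(k == ka)
  cc <- abs(spatial_correlation(ts$maps, archetypes$maps))
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(cc[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]   # template i -> archetype best[i]
  ord <- order(best)
  out <- ts
  out$maps <- ts$maps[ord, , drop = FALSE]
  out$labels <- rownames(archetypes$maps)
  rownames(out$maps) <- out$labels
  out$provenance$label_corr <- cc
  out$provenance$label_assignment <- best
  out
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}
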