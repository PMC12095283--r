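#' Canonical microstate archetype maps
#'
#' Constructs smooth, dipole-like template topographies over a montage,
#' matching the classical four-class description: maps A and B are
#' oriented left-right diagonal dipoles (left-anterior/right-posterior
#' and right-anterior/left-posterior), map D is an anterior-posterior
#' dipole, and map C has its extremum over the anterior central region.
#' Maps are zero-mean across channels and unit L2 norm, and any pair has
#' absolute spatial correlation at most 0.7.
#'
#' @param n_channels Number of channels (>= 8). Channels are drawn from
#'   the 64-channel montage; values below 64 take an evenly spaced subset.
#' @param k Number of templates, 2..7. Beyond the four built-in
#'   archetypes, additional maps require `orientations`.
#' @param geometry Montage name passed to [montage_positions()].
#' @param seed Integer seed (the archetypes are deterministic; the seed
#'   is recorded for provenance and reserved for perturbed variants).
#' @param orientations Optional list of 2-vectors (x, y direction on the
#'   disc) defining extra dipolar maps for k > 4.
#' @return An object of class `ms_templates`: list with `maps` (k x C,
#'   rownames are labels), `labels`, `positions`, `gev_total`,
#'   `k_criteria`, `provenance`.
#' @export
make_templates <- function(n_channels = 64, k = 4, geometry = "standard-64",
                           seed = 1L, orientations = NULL) {
  if (n_channels < 8) stop("need at least 8 channels", call. = FALSE)
  if (k < 1 || k > 7) stop("k must be in 1..7", call. = FALSE)
  pos <- montage_positions(geometry)
  if (n_channels > nrow(pos)) {
    stop("montage provides only ", nrow(pos), " channels", call. = FALSE)
  }
  if (n_channels < nrow(pos)) {
    keep <- unique(round(seq(1, nrow(pos), length.out = n_channels)))
    pos <- pos[keep, , drop = FALSE]
  }
  x <- pos$x2d; y <- pos$y2d

  gauss <- function(cx, cy, s) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  arch <- list(
    A = -x + 0.5 * y,                        # left-anterior / right-posterior
    B = x + 0.5 * y,                         # right-anterior / left-posterior
    C = gauss(0, 0.4, 0.3),                  # anterior-central focal peak
    D = y                                    # anterior-posterior dipole
  )
  if (k > length(arch)) {
    if (is.null(orientations) || length(orientations) < k - length(arch)) {
      stop("k > 4 requires an `orientations` list for the extra maps",
           call. = FALSE)
    }
    for (j in seq_len(k - length(arch))) {
      o <- orientations[[j]]
      arch[[paste0("M", length(arch) + 1)]] <- (o[1] * x + o[2] * y) /
        sqrt(sum(o^2))
    }
  }
  maps <- do.call(rbind, arch[seq_len(k)])
  maps <- normalize_maps(maps)
  rownames(maps) <- names(arch)[seq_len(k)]
  colnames(maps) <- pos$label

  if (k > 1) {
    cc <- abs(spatial_correlation(maps, maps))
    diag(cc) <- 0
    if (max(cc) > 0.7) {
      warning("archetype pair with |spatial correlation| > 0.7: ",
              signif(max(cc), 3))
    }
  }
  new_ms_templates(maps, positions = pos,
                   provenance = list(source = "archetypes", seed = seed,
                                     geometry = geometry))
}

new_ms_templates <- function(maps, positions = NULL, gev_total = NA_real_,
                             k_criteria = NULL, provenance = list()) {
  structure(
    list(maps = maps, labels = rownames(maps), positions = positions,
         gev_total = gev_total, k_criteria = k_criteria,
         provenance = provenance),
    class = "ms_templates"
  )
}

#' @export
print.ms_templates <- function(x, ...) {
  cat("<ms_templates> ", nrow(x$maps), " maps x ", ncol(x$maps),
      " channels (", paste(x$labels, collapse = ", "), ")\n", sep = "")
  if (!is.na(x$gev_total)) {
    cat("  total GEV: ", sprintf("%.3f", x$gev_total), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a template set to long format
#'
#' @param x An `ms_templates` object.
#' @param ... Unused.
#' @return Tibble with columns `label`, `channel`, `value` (plus sensor
#'   coordinates when the object carries positions).
#' @method tidy ms_templates
#' @export
tidy.ms_templates <- function(x, ...) {
  out <- tibble::as_tibble(x$maps, rownames = NA)
  out <- tibble::tibble(
    label = rep(x$labels, each = ncol(x$maps)),
    channel = rep(colnames(x$maps), times = nrow(x$maps)),
    value = as.vector(t(x$maps))
  )
  if (!is.null(x$positions)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$positions, "label", "x2d", "y2d"),
      by = c(channel = "label")
    )
  }
  out
}
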