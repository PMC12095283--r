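#' Topographic atomize-and-agglomerate hierarchical clustering
#'
#' Bottom-up clustering of scalp maps under the polarity-invariant
#' correlation metric. Every map starts as its own cluster; at each step
#' the cluster contributing least global explained variance (GEV) is
#' dissolved ("atomized") and each of its member maps is reassigned to
#' the cluster whose centroid it matches best in absolute spatial
#' correlation; affected centroids are recomputed as polarity-aligned
#' means (optionally the first principal pattern). Stops at `k`
#' clusters.
#'
#' @param maps Matrix (N x C) of maps; normalized internally.
#' @param k Target number of clusters (N >= k).
#' @param weights Per-map GEV weights, typically the GFP at the peak the
#'   map was taken from; defaults to the maps' own GFP (equal weights if
#'   the maps are pre-normalized).
#' @param centroid `"aligned_mean"` (default) or `"principal"` (first
#'   eigenvector of the members' scatter).
#' @return An `ms_templates` object; `gev_total` holds the final GEV,
#'   `provenance$assignment` the cluster id of every input map.
#' @export
taahc <- function(maps, k, weights = NULL,
                  centroid = c("aligned_mean", "principal")) {
  centroid <- match.arg(centroid)
  stopifnot(is.matrix(maps), nrow(maps) >= k, k >= 1)
  if (is.null(weights)) weights <- apply(maps, 1, sd_pop)
  keep <- weights > 0
  if (!all(keep)) {
    maps <- maps[keep, , drop = FALSE]
    weights <- weights[keep]
    if (nrow(maps) < k) stop("too few nonzero maps for k", call. = FALSE)
  }
  x <- normalize_maps(maps)
  n <- nrow(x)
  w2 <- weights^2
  W <- sum(w2)

  compute_centroid <- function(members) {
    xm <- x[members, , drop = FALSE]
    if (length(members) == 1) return(xm[1, ])
    if (centroid == "principal") {
      sc <- crossprod(xm * weights[members])
      v <- eigen(sc, symmetric = TRUE)$vectors[, 1]
      return(drop(normalize_maps(v)))
    }
    ref <- xm[1, ]
    for (rep in 1:2) {                       # align, average, re-align once
      sgn <- sign(drop(xm %*% ref)); sgn[sgn == 0] <- 1
      ref <- drop(normalize_maps(colSums(xm * sgn)))
    }
    ref
  }

  assign_id <- seq_len(n)
  centroids <- x
  active <- rep(TRUE, n)
  # GEV contribution of cluster j = sum over members (w_i r_ij)^2 / W
  contrib <- w2 / W                          # singletons: r = 1

  member_list <- as.list(seq_len(n))
  n_active <- n
  while (n_active > k) {
    worst <- which(active)[which.min(contrib[active])]
    members <- member_list[[worst]]
    active[worst] <- FALSE
    cand <- which(active)
    r <- abs(x[members, , drop = FALSE] %*% t(centroids[cand, , drop = FALSE]))
    new_cl <- cand[max.col(r, ties.method = "first")]
    affected <- unique(new_cl)
    for (j in seq_along(members)) {
      cl <- new_cl[j]
      member_list[[cl]] <- c(member_list[[cl]], members[j])
      assign_id[members[j]] <- cl
    }
    member_list[[worst]] <- integer(0)
    for (cl in affected) {
      centroids[cl, ] <- compute_centroid(member_list[[cl]])
      rr <- drop(x[member_list[[cl]], , drop = FALSE] %*% centroids[cl, ])
      contrib[cl] <- sum((weights[member_list[[cl]]] * rr)^2) / W
    }
    n_active <- n_active - 1
  }

  cl_ids <- which(active)
  final <- centroids[cl_ids, , drop = FALSE]
  rownames(final) <- paste0("M", seq_len(k))
  colnames(final) <- colnames(maps)
  gev_total <- sum(contrib[cl_ids])
  if (k > 1) {
    cc <- abs(tcrossprod(final))
    diag(cc) <- 0
    if (max(cc) > 0.9999) {
      warning("duplicate templates in T-AAHC solution (degenerate input?)")
    }
  }
  assignment <- match(assign_id, cl_ids)
  new_ms_templates(final, gev_total = gev_total,
                   provenance = list(source = "taahc", k = k,
                                     assignment = assignment,
                                     centroid = centroid))
}

#' Global explained variance of a labeling
#'
#' GEV = sum_t (gfp_t * r_t)^2 / sum_t gfp_t^2 over assigned samples,
#' where r_t is the spatial correlation between the sample map and its
#' assigned template.
#'
#' @param maps Matrix (N x C) of sample maps.
#' @param templates Template matrix (K x C) or `ms_templates`.
#' @param assignment Integer template index per map (NA = unassigned).
#' @param weights Per-map GFP; defaults to the maps' own GFP.
#' @return Scalar in `[0, 1]`.
#' @export
gev_of_assignment <- function(maps, templates, assignment, weights = NULL) {
  tm <- if (inherits(templates, "ms_templates")) templates$maps else templates
  if (is.null(weights)) weights <- apply(maps, 1, sd_pop)
  ok <- !is.na(assignment) & weights > 0
  if (!any(ok)) return(0)
  x <- normalize_maps(maps[ok, , drop = FALSE])
  a <- normalize_maps(tm)
  r <- rowSums(x * a[assignment[ok], , drop = FALSE])
  sum((weights[ok] * r)^2) / sum(weights[ok]^2)
}
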