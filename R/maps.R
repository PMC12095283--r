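# Map normalization and spatial similarity primitives shared by the
# clustering, backfitting and synthetic modules. A "map" is one scalp
# topography: a numeric vector with one value per channel.

#' Normalize topographic maps
#'
#' Removes the channel mean (average reference) from each map and scales
#' it to unit L2 norm. Rows are maps, columns channels.
#'
#' @param maps Numeric matrix (K x C) or vector (one map).
#' @return Matrix of the same shape; zero-norm maps are left at zero.
#' @export
normalize_maps <- function(maps) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  nz <- nrm > 0
  maps[nz, ] <- maps[nz, , drop = FALSE] / nrm[nz]
  maps
}

#' Spatial correlation between sets of maps
#'
#' Pearson correlation across channels. Because both inputs are
#' average-referenced and unit-normalized first, this is the cosine of
#' the angle between the centered maps.
#'
#' @param a,b Map matrices (rows are maps) or single-map vectors.
#' @return Matrix of correlations, `nrow(a)` x `nrow(b)`.
#' @export
spatial_correlation <- function(a, b) {
  a <- normalize_maps(a)
  b <- normalize_maps(b)
  tcrossprod(a, b)
}

#' Global map dissimilarity (GMD)
#'
#' Polarity-invariant distance between two scalp maps: both maps are
#' average-referenced and scaled to unit global field power, and the
#' root-mean-square difference is minimized over polarity. Satisfies
#' GMD^2 = 2 (1 - |r|) with r the spatial Pearson correlation, so the
#' range is [0, sqrt(2)].
#'
#' @param u,v Numeric vectors on the same channels.
#' @return Scalar dissimilarity.
#' @export
gmd <- function(u, v) {
  if (length(u) != length(v)) stop("maps must share channels", call. = FALSE)
  gu <- sd_pop(u); gv <- sd_pop(v)
  if (gu == 0 || gv == 0) stop("GMD undefined for a zero-GFP map", call. = FALSE)
  r <- drop(spatial_correlation(u, v))
  sqrt(max(0, 2 * (1 - abs(r))))
}

# population standard deviation (spatial, across channels)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
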