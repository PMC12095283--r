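# Cluster-validity criteria for choosing the number of microstate
# classes. All indices operate on the polarity-invariant correlation
# distance d = 1 - |r|, so they are unchanged by sign flips of any map.
# The exact formulas of some proprietary variants are not public; these
# follow the standard cluster-validity literature.

#' Cluster-count selection criteria
#'
#' Clusters the peak maps with [taahc()] for each candidate k and
#' scores the solution with Davies-Bouldin, silhouette, Dunn,
#' point-biserial, Baker-Hubert Gamma, Krzanowski-Lai and the
#' predictive-residual cross-validation criterion. A meta-criterion
#' reports the modal best k across indices (ties resolved toward the
#' smaller k).
#'
#' @param maps N x C matrix of (GFP-peak) maps.
#' @param k_range Candidate cluster counts, within 2..10.
#' @param weights Optional per-map GFP weights (see [taahc()]).
#' @param max_maps Cap on the number of maps scored (seeded subsample).
#' @param seed Seed for the subsample.
#' @return Tibble with one row per k and one column per criterion, plus
#'   attributes `"votes"` (best k per criterion) and `"k_opt"` (the
#'   meta-criterion choice).
#' @export
k_selection_criteria <- function(maps, k_range = 2:7, weights = NULL,
                                 max_maps = 400, seed = 1L) {
  if (length(k_range) == 0) stop("empty k range", call. = FALSE)
  stopifnot(min(k_range) >= 2, max(k_range) <= 10)
  if (is.null(weights)) weights <- apply(maps, 1, sd_pop)
  if (nrow(maps) > max_maps) {
    set.seed(seed)
    i <- sort(sample.int(nrow(maps), max_maps))
    maps <- maps[i, , drop = FALSE]
    weights <- weights[i]
  }
  x <- normalize_maps(maps)
  n <- nrow(x)
  C <- ncol(x)
  D <- 1 - abs(tcrossprod(x))
  D[D < 0] <- 0

  ks <- sort(unique(c(k_range, min(k_range) - 1, max(k_range) + 1)))
  ks <- ks[ks >= 1 & ks <= n]
  fits <- lapply(ks, function(k) taahc(maps, k, weights = weights))
  names(fits) <- as.character(ks)
  Wk <- vapply(fits, function(f) {
    a <- f$provenance$assignment
    r <- rowSums(x * normalize_maps(f$maps)[a, , drop = FALSE])
    sum((1 - abs(r))^2)
  }, numeric(1))

  score_one <- function(k) {
    f <- fits[[as.character(k)]]
    a <- f$provenance$assignment
    cm <- normalize_maps(f$maps)
    r_own <- abs(rowSums(x * cm[a, , drop = FALSE]))
    d_own <- 1 - r_own

    # Davies-Bouldin (minimize)
    S <- vapply(seq_len(k), function(j) mean(d_own[a == j]), numeric(1))
    M <- 1 - abs(tcrossprod(cm))
    db <- mean(vapply(seq_len(k), function(i) {
      max(vapply(setdiff(seq_len(k), i),
                 function(j) (S[i] + S[j]) / max(M[i, j], 1e-12), numeric(1)))
    }, numeric(1)))

    # silhouette (maximize)
    sil <- mean(vapply(seq_len(n), function(i) {
      same <- a == a[i]; same[i] <- FALSE
      ai <- if (any(same)) mean(D[i, same]) else 0
      bi <- min(vapply(setdiff(seq_len(k), a[i]),
                       function(j) mean(D[i, a == j]), numeric(1)))
      (bi - ai) / max(ai, bi, 1e-12)
    }, numeric(1)))

    # Dunn (maximize): min between-cluster distance / max diameter
    diam <- max(vapply(seq_len(k), function(j) {
      m <- which(a == j)
      if (length(m) < 2) 0 else max(D[m, m])
    }, numeric(1)))
    sep <- min(vapply(seq_len(k - 1), function(i) {
      min(vapply((i + 1):k, function(j) min(D[a == i, a == j]), numeric(1)))
    }, numeric(1)))
    dunn <- sep / max(diam, 1e-12)

    # pairwise within/between split (upper triangle)
    ut <- upper.tri(D)
    same_cl <- outer(a, a, "==")
    dw <- D[ut & same_cl]
    db_pairs <- D[ut & !same_cl]

    # point-biserial (maximize): between minus within, scaled
    all_d <- c(dw, db_pairs)
    pb <- (mean(db_pairs) - mean(dw)) *
      sqrt(length(dw) * length(db_pairs)) / length(all_d) / sd(all_d)

    # Baker-Hubert Gamma (maximize), via sorted between distances
    sb <- sort(db_pairs)
    s_plus <- sum(length(sb) - findInterval(dw, sb))        # between > within
    s_minus <- sum(findInterval(dw, sb, left.open = TRUE))  # between < within
    gamma <- (s_plus - s_minus) / max(s_plus + s_minus, 1)

    # predictive-residual cross-validation criterion (minimize)
    sigma2 <- sum(weights^2 * (1 - r_own^2)) / (n * (C - 1))
    cv <- sigma2 * ((C - 1) / (C - 1 - k))^2

    c(davies_bouldin = db, silhouette = sil, dunn = dunn,
      point_biserial = pb, gamma = gamma, cv = cv)
  }

  tab <- t(vapply(k_range, score_one, numeric(6)))
  tab <- tibble::as_tibble(tab)
  tab$k <- k_range

  # Krzanowski-Lai from the W_k sequence (maximize)
  p_eff <- C - 1
  diff_k <- function(k) {
    (k - 1)^(2 / p_eff) * Wk[[as.character(k - 1)]] -
      k^(2 / p_eff) * Wk[[as.character(k)]]
  }
  tab$krzanowski_lai <- vapply(k_range, function(k) {
    if (!as.character(k - 1) %in% names(Wk) ||
        !as.character(k + 1) %in% names(Wk)) return(NA_real_)
    abs(diff_k(k)) / max(abs(diff_k(k + 1)), 1e-12)
  }, numeric(1))

  tab <- dplyr::select(tab, "k", dplyr::everything())
  directions <- c(davies_bouldin = -1, silhouette = 1, dunn = 1,
                  point_biserial = 1, gamma = 1, cv = -1,
                  krzanowski_lai = 1)
  votes <- vapply(names(directions), function(nm) {
    v <- tab[[nm]] * directions[[nm]]
    tab$k[which.max(replace(v, is.na(v), -Inf))]
  }, numeric(1))
  counts <- table(votes)
  k_opt <- as.integer(names(counts)[order(-counts, as.integer(names(counts)))][1])
  attr(tab, "votes") <- votes
  attr(tab, "k_opt") <- k_opt
  tab
}
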