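# Independent oracles used by the equivalence tests. These never call
# the implementation paths they check.

# naive per-sample backfit: explicit loop over samples and templates,
# computing GMD directly and taking the argmin
naive_backfit <- function(rec, template_maps) {
  k <- nrow(template_maps)
  out <- integer(ncol(rec$data))
  for (t in seq_len(ncol(rec$data))) {
    map <- rec$data[, t]
    if (sqrt(mean((map - mean(map))^2)) == 0) {
      out[t] <- NA_integer_
      next
    }
    dis <- numeric(k)
    for (j in seq_len(k)) dis[j] <- gmd(map, template_maps[j, ])
    out[t] <- which.min(dis)
  }
  out
}

# exhaustive-partition GEV optimum: all partitions of n maps into
# exactly 3 non-empty blocks, optimal rank-1 centroid per block
# (top eigenvalue of the block scatter). Unit-weight maps.
exhaustive_gev_k3 <- function(maps) {
  x <- normalize_maps(maps)
  n <- nrow(x)
  stopifnot(n <= 14)
  # top eigenvalue of the scatter of every non-empty subset (bitmask)
  lam <- numeric(2^n - 1)
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    s <- crossprod(x[idx, , drop = FALSE])
    lam[m] <- max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  }
  # item 1 fixed in block 1; items 2..n assigned to blocks 1..3
  digits <- as.matrix(expand.grid(rep(list(0:2), n - 1)))
  bits <- 2^(1:(n - 1))
  m1 <- (digits == 0) %*% bits + 1
  m2 <- (digits == 1) %*% bits
  m3 <- (digits == 2) %*% bits
  ok <- m2 > 0 & m3 > 0
  best <- max(lam[m1[ok]] + lam[m2[ok]] + lam[m3[ok]])
  best / n                                  # unit weights: sum w^2 = n
}

# first-principles pooled t from explicit sums (independent arithmetic)
brute_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
}
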