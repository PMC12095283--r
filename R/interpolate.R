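# Spherical-spline scalp interpolation (Perrin et al. 1989): bad
# channels are reconstructed from the remaining sensors with an
# order-4 spline on the unit sphere.

# g(x) = 1/(4*pi) * sum_n (2n+1) / (n (n+1))^m * P_n(x)
spline_g <- function(x, m = 4, nterms = 20) {
  x <- pmin(pmax(x, -1), 1)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:nterms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur
    p_cur <- p_new
  }
  out / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' @param rec An [eeg_recording()] carrying sensor positions.
#' @param bad Character vector of channel labels to reconstruct; must
#'   number fewer than 6 (a subject needing 6 or more replacements is
#'   excluded rather than repaired).
#' @param lambda Ridge regularization added to the spline system.
#' @return The recording with `bad` channels replaced.
#' @export
interpolate_channels <- function(rec, bad, lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  if (length(bad) >= 6) {
    stop("6 or more bad channels: subject flagged for exclusion",
         call. = FALSE)
  }
  if (is.null(rec$positions)) stop("sensor positions required", call. = FALSE)
  if (!all(bad %in% rec$labels)) {
    stop("unknown channel(s): ", paste(setdiff(bad, rec$labels), collapse = ","),
         call. = FALSE)
  }
  pos <- rec$positions[match(rec$labels, rec$positions$label), ]
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  good <- setdiff(rec$labels, bad)
  gi <- match(good, rec$labels)
  bi <- match(bad, rec$labels)

  cosang <- tcrossprod(xyz)                   # cos of inter-sensor angles
  G <- spline_g(cosang[gi, gi, drop = FALSE])
  Gb <- spline_g(cosang[bi, gi, drop = FALSE])
  ng <- length(gi)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[gi, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  cvec <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  out <- rec
  out$data[bi, ] <- Gb %*% cvec + matrix(c0, length(bi), ncol(rec$data),
                                         byrow = TRUE)
  out
}
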