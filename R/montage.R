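#' Schematic 64-channel 10-10 montage
#'
#' Builds sensor positions for the 64 electrodes of an extended 10-20
#' (10-10) cap. The layout is schematic: the outer 10% ring is placed on
#' the unit circle at 18-degree steps, inner electrodes are interpolated
#' between the midline and the ring along their row, and the inferior
#' 9/10 electrodes (FT9, TP9, PO9, ...) sit just below the equator.
#' Disc coordinates are lifted onto the unit sphere (inclination
#' proportional to disc radius), which is the geometry used for dipolar
#' archetype maps, spherical-spline interpolation and plotting.
#'
#' @param name Montage name; `"standard-64"` and `"standard-10-20"` are
#'   accepted aliases for the built-in 64-channel cap.
#' @return A tibble with columns `label`, `x`, `y`, `z` (unit sphere;
#'   +x right, +y anterior, +z superior) and `x2d`, `y2d` (orthographic
#'   disc projection).
#' @export
montage_positions <- function(name = "standard-64") {
  if (!name %in% c("standard-64", "standard-10-20", "standard_1020")) {
    stop("unknown montage: ", name, call. = FALSE)
  }
  rows <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
            TP = -1, CP = -1, P = -2, PO = -3, O = -4)
  labels <- c(
    "Fp1", "Fp2",
    "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2"
  )
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)(z|[0-9]+)$", lab))[[1]]
    row_name <- m[2]
    col_tok <- m[3]
    t_row <- rows[[row_name]]
    if (col_tok == "z") {
      s <- 0L
    } else {
      n <- as.integer(col_tok)
      side <- if (n %% 2 == 1) -1 else 1   # odd left, even right
      s <- side * ceiling(n / 2)
    }
    c(t = t_row, s = s)
  }
  grid <- t(vapply(labels, parse_one, c(t = 0, s = 0)))

  # outer-ring azimuth for a row: Fp row endpoints at +/-18deg, ..., O at 162
  ring_psi <- function(t_row) (90 - t_row * 18)  # degrees from +y, for right side
  pos <- lapply(seq_along(labels), function(i) {
    t_row <- grid[i, "t"]; s <- grid[i, "s"]
    side <- sign(s)
    if (abs(s) == 5) {           # inferior 9/10 ring, below the equator
      psi <- side * ring_psi(t_row)  # FT9 under FT7, TP9 under TP7, PO9 under PO7
      r <- 1.15
    } else if (abs(s) == 4 || abs(t_row) == 4 ||
               (abs(t_row) == 3 && abs(s) == 3)) {  # outer ring (incl AF7/8, PO7/8)
      psi <- side * ring_psi(t_row)
      if (t_row == 4) psi <- side * 18              # Fp1/Fp2
      if (t_row == -4) psi <- if (s == 0) 180 else side * 162  # O1/Oz/O2
      r <- 1
    } else {                      # interior: interpolate midline -> ring endpoint
      frac <- abs(s) / 4
      m_r <- abs(t_row) / 4 * 0.82   # midline electrode radius fraction
      M <- c(0, sign(t_row) * m_r)
      psi_e <- side * ring_psi(t_row)
      E <- c(sinpi(psi_e / 180), cospi(psi_e / 180))
      if (s == 0) {
        xy <- M
      } else {
        xy <- M + frac * (E - M)
        # gentle outward bow so row arcs look like arcs, not chords
        bow <- 0.12 * sinpi(frac)
        nrm <- sqrt(sum(xy^2))
        if (nrm > 0) xy <- xy * (1 + bow * (1 - nrm))
      }
      r <- sqrt(sum(xy^2))
      psi <- atan2(xy[1], xy[2]) * 180 / pi
    }
    incl <- min(r, 1.3) * 90
    x <- sinpi(incl / 180) * sinpi(psi / 180)
    y <- sinpi(incl / 180) * cospi(psi / 180)
    z <- cospi(incl / 180)
    c(x = x, y = y, z = z)
  })
  pos <- do.call(rbind, pos)
  tibble::tibble(
    label = labels,
    x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
    x2d = pos[, "x"], y2d = pos[, "y"]
  )
}
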