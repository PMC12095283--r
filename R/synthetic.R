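# Synthetic ground-truth EEG: a semi-Markov state sequence over K
# template topographies, each segment carrying a sinusoidal waveform at
# the alpha-band carrier with a random phase (so polarity flips across
# segments), plus spatially white sensor noise at a chosen SNR.

#' Ground-truth description for a synthetic recording
#'
#' @param templates An `ms_templates` object (see [make_templates()]) or
#'   a K x C matrix of zero-mean unit-norm maps.
#' @param dwell_ms_mean Per-state mean dwell time in ms.
#' @param jump_matrix K x K row-stochastic matrix with zero diagonal
#'   governing which state follows which (dwell-conditional jump chain).
#'   Default: uniform over the other states.
#' @param carrier_hz Oscillation frequency of the within-segment
#'   waveform (Hz); 10 Hz emulates eyes-closed alpha.
#' @param snr Ratio of state-signal RMS to noise RMS; `Inf` for
#'   noiseless.
#' @param seed Integer seed.
#' @return An object of class `ms_ground_truth`.
#' @export
make_ground_truth <- function(templates, dwell_ms_mean,
                              jump_matrix = NULL, carrier_hz = 10,
                              snr = 4, seed = 1L) {
  maps <- if (inherits(templates, "ms_templates")) templates$maps else templates
  k <- nrow(maps)
  if (length(dwell_ms_mean) == 1) dwell_ms_mean <- rep(dwell_ms_mean, k)
  stopifnot(length(dwell_ms_mean) == k, all(dwell_ms_mean > 0))
  if (is.null(jump_matrix)) {
    jump_matrix <- matrix(1 / max(k - 1, 1), k, k)
    diag(jump_matrix) <- 0
    if (k == 1) jump_matrix <- matrix(0, 1, 1)
  }
  check_jump_matrix(jump_matrix, k)
  structure(
    list(templates = templates, maps = maps, k = k,
         dwell_ms_mean = dwell_ms_mean, jump_matrix = jump_matrix,
         carrier_hz = carrier_hz, snr = snr, seed = as.integer(seed),
         label_seq = NULL, segments = NULL),
    class = "ms_ground_truth"
  )
}

check_jump_matrix <- function(m, k) {
  stopifnot(is.matrix(m), nrow(m) == k, ncol(m) == k)
  if (k == 1) return(invisible(TRUE))
  if (any(diag(m) != 0)) {
    stop("jump matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("jump matrix rows must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample a semi-Markov state sequence
#'
#' States follow the jump chain; dwell times are gamma-distributed
#' (shape 2 by default, so very short dwells are rare) with the stated
#' per-state means, rounded to whole samples.
#'
#' @param duration_s Length of the sequence in seconds.
#' @param srate Sampling rate (Hz).
#' @param dwell_ms_mean Per-state mean dwell (ms); each must be at least
#'   2 samples long.
#' @param jump_matrix Row-stochastic zero-diagonal K x K matrix.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param dwell_shape Gamma shape parameter of the dwell law.
#' @return Integer vector of 1-based state ids covering
#'   `round(duration_s * srate)` samples, with the per-segment table in
#'   attribute `"segments"` (tibble: state, start, end, n_samples).
#' @export
sample_state_sequence <- function(duration_s, srate, dwell_ms_mean,
                                  jump_matrix, seed = NULL,
                                  dwell_shape = 2) {
  k <- length(dwell_ms_mean)
  check_jump_matrix(jump_matrix, k)
  if (any(dwell_ms_mean * srate / 1000 < 2)) {
    stop("dwell means must be at least 2 samples", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * srate)
  est_seg <- ceiling(n / (min(dwell_ms_mean) * srate / 1000)) + 50

  states <- integer(est_seg)
  lens <- integer(est_seg)
  cur <- sample.int(k, 1)
  total <- 0L
  nseg <- 0L
  while (total < n) {
    dwell_ms <- rgamma(1, shape = dwell_shape,
                       scale = dwell_ms_mean[cur] / dwell_shape)
    len <- max(1L, as.integer(round(dwell_ms * srate / 1000)))
    nseg <- nseg + 1L
    if (nseg > length(states)) {          # rare: extend the preallocation
      states <- c(states, integer(est_seg))
      lens <- c(lens, integer(est_seg))
    }
    states[nseg] <- cur
    lens[nseg] <- len
    total <- total + len
    cur <- if (k == 1) cur else
      sample.int(k, 1, prob = jump_matrix[cur, ])
  }
  states <- states[seq_len(nseg)]
  lens <- lens[seq_len(nseg)]
  lens[length(lens)] <- lens[length(lens)] - (total - n)  # trim to duration
  keep <- lens > 0
  states <- states[keep]; lens <- lens[keep]
  seq_out <- rep.int(states, lens)
  ends <- cumsum(lens)
  segs <- tibble::tibble(state = states,
                         start = ends - lens + 1L, end = ends,
                         n_samples = lens)
  attr(seq_out, "segments") <- segs
  seq_out
}

#' Synthesize a multichannel recording from ground truth
#'
#' At sample t the scalp map is `templates[state_t] * sin(2*pi*f*t +
#' phase)` with an independent uniform phase per segment (so segment
#' polarity is random), scaled so GFP peaks at about 5 microvolts, plus
#' spatially white Gaussian noise scaled to the requested SNR.
#'
#' @param truth An `ms_ground_truth`.
#' @param srate Sampling rate (Hz).
#' @param duration_s Duration in seconds (>= 1).
#' @param line_hz Optional line-noise frequency to inject (for notch
#'   tests); `NULL` for none.
#' @param line_uv Line-noise amplitude (microvolts) when `line_hz` set.
#' @return A list with `recording` (an [eeg_recording()]) and `truth`
#'   (the input with `label_seq` and `segments` filled in).
#' @export
synthesize_recording <- function(truth, srate = 1000, duration_s = 60,
                                 line_hz = NULL, line_uv = 5) {
  stopifnot(inherits(truth, "ms_ground_truth"), duration_s >= 1)
  set.seed(truth$seed)
  maps <- truth$maps
  C <- ncol(maps)
  label_seq <- sample_state_sequence(
    duration_s, srate, truth$dwell_ms_mean, truth$jump_matrix,
    seed = NULL, dwell_shape = 2
  )
  segs <- attr(label_seq, "segments")
  n <- length(label_seq)
  tt <- seq_len(n) - 1L

  amp <- 5 * sqrt(C)                       # peak GFP ~5 uV for unit-norm maps
  phase <- runif(nrow(segs), 0, 2 * pi)
  carrier <- sin(2 * pi * truth$carrier_hz * tt / srate +
                   rep.int(phase, segs$n_samples))
  signal <- t(maps[label_seq, , drop = FALSE]) * rep(amp * carrier, each = C)

  if (is.finite(truth$snr)) {
    sigma <- amp * sqrt(0.5 / C) / truth$snr
    signal <- signal + matrix(rnorm(C * n, sd = sigma), C, n)
  }
  if (!is.null(line_hz)) {
    signal <- signal + matrix(rep(line_uv * sin(2 * pi * line_hz * tt / srate),
                                  each = C), C, n)
  }

  pos <- if (inherits(truth$templates, "ms_templates")) {
    truth$templates$positions
  } else NULL
  rec <- eeg_recording(signal, srate, labels = colnames(maps),
                       positions = pos, reference = "original")
  truth$label_seq <- label_seq
  truth$segments <- segs
  list(recording = rec, truth = truth)
}

#' Simulate a two-group microstate study
#'
#' Generates a high/low group design with per-subject ground-truth dwell
#' means: group `high` gets the dwell offsets in `effect_spec` (default
#' +20 ms for state C and -25 ms for state D), on top of between-subject
#' variation. Anxiety-scale-like scores (total plus fear and avoidance
#' subscales on a 0-144 / 0-72 range) are generated with a configurable
#' within-group correlation to the subject's true C dwell.
#'
#' @param n_per_group Integer vector `c(high, low)`, each >= 2.
#' @param effect_spec Named numeric vector of dwell offsets (ms) applied
#'   to the high group; names must be template labels.
#' @param seed Integer seed.
#' @param baseline_dwell Named per-state baseline dwell means (ms).
#' @param between_sd Per-state between-subject SD of true dwell (ms).
#' @param score_cor Within-group correlation between true C dwell and
#'   the total score.
#' @param templates Template set shared by all subjects.
#' @param srate,duration_s,snr,carrier_hz Per-subject recording
#'   parameters (used when recordings are synthesized).
#' @param simulate_eeg If `TRUE`, attach a synthesized recording per
#'   subject; if `FALSE` only the design, truth table and per-subject
#'   seeds are returned (recordings can be built later with
#'   [subject_recording()]).
#' @return A list of class `ms_group_study`: `design` (tibble:
#'   subject_id, group, lsas_total, lsas_fear, lsas_avoidance), `truth`
#'   (tibble: subject_id, group, state, dwell_ms_true), `subjects`
#'   (per-subject parameter list incl. seeds), `templates`, and
#'   `recordings` when requested.
#' @export
make_group_study <- function(n_per_group = c(23, 18),
                             effect_spec = c(C = 20, D = -25),
                             seed = 1L,
                             baseline_dwell = c(A = 70, B = 70, C = 62, D = 110),
                             between_sd = c(A = 10, B = 10, C = 10, D = 18),
                             score_cor = 0.5,
                             templates = make_templates(64, 4),
                             srate = 250, duration_s = 16, snr = 4,
                             carrier_hz = 10,
                             simulate_eeg = FALSE) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2))
  labs <- rownames(templates$maps)
  if (!all(names(effect_spec) %in% labs)) {
    stop("effect_spec names unknown state(s): ",
         paste(setdiff(names(effect_spec), labs), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(labs %in% names(baseline_dwell)),
            all(labs %in% names(between_sd)))
  set.seed(seed)
  n_tot <- sum(n_per_group)
  group <- rep(c("high", "low"), n_per_group)
  subject_id <- sprintf("S%02d", seq_len(n_tot))
  subject_seed <- sample.int(2^30, n_tot)

  k <- length(labs)
  dwell <- matrix(rep(baseline_dwell[labs], each = n_tot), n_tot, k,
                  dimnames = list(subject_id, labs))
  for (s in names(effect_spec)) {
    dwell[group == "high", s] <- dwell[group == "high", s] + effect_spec[[s]]
  }
  dwell <- dwell + matrix(rnorm(n_tot * k), n_tot, k) %*%
    diag(between_sd[labs], k)
  min_dwell <- max(20, 2 * 1000 / srate + 1)
  dwell[dwell < min_dwell] <- min_dwell

  # scores: group anchors from a high/low anxiety contrast, correlated
  # with the subject's true C-dwell deviation within group
  anchor <- c(high = 82.17, low = 27.83)
  score_sd <- 12.5
  total <- numeric(n_tot)
  for (g in c("high", "low")) {
    i <- group == g
    z <- as.numeric(scale(dwell[i, "C"]))
    total[i] <- anchor[[g]] + score_sd *
      (score_cor * z + sqrt(1 - score_cor^2) * rnorm(sum(i)))
  }
  total <- pmin(pmax(total, 0), 144)
  fear <- pmin(pmax(0.51 * total + rnorm(n_tot, sd = 3), 0), 72)
  avoid <- pmin(pmax(0.49 * total + rnorm(n_tot, sd = 3), 0), 72)

  design <- tibble::tibble(
    subject_id = subject_id, group = group,
    lsas_total = round(total, 1), lsas_fear = round(fear, 1),
    lsas_avoidance = round(avoid, 1)
  )
  truth <- tibble::tibble(
    subject_id = rep(subject_id, each = k),
    group = rep(group, each = k),
    state = rep(labs, times = n_tot),
    dwell_ms_true = as.vector(t(dwell))
  )
  subjects <- purrr::map(seq_len(n_tot), function(i) {
    list(subject_id = subject_id[i], group = group[i],
         dwell_ms_mean = dwell[i, ], seed = subject_seed[i],
         srate = srate, duration_s = duration_s, snr = snr,
         carrier_hz = carrier_hz)
  })
  out <- list(design = design, truth = truth, subjects = subjects,
              templates = templates, seed = seed,
              params = list(srate = srate, duration_s = duration_s,
                            snr = snr, carrier_hz = carrier_hz))
  class(out) <- "ms_group_study"
  if (simulate_eeg) {
    out$recordings <- purrr::map(out$subjects,
                                 ~ subject_recording(.x, templates))
  }
  out
}

#' Synthesize one subject's recording from its study entry
#'
#' @param subject One element of the `subjects` list of an
#'   `ms_group_study`.
#' @param templates The study's template set.
#' @return As [synthesize_recording()].
#' @export
subject_recording <- function(subject, templates) {
  truth <- make_ground_truth(
    templates, dwell_ms_mean = subject$dwell_ms_mean,
    carrier_hz = subject$carrier_hz, snr = subject$snr,
    seed = subject$seed
  )
  synthesize_recording(truth, srate = subject$srate,
                       duration_s = subject$duration_s)
}

#' @export
print.ms_group_study <- function(x, ...) {
  n <- table(x$design$group)
  cat("<ms_group_study> high n=", n[["high"]], ", low n=", n[["low"]],
      "; ", x$params$duration_s, " s @ ", x$params$srate,
      " Hz, snr=", x$params$snr, "\n", sep = "")
  invisible(x)
}
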