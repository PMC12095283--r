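test_that("montage provides 64 unit-sphere positions with unique labels", {
  m <- montage_positions()
  expect_equal(nrow(m), 64)
  expect_false(anyDuplicated(m$label) > 0)
  expect_true(all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-9))
  expect_error(montage_positions("no-such-cap"), "unknown montage")
})

test_that("archetype maps are normalized, separated and oriented", {
  ts <- make_templates(64, 4, seed = 1)
  expect_equal(rownames(ts$maps), c("A", "B", "C", "D"))
  expect_true(all(abs(rowMeans(ts$maps)) < 1e-12))
  expect_true(all(abs(rowSums(ts$maps^2) - 1) < 1e-12))
  cc <- abs(spatial_correlation(ts$maps, ts$maps))
  diag(cc) <- 0
  expect_lte(max(cc), 0.7)
  # orientation: A is a left-anterior/right-posterior diagonal dipole,
  # D an anterior-posterior gradient
  pos <- ts$positions
  diagonal <- normalize_maps(-pos$x2d + 0.5 * pos$y2d)
  expect_gt(abs(spatial_correlation(ts$maps["A", ], diagonal)), 0.95)
  expect_gt(abs(spatial_correlation(ts$maps["D", ], pos$y2d)), 0.95)
  # C peaks anterior-central: extremum channel lies forward of midline
  peak_ch <- which.max(abs(ts$maps["C", ]))
  expect_gt(pos$y2d[peak_ch], 0.2)
})

test_that("make_templates handles degenerate and invalid k", {
  one <- make_templates(64, 1)
  expect_equal(nrow(one$maps), 1)
  expect_true(abs(sum(one$maps^2) - 1) < 1e-12)
  expect_identical(make_templates(64, 4, seed = 1)$maps,
                   make_templates(64, 4, seed = 2)$maps)  # deterministic
  expect_error(make_templates(64, 5), "orientations")
  expect_error(make_templates(4, 4), "at least 8")
  # any 5th dipole lies in the span of the built-in orientations, so the
  # separation check is expected to flag it
  expect_warning(ext <- make_templates(64, 5, orientations = list(c(1, -1))),
                 "spatial correlation")
  expect_equal(nrow(ext$maps), 5)
})

test_that("semi-Markov dwell times match the requested means", {
  k <- 4
  jm <- matrix(1 / 3, k, k); diag(jm) <- 0
  s <- sample_state_sequence(300, 250, rep(80, k), jm, seed = 5)
  segs <- attr(s, "segments")
  expect_gt(nrow(segs), 3000)
  emp <- mean(segs$n_samples) * 1000 / 250
  expect_lt(abs(emp / 80 - 1), 0.05)
  expect_equal(length(s), 300 * 250)
  expect_true(all(s %in% 1:4))
})

test_that("deterministic alternation matrix forces strict alternation", {
  jm <- matrix(c(0, 1, 1, 0), 2, 2)
  s <- sample_state_sequence(10, 100, c(50, 50), jm, seed = 2)
  segs <- attr(s, "segments")
  expect_true(all(diff(segs$state) != 0))
  expect_true(all(sort(unique(segs$state)) == 1:2))
})

test_that("empirical jump frequencies converge to the jump matrix", {
  k <- 4
  jm <- matrix(c(0, .5, .3, .2,
                 .2, 0, .5, .3,
                 .3, .2, 0, .5,
                 .5, .3, .2, 0), k, k, byrow = TRUE)
  s <- sample_state_sequence(1200, 250, rep(40, k), jm, seed = 9)
  segs <- attr(s, "segments")
  emp <- matrix(0, k, k)
  st <- segs$state
  for (i in seq_len(length(st) - 1)) emp[st[i], st[i + 1]] <- emp[st[i], st[i + 1]] + 1
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - jm)), 0.02)
})

test_that("sequence sampling validates its inputs", {
  jm_bad <- matrix(0.5, 2, 2)
  expect_error(sample_state_sequence(10, 100, c(50, 50), jm_bad), "diagonal")
  jm <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(sample_state_sequence(10, 100, c(5, 50), jm), "2 samples")
  jm_neg <- matrix(c(0, 1, 2, 0) - c(0, 0, 1, 0), 2, 2)
  expect_error(sample_state_sequence(10, 100, c(50, 50),
                                     matrix(c(0, 2, -1, 0), 2, 2)), "sum to 1")
})

test_that("synthesized recordings are seeded-deterministic with truth sidecar", {
  sim1 <- quick_sim(seed = 3, duration_s = 4)
  sim2 <- quick_sim(seed = 3, duration_s = 4)
  expect_identical(sim1$recording$data, sim2$recording$data)
  expect_identical(sim1$truth$label_seq, sim2$truth$label_seq)
  expect_equal(nrow(sim1$truth$segments) > 0, TRUE)
})

test_that("noiseless recordings are exactly identifiable at GFP peaks", {
  sim <- quick_sim(seed = 4, snr = Inf, duration_s = 10)
  rec <- average_reference(epoch_recording(sim$recording))
  lab <- backfit(rec, sim$templates)
  g <- compute_gfp(rec)
  pk <- find_gfp_peaks(g)
  expect_gt(nrow(pk), 50)
  expect_true(all(lab$states[pk$sample] == sim$truth$label_seq[pk$sample]))
  # everywhere the signal is nonzero, labels equal ground truth
  ok <- !is.na(lab$states)
  expect_true(all(lab$states[ok] == sim$truth$label_seq[ok]))
})

test_that("at snr 4 at least 95 percent of GFP-peak labels match truth", {
  sim <- quick_sim(seed = 6, snr = 4, duration_s = 60)
  rec <- quick_clean(sim)
  lab <- backfit(rec, sim$templates)
  g <- compute_gfp(rec)
  pk <- find_gfp_peaks(g)
  agree <- mean(lab$states[pk$sample] == sim$truth$label_seq[pk$sample],
                na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("a 10 Hz carrier spaces GFP peaks at about half a period", {
  # long dwells so segment-boundary phase jumps are rare and the GFP
  # envelope is dominated by the rectified carrier
  sim <- quick_sim(seed = 8, snr = Inf, duration_s = 20, dwell = rep(400, 4))
  rec <- average_reference(epoch_recording(sim$recording))
  pk <- find_gfp_peaks(compute_gfp(rec))
  spacing <- unlist(tapply(pk$sample, pk$epoch, diff)) * 1000 / 250
  expect_lt(abs(mean(spacing) - 50), 5)
})

test_that("group study designs carry effects, scores and truth tables", {
  st <- make_group_study(n_per_group = c(6, 5), seed = 2)
  expect_equal(nrow(st$design), 11)
  expect_true(all(st$design$lsas_total >= 0 & st$design$lsas_total <= 144))
  hi <- st$truth[st$truth$group == "high" & st$truth$state == "C", ]
  lo <- st$truth[st$truth$group == "low" & st$truth$state == "C", ]
  expect_gt(mean(hi$dwell_ms_true), mean(lo$dwell_ms_true))
  expect_error(make_group_study(effect_spec = c(Z = 10)), "unknown state")
})

test_that("the smallest legal design runs end to end and is flagged low-n", {
  st <- make_group_study(n_per_group = c(2, 2), seed = 3, srate = 125,
                         duration_s = 8)
  cfg <- default_config(band = c(0.5, 55), max_peak_maps = 60)
  expect_warning(ana <- run_group_analysis(st, config = cfg), "low-n")
  expect_true(glance(ana$stats)$low_n)
  expect_equal(length(ana$failed), 0)
})
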