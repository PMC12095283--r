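test_that("GFP is the spatial RMS of average-referenced maps", {
  rec <- average_reference(eeg_recording(matrix(c(1, -1, 0, 0, 3, -3), 2),
                                         10))
  g <- compute_gfp(rec)
  expect_equal(g$gfp, c(1, 0, 3))
  raw <- eeg_recording(matrix(rnorm(20), 4), 10)
  expect_error(compute_gfp(raw), "average-referenced")
  # homogeneity: scaling maps by c scales GFP by |c|
  sc <- rec; sc$data <- sc$data * -2.5
  expect_equal(compute_gfp(sc)$gfp, 2.5 * g$gfp)
})

test_that("GFP peaks are strict interior maxima with separation", {
  srate <- 100
  g <- tibble::tibble(
    sample = 1:30, epoch = 1L,
    gfp = c(0, 1, 0, rep(0, 5), 2, 0.5, 0, 0, 2, 0, rep(0.1, 16))
  )
  attr(g, "srate") <- srate
  pk <- find_gfp_peaks(g, min_separation_ms = 50)  # 5 samples
  expect_true(2 %in% pk$sample)                     # strict maximum kept
  # equal-height maxima at 9 and 12 within 5 samples: earlier kept
  expect_true(9 %in% pk$sample)
  expect_false(12 %in% pk$sample)
  ramp <- tibble::tibble(sample = 1:20, epoch = 1L, gfp = seq(0, 1, length.out = 20))
  attr(ramp, "srate") <- srate
  expect_equal(nrow(find_gfp_peaks(ramp)), 0)       # monotone: no peaks
})

test_that("GMD is polarity invariant with the closed-form range", {
  u <- rnorm(32)
  expect_lt(gmd(u, u), 1e-6)
  expect_lt(gmd(u, -u), 1e-6)
  # orthogonal pair after centering: sqrt(2)
  a <- rep(c(1, -1), 16)
  b <- rep(c(1, 1, -1, -1), 8)
  expect_equal(gmd(a, b), sqrt(2))
  expect_error(gmd(u, rep(1, 32)), "zero-GFP")
  # GMD^2 = 2 (1 - |r|) for random maps
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(16); v <- rnorm(16)
    r <- abs(spatial_correlation(u, v))
    expect_equal(gmd(u, v)^2, 2 * (1 - as.numeric(r)), tolerance = 1e-10)
  }
})

test_that("taahc recovers orthogonal templates from sign-flipped copies", {
  set.seed(2)
  base <- normalize_maps(matrix(rnorm(4 * 32), 4))
  # orthogonalize
  q <- qr.Q(qr(t(base)))[, 1:4]
  tmpl <- normalize_maps(t(q))
  maps <- tmpl[rep(1:4, each = 25), ] * sample(c(-1, 1), 100, TRUE)
  fit <- taahc(maps, 4)
  cc <- abs(spatial_correlation(fit$maps, tmpl))
  expect_equal(unname(sort(apply(cc, 1, max))), rep(1, 4), tolerance = 1e-8)
  expect_equal(fit$gev_total, 1, tolerance = 1e-8)
  # nested property: fewer clusters never explain more variance
  expect_lte(taahc(maps, 2)$gev_total, fit$gev_total + 1e-12)
  expect_error(taahc(maps[1:3, ], 4), "nrow")
})

test_that("taahc flags degenerate all-identical input", {
  one <- normalize_maps(matrix(rnorm(16), 1))
  maps <- one[rep(1, 10), ]
  expect_warning(taahc(maps, 2), "duplicate")
})

test_that("taahc GEV is near the exhaustive-partition optimum", {
  set.seed(3)
  centers <- normalize_maps(matrix(rnorm(3 * 8), 3))
  maps <- centers[rep(1:3, each = 4), ] + 0.4 * matrix(rnorm(12 * 8), 12)
  maps <- normalize_maps(maps) * sample(c(-1, 1), 12, TRUE)
  fit <- taahc(maps, 3)
  best <- exhaustive_gev_k3(maps)
  expect_gte(fit$gev_total, 0.95 * best)
  expect_lte(fit$gev_total, best + 1e-8)
})

test_that("validity criteria select k = 4 for four separated families", {
  set.seed(4)
  ts <- make_templates(32, 4)
  maps <- ts$maps[rep(1:4, each = 30), ] + 0.15 * matrix(rnorm(120 * 32), 120)
  maps <- maps * sample(c(-1, 1), 120, TRUE)
  tab <- k_selection_criteria(maps, k_range = 2:6)
  expect_equal(attr(tab, "k_opt"), 4)
  # sign-flip invariance of every criterion
  flipped <- maps * rep(sample(c(-1, 1), 120, TRUE), times = ncol(maps))
  tab2 <- k_selection_criteria(flipped, k_range = 2:6)
  expect_equal(as.data.frame(tab), as.data.frame(tab2), tolerance = 1e-8)
  expect_error(k_selection_criteria(maps, integer(0)), "empty")
})

test_that("canonical labeling recovers letters under permutation and flips", {
  arch <- make_templates(64, 4)
  perm <- c(3, 1, 4, 2)
  shuffled <- arch$maps[perm, ] * c(-1, 1, -1, 1)
  rownames(shuffled) <- paste0("M", 1:4)
  ts <- msdyn:::new_ms_templates(shuffled, positions = arch$positions)
  out <- canonical_labels(ts)
  expect_equal(out$labels, c("A", "B", "C", "D"))
  cc <- abs(spatial_correlation(out$maps, arch$maps))
  expect_equal(unname(diag(cc)), rep(1, 4), tolerance = 1e-8)
  # K != 4 falls back to generic labels with a warning
  ts3 <- msdyn:::new_ms_templates(arch$maps[1:3, ], positions = arch$positions)
  expect_warning(out3 <- canonical_labels(ts3), "K = 4")
  expect_equal(out3$labels, c("M1", "M2", "M3"))
})

test_that("backfit equals the naive per-sample GMD argmin", {
  sim <- quick_sim(seed = 5, duration_s = 4, srate = 250)
  rec <- quick_clean(sim)
  one_s <- rec
  one_s$data <- one_s$data[, 1:250]
  one_s$epochs <- tibble::tibble(start = 1L, end = 250L)
  fast <- backfit(one_s, sim$templates)
  slow <- naive_backfit(one_s, sim$templates$maps)
  expect_equal(fast$states, slow)
})

test_that("labels are invariant to global gain and polarity", {
  sim <- quick_sim(seed = 6, duration_s = 6, srate = 250)
  rec <- quick_clean(sim)
  lab1 <- backfit(rec, sim$templates)
  scaled <- rec; scaled$data <- scaled$data * -2.5
  lab2 <- backfit(scaled, sim$templates)
  expect_identical(lab1$states, lab2$states)
  sm1 <- smooth_labels(lab1, rec, sim$templates)
  sm2 <- smooth_labels(lab2, scaled, sim$templates)
  expect_identical(sm1$states, sm2$states)
  p1 <- microstate_parameters(
    drop_short_segments(sm1, rec, sim$templates), rec, sim$templates)
  p2 <- microstate_parameters(
    drop_short_segments(sm2, scaled, sim$templates), scaled, sim$templates)
  expect_equal(p1$params, p2$params)
  expect_equal(p1$gev, p2$gev)
  expect_equal(p1$transitions, p2$transitions)
})

test_that("smoothing reduces switching and respects its fixed points", {
  sim <- quick_sim(seed = 7, duration_s = 10, srate = 250, snr = 2)
  rec <- quick_clean(sim)
  lab <- backfit(rec, sim$templates)
  sm <- smooth_labels(lab, rec, sim$templates, besag = 10)
  expect_lt(msdyn:::count_switches(sm), msdyn:::count_switches(lab))
  # besag = 0 is the identity
  expect_identical(smooth_labels(lab, rec, sim$templates, besag = 0)$states,
                   lab$states)
  # an already-smooth sequence is a fixed point
  sm2 <- smooth_labels(sm, rec, sim$templates, besag = 10)
  expect_identical(sm2$states, sm$states)
})

test_that("short-segment removal absorbs sub-threshold interior runs", {
  sim <- quick_sim(seed = 8, duration_s = 4, srate = 250, snr = Inf)
  rec <- quick_clean(sim, ms_band = FALSE)
  # construct A(50 ms) B(10 ms) A(60 ms) inside epoch 1, at 250 Hz
  n <- ncol(rec$data)
  states <- rep(4L, n)
  ep1 <- which(msdyn:::epoch_of_sample(rec) == 1)
  seg <- c(rep(1L, 13), rep(2L, 2), rep(1L, 15))
  states[ep1[100 + seq_along(seg)]] <- seg
  lab <- msdyn:::new_ms_labels(states, msdyn:::epoch_of_sample(rec),
                               250, 4, gfp = rep(1, n))
  out <- drop_short_segments(lab, rec, make_templates(64, 4), min_ms = 30)
  run <- rle(out$states[ep1[100 + seq_along(seg)]])
  expect_equal(run$values, 1L)              # B absorbed into surrounding A
  expect_equal(sum(run$lengths), 30)
  # nothing below threshold: unchanged
  seg_ok <- c(rep(1L, 13), rep(2L, 10), rep(3L, 13))
  states2 <- rep(4L, n)
  states2[ep1[100 + seq_along(seg_ok)]] <- seg_ok
  lab2 <- msdyn:::new_ms_labels(states2, msdyn:::epoch_of_sample(rec),
                                250, 4, gfp = rep(1, n))
  out2 <- drop_short_segments(lab2, rec, make_templates(64, 4), min_ms = 30)
  expect_identical(out2$states, states2)
})

test_that("cleanup leaves no interior segment under the minimum", {
  sim <- quick_sim(seed = 9, duration_s = 10, srate = 250, snr = 2)
  rec <- quick_clean(sim)
  lab <- backfit(rec, sim$templates)
  out <- drop_short_segments(lab, rec, sim$templates, min_ms = 30)
  st <- segment_table(out)
  inner <- st[!st$edge & !is.na(st$state), ]
  expect_true(all(inner$duration_ms >= 30))
})

test_that("parameters reproduce the single-adjacency transition example", {
  sim <- quick_sim(seed = 10, duration_s = 4, srate = 1000)
  rec <- quick_clean(sim, ms_band = FALSE)
  n <- ncol(rec$data)
  ep <- msdyn:::epoch_of_sample(rec)
  states <- rep(NA_integer_, n)
  ep1 <- which(ep == 1)
  states[ep1[1:4]] <- c(1L, 1L, 2L, 2L)
  lab <- msdyn:::new_ms_labels(states, ep, 1000, 4, gfp = rep(1, n))
  par <- microstate_parameters(lab, rec, sim$templates)
  tr <- par$transitions
  expect_equal(tr$probability[tr$from == "A" & tr$to == "B"], 1)
  expect_equal(sum(tr$probability), 1)
  expect_equal(sum(tr$probability > 0), 1)
})

test_that("coverage partitions assigned time and accounting closes", {
  sim <- quick_sim(seed = 11, duration_s = 20, srate = 250)
  rec <- quick_clean(sim)
  lab <- drop_short_segments(
    smooth_labels(backfit(rec, sim$templates), rec, sim$templates),
    rec, sim$templates)
  par <- microstate_parameters(lab, rec, sim$templates)
  expect_equal(sum(par$params$coverage_pct), 100, tolerance = 1e-9)
  expect_equal(sum(par$transitions$probability), 1, tolerance = 1e-9)
  expect_true(all(par$transitions$probability >= 0))
  expect_gte(par$gev, 0); expect_lte(par$gev, 1)
  # ms-per-second accounting: occurrence x duration vs coverage
  acc <- sum(par$params$occurrence_hz * par$params$duration_ms)
  expect_lt(abs(acc - 10 * sum(par$params$coverage_pct)) /
              (10 * sum(par$params$coverage_pct)), 0.2)
})

test_that("an absent state reports missing duration and zero coverage", {
  sim <- quick_sim(seed = 12, duration_s = 4, srate = 250)
  rec <- quick_clean(sim, ms_band = FALSE)
  n <- ncol(rec$data)
  ep <- msdyn:::epoch_of_sample(rec)
  states <- rep(c(1L, 2L), length.out = n)
  states <- rep(1L, n); states[seq(1, n, by = 50)] <- 2L
  lab <- msdyn:::new_ms_labels(states, ep, 250, 4, gfp = rep(1, n))
  par <- microstate_parameters(lab, rec, sim$templates)
  d <- par$params[par$params$state == "D", ]
  expect_true(is.na(d$duration_ms))
  expect_equal(d$occurrence_hz, 0)
  expect_equal(d$coverage_pct, 0)
})

test_that("GEV drops when templates are replaced by random maps", {
  sim <- quick_sim(seed = 13, duration_s = 8, srate = 250)
  rec <- quick_clean(sim)
  lab <- backfit(rec, sim$templates)
  par <- microstate_parameters(lab, rec, sim$templates)
  set.seed(14)
  rnd <- normalize_maps(matrix(rnorm(4 * 64), 4))
  colnames(rnd) <- colnames(sim$templates$maps)
  rownames(rnd) <- rownames(sim$templates$maps)
  par_rnd <- microstate_parameters(lab, rec, rnd)
  expect_lt(par_rnd$gev, par$gev)
})
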