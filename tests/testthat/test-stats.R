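test_that("moment-based t reproduces published group rows", {
  # scale-score rows (pooled)
  expect_equal(t_from_summary(82.170, 12.702, 23, 27.830, 12.282, 18)$t,
               13.79, tolerance = 0.01)
  # state-C duration row (pooled) and state-D duration row (Welch)
  expect_equal(t_from_summary(83.640, 13.560, 23, 62.230, 10.170, 18)$t,
               5.58, tolerance = 0.01)
  w <- t_from_summary(81.880, 12.190, 23, 109.670, 35.360, 18, "welch")
  expect_equal(w$t, -3.19, tolerance = 0.01)
  expect_lt(w$df, 39)                        # Satterthwaite df shrinks
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(t_from_summary(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("raw-sample t matches a first-principles computation", {
  set.seed(1)
  x <- rnorm(12, 1); y <- rnorm(8)
  mine <- two_sample_t(x, y, "pooled")
  expect_equal(mine$t, brute_pooled_t(x, y), tolerance = 1e-12)
  expect_equal(mine$df, 18)
  same <- two_sample_t(x, x, "pooled")
  expect_equal(same$t, 0)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("moment t on empirical moments equals the raw-sample t", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    raw <- two_sample_t(x, y, "pooled")
    mom <- t_from_summary(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y), "pooled")
    expect_equal(raw$t, mom$t, tolerance = 1e-10)
    expect_equal(raw$p, mom$p, tolerance = 1e-10)
    # p-values invariant to group order, t flips sign
    rev <- two_sample_t(y, x, "pooled")
    expect_equal(rev$p, raw$p, tolerance = 1e-12)
    expect_equal(rev$t, -raw$t, tolerance = 1e-12)
  }
})

test_that("the Levene gate switches variants on unequal variances", {
  set.seed(3)
  unequal <- replicate(40, two_sample_t(rnorm(40, sd = 1), rnorm(40, sd = 5),
                                        "auto")$variant)
  expect_gt(mean(unequal == "welch"), 0.9)
  equal <- replicate(40, two_sample_t(rnorm(40), rnorm(40), "auto")$variant)
  expect_gt(mean(equal == "pooled"), 0.8)   # gate level is 0.05
})

test_that("effect sizes follow the d and small-sample formulas", {
  expect_equal(effect_size(5.576, 23, 18, corrected = TRUE), 1.721,
               tolerance = 0.001)
  expect_equal(effect_size(0, 23, 18), 0)
  set.seed(4)
  for (i in 1:10) {
    t <- runif(1, 0.5, 6); n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    expect_lt(effect_size(t, n1, n2, TRUE), effect_size(t, n1, n2, FALSE))
  }
})

test_that("Bonferroni families use strict per-family thresholds", {
  tab <- tibble::tibble(p = c(0.012, 0.05 / 12, 0.001))
  fam4 <- bonferroni_family(tab, 4)
  expect_equal(fam4$threshold[1], 0.0125)
  expect_true(fam4$significant[1])
  fam12 <- bonferroni_family(tab, 12)
  expect_false(fam12$significant[1])
  expect_false(fam12$significant[2])          # exactly at threshold: not sig
  expect_true(fam12$significant[3])
})

test_that("correlations behave as Pearson with t-transform p-values", {
  d <- tibble::tibble(s = rnorm(20), f = NA)
  d$f <- d$s
  perfect <- ms_correlate(d, "s", "f")
  expect_equal(perfect$r, 1)
  # symmetry
  set.seed(5)
  d2 <- tibble::tibble(a = rnorm(15), b = rnorm(15))
  expect_equal(ms_correlate(d2, "a", "b")$r, ms_correlate(d2, "b", "a")$r)
  # generated r = -0.57 is recovered on average at n = 18
  set.seed(6)
  rs <- replicate(300, {
    x <- rnorm(18)
    y <- -0.57 * x + sqrt(1 - 0.57^2) * rnorm(18)
    ms_correlate(tibble::tibble(x = x, y = y), "x", "y")$r
  })
  expect_lt(abs(mean(rs) - (-0.57)), 0.05)
  expect_error(ms_correlate(tibble::tibble(x = 1:2, y = 1:2), "x", "y"),
               "n >= 3")
  expect_warning(
    ms_correlate(tibble::tibble(x = rep(1, 5), y = rnorm(5)), "x", "y"),
    "zero variance")
})

test_that("group comparison assembles families, effects and glance", {
  set.seed(7)
  subj <- sprintf("S%02d", 1:20)
  grp <- rep(c("high", "low"), each = 10)
  params <- tidyr::expand_grid(subject_id = subj, state = c("A", "B", "C", "D"))
  params$group <- rep(grp, each = 4)
  params$duration_ms <- rnorm(80, 70, 8) +
    ifelse(params$group == "high" & params$state == "C", 25, 0)
  params$occurrence_hz <- rnorm(80, 5, 1)
  params$coverage_pct <- 25 + rnorm(80, 0, 3)
  params$gev <- rep(runif(20, 0.6, 0.8), each = 4)
  trans <- tidyr::expand_grid(subject_id = subj,
                              from = c("A", "B"), to = c("C", "D"))
  trans$group <- rep(grp, each = 4)
  trans$probability <- runif(80, 0.05, 0.12)
  cmp <- compare_groups(params, trans)
  tab <- tidy(cmp)
  expect_true(all(c("duration_ms", "occurrence_hz", "coverage_pct",
                    "gev", "transition") %in% tab$measure))
  cdur <- tab[tab$measure == "duration_ms" & tab$state == "C", ]
  expect_gt(cdur$t, 3)
  expect_true(cdur$significant)
  expect_equal(unique(tab$family_size[tab$measure == "transition"]), 12)
  g <- glance(cmp)
  expect_equal(g$n_high, 10); expect_equal(g$n_low, 10)
  expect_false(g$low_n)
  expect_equal(tab$d_corrected / tab$d,
               rep(1 - 3 / (4 * 18 - 1), nrow(tab)), tolerance = 0.2)
})
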