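# Two-group inference layer: independent-sample t-tests (pooled or
# Welch, with a Levene gate for "auto"), Cohen's d with the small-sample
# correction, Bonferroni families, and within-group Pearson correlations
# between scale scores and microstate features.

#' Independent-samples t-test on raw values
#'
#' `variant = "auto"` (default) runs Levene's test on the absolute
#' deviations from the group means at the 0.05 level and switches to
#' Welch when variances are unequal.
#'
#' @param x,y Numeric samples (group 1, group 2), each n >= 2.
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p`, `variant`, group moments.
#' @export
two_sample_t <- function(x, y, variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    stop("zero variance in both groups: t undefined", call. = FALSE)
  }
  if (variant == "auto") {
    lev_p <- tryCatch(
      t.test(abs(x - mean(x)), abs(y - mean(y)), var.equal = TRUE)$p.value,
      error = function(e) 1)               # degenerate deviations: keep pooled
    variant <- if (is.finite(lev_p) && lev_p < 0.05) "welch" else "pooled"
  }
  tt <- t.test(x, y, var.equal = (variant == "pooled"))
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, variant = variant,
    m1 = mean(x), s1 = sd(x), n1 = length(x),
    m2 = mean(y), s2 = sd(y), n2 = length(y)
  )
}

#' Independent-samples t-test from summary moments
#'
#' Recomputes the t statistic from group means, SDs and sizes, as when
#' checking published tables. Pooled: \eqn{t = (m_1 - m_2) / (s_p
#' \sqrt{1/n_1 + 1/n_2})} with \eqn{s_p^2} the pooled variance and
#' \eqn{df = n_1 + n_2 - 2}; Welch uses per-group variances with
#' Satterthwaite df.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p`, `variant`.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) {
    stop("zero variance in both groups: t undefined", call. = FALSE)
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df), variant = variant)
}

#' Cohen's d from a t statistic
#'
#' \eqn{d = t \sqrt{1/n_1 + 1/n_2}}; the small-sample (Hedges)
#' correction multiplies by \eqn{1 - 3/(4(n_1 + n_2 - 2) - 1)}.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @param corrected Apply the small-sample correction.
#' @return Standardized mean difference.
#' @export
effect_size <- function(t, n1, n2, corrected = FALSE) {
  d <- t * sqrt(1 / n1 + 1 / n2)
  if (corrected) d <- d * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  d
}

#' Flag significance under a Bonferroni family
#'
#' Significance requires `p < alpha / family_size` (strict inequality).
#'
#' @param results Data frame with a `p` column.
#' @param family_size Number of comparisons in the family.
#' @param alpha Family-wise level.
#' @return `results` with `family_size`, `threshold` and `significant`
#'   columns added.
#' @export
bonferroni_family <- function(results, family_size, alpha = 0.05) {
  thr <- alpha / family_size
  dplyr::mutate(tibble::as_tibble(results),
                family_size = family_size, threshold = thr,
                significant = .data$p < thr)
}

#' Within-group Pearson correlations between scores and features
#'
#' @param data Data frame with one row per subject.
#' @param score,feature Column names (strings) of the scale score and
#'   the microstate feature.
#' @param group Optional grouping column name; correlations are
#'   computed separately per group (n >= 3 required within group).
#' @param fdr Apply Benjamini-Hochberg adjustment across the returned
#'   rows.
#' @return Tibble with `group` (if any), `r`, `p`, `n`.
#' @export
ms_correlate <- function(data, score, feature, group = NULL, fdr = FALSE) {
  run_one <- function(d, gname) {
    xs <- d[[score]]; ys <- d[[feature]]
    ok <- is.finite(xs) & is.finite(ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < 3) stop("need n >= 3 within group", call. = FALSE)
    if (sd(xs) == 0 || sd(ys) == 0) {
      warning("zero variance: correlation undefined")
      return(tibble::tibble(group = gname, r = NA_real_, p = NA_real_,
                            n = length(xs)))
    }
    ct <- cor.test(xs, ys)
    tibble::tibble(group = gname, r = unname(ct$estimate),
                   p = ct$p.value, n = length(xs))
  }
  out <- if (is.null(group)) {
    run_one(data, NA_character_)
  } else {
    dplyr::bind_rows(lapply(split(data, data[[group]]),
                            function(d) run_one(d, d[[group]][1])))
  }
  if (fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Two-group comparison of microstate parameters and transitions
#'
#' Runs the full inference of a high/low design: per-parameter t-tests
#' (duration, occurrence, coverage; Bonferroni family of 4 states
#' each), per-transition t-tests (family of 12), and a single test on
#' GEV. Group order is high minus low, so positive t means higher in
#' the high group.
#'
#' @param params Tibble with columns `subject_id`, `group`, `state`,
#'   `duration_ms`, `occurrence_hz`, `coverage_pct`, `gev`.
#' @param transitions Tibble with `subject_id`, `group`, `from`, `to`,
#'   `probability`.
#' @param variant t-test variant (see [two_sample_t()]).
#' @param alpha Family-wise level.
#' @return Object of class `ms_group_comparison`; [tidy()] returns the
#'   comparison table, [glance()] a one-row design summary.
#' @export
compare_groups <- function(params, transitions = NULL,
                           variant = "auto", alpha = 0.05) {
  stopifnot(all(c("group", "state") %in% names(params)))
  groups <- unique(params$group)
  stopifnot(length(groups) == 2)
  g1 <- if ("high" %in% groups) "high" else groups[1]
  g2 <- setdiff(groups, g1)

  test_rows <- function(d, value_col, label_cols) {
    keys <- unique(d[label_cols])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      sel <- d
      for (cl in label_cols) sel <- sel[sel[[cl]] == keys[[cl]][i], ]
      x <- sel[[value_col]][sel$group == g1]
      y <- sel[[value_col]][sel$group == g2]
      if (sum(is.finite(x)) < 2 || sum(is.finite(y)) < 2) return(NULL)
      res <- two_sample_t(x, y, variant)
      dplyr::bind_cols(keys[i, , drop = FALSE], res)
    })
    dplyr::bind_rows(out)
  }

  res <- list()
  for (measure in c("duration_ms", "occurrence_hz", "coverage_pct")) {
    tab <- test_rows(params, measure, "state")
    if (nrow(tab) > 0) {
      tab$measure <- measure
      res[[measure]] <- bonferroni_family(tab, 4, alpha)
    }
  }
  gev_tab <- unique(params[c("subject_id", "group", "gev")])
  if (nrow(gev_tab) > 0 && !all(is.na(gev_tab$gev))) {
    gv <- two_sample_t(gev_tab$gev[gev_tab$group == g1],
                       gev_tab$gev[gev_tab$group == g2], variant)
    gv$measure <- "gev"
    gv$state <- NA_character_
    res$gev <- bonferroni_family(gv, 1, alpha)
  }
  if (!is.null(transitions)) {
    tt <- test_rows(transitions, "probability", c("from", "to"))
    if (nrow(tt) > 0) {
      tt$measure <- "transition"
      res$transition <- bonferroni_family(tt, 12, alpha)
    }
  }
  table <- dplyr::bind_rows(res)
  table$d <- effect_size(table$t, table$n1, table$n2, corrected = FALSE)
  table$d_corrected <- effect_size(table$t, table$n1, table$n2,
                                   corrected = TRUE)
  n1 <- sum(params$group == g1 & params$state == params$state[1])
  n2 <- sum(params$group == g2 & params$state == params$state[1])
  low_n <- min(n1, n2) < 5
  if (low_n) warning("group size below 5: statistics flagged low-n")
  structure(
    list(table = table, groups = c(g1, g2), alpha = alpha,
         n = c(n1, n2), low_n = low_n, variant = variant),
    class = "ms_group_comparison"
  )
}

#' @export
print.ms_group_comparison <- function(x, ...) {
  cat("<ms_group_comparison> ", x$groups[1], " (n=", x$n[1], ") vs ",
      x$groups[2], " (n=", x$n[2], "), variant=", x$variant,
      if (x$low_n) " [low-n]", "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `ms_group_comparison`.
#' @param ... Unused.
#' @method tidy ms_group_comparison
#' @export
tidy.ms_group_comparison <- function(x, ...) {
  dplyr::select(x$table, "measure", dplyr::any_of(c("state", "from", "to")),
                dplyr::everything())
}

#' @rdname compare_groups
#' @method glance ms_group_comparison
#' @export
glance.ms_group_comparison <- function(x, ...) {
  tibble::tibble(
    group_high = x$groups[1], group_low = x$groups[2],
    n_high = x$n[1], n_low = x$n[2], alpha = x$alpha,
    variant = x$variant, low_n = x$low_n,
    n_comparisons = nrow(x$table),
    n_significant = sum(x$table$significant, na.rm = TRUE)
  )
}
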