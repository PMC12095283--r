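# End-to-end drivers: subject-level segmentation, the two-level group
# template scheme, and a directory-writing pipeline wrapper.

#' Default analysis configuration
#'
#' Collects the pipeline settings in one list: broadband `band`
#' (0.5-80 Hz) and `notch` (50 Hz), `epoch_s` (2 s), rejection
#' threshold `amp_uv` (80 uV) and `max_bad_channels` (10), microstate
#' `ms_band` (2-20 Hz), cluster count `k` (4), GFP-peak separation
#' `min_sep_ms` (10 ms), smoothing `smooth_ms` (30 ms) and `besag`
#' (10), minimum segment `min_ms` (30 ms), the GFP-peak subsample cap
#' `max_peak_maps` and the group `template_level` ("two_level" or
#' "pooled").
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    band = c(0.5, 80), notch = 50, epoch_s = 2, amp_uv = 80,
    max_bad_channels = 10, ms_band = c(2, 20), min_retained_s = 0,
    k = 4, min_sep_ms = 10, smooth_ms = 30, besag = 10, min_ms = 30,
    max_peak_maps = 200, template_level = "two_level"
  )
  utils::modifyList(cfg, list(...))
}

#' Segment one preprocessed recording
#'
#' GFP-peak extraction, subject-level T-AAHC (unless templates are
#' supplied), backfitting, window smoothing, short-segment removal and
#' parameter extraction.
#'
#' @param rec Preprocessed (average-referenced, microstate-band)
#'   [eeg_recording()].
#' @param templates Optional `ms_templates` to backfit with; when
#'   `NULL` the subject's own T-AAHC solution is used.
#' @param k Number of classes for subject-level clustering.
#' @param config List from [default_config()].
#' @param seed Seed for the peak-map subsample.
#' @return List: `labels` (`ms_labels`), `params` (`ms_params`),
#'   `templates` (backfitting set), `subject_templates` (own T-AAHC
#'   fit), `peaks`.
#' @export
segment_recording <- function(rec, templates = NULL, k = 4,
                              config = default_config(), seed = 1L) {
  g <- compute_gfp(rec)
  pk <- find_gfp_peaks(g, config$min_sep_ms)
  pm <- peak_maps(rec, pk, max_maps = config$max_peak_maps, seed = seed)
  own <- taahc(pm, k, weights = attr(pm, "gfp"))
  fit_templates <- if (is.null(templates)) own else templates
  lab <- backfit(rec, fit_templates)
  lab <- smooth_labels(lab, rec, fit_templates,
                       window_ms = config$smooth_ms, besag = config$besag)
  lab <- drop_short_segments(lab, rec, fit_templates, min_ms = config$min_ms)
  par <- microstate_parameters(lab, rec, fit_templates)
  list(labels = lab, params = par, templates = fit_templates,
       subject_templates = own, peaks = pk)
}

#' Analyze a simulated two-group study end to end
#'
#' For every subject: synthesize (unless recordings are attached),
#' preprocess, extract GFP-peak maps and a subject-level T-AAHC
#' solution. Group templates are then built per group -- either a
#' second T-AAHC across the subjects' templates (`"two_level"`, the
#' default) or one T-AAHC over the pooled peak maps (`"pooled"`) --
#' labeled canonically, and backfitted to every subject of that group.
#' Ends with the two-group comparison and score correlations.
#'
#' @param study An `ms_group_study` from [make_group_study()].
#' @param config List from [default_config()].
#' @param preprocess Run the full preprocessing chain per subject
#'   (band-pass + notch, epoching, rejection, average reference,
#'   microstate band).
#' @param backfit_truth Backfit with the study's generating templates
#'   instead of estimated group templates (for calibration runs).
#' @return Object of class `ms_group_analysis`: per-subject `params`
#'   and `transitions` tibbles, `group_templates`, `qc`, `stats`
#'   (`ms_group_comparison`), `correlations`, `failed`.
#' @export
run_group_analysis <- function(study, config = default_config(),
                               preprocess = TRUE, backfit_truth = FALSE) {
  stopifnot(inherits(study, "ms_group_study"))
  subjects <- study$subjects
  n <- length(subjects)
  recs <- vector("list", n)
  subj_templates <- vector("list", n)
  qc <- vector("list", n)
  failed <- character()

  for (i in seq_len(n)) {
    sid <- subjects[[i]]$subject_id
    res <- tryCatch({
      rec <- if (!is.null(study$recordings)) {
        study$recordings[[i]]$recording
      } else {
        subject_recording(subjects[[i]], study$templates)$recording
      }
      if (preprocess) {
        pp <- preprocess_recording(
          rec, band = config$band, notch = config$notch,
          epoch_s = config$epoch_s, amp_uv = config$amp_uv,
          max_bad_channels = config$max_bad_channels,
          ms_band = config$ms_band,
          min_retained_s = config$min_retained_s
        )
        list(rec = pp$recording, qc = pp$qc)
      } else {
        list(rec = microstate_band(average_reference(rec),
                                   config$ms_band[1], config$ms_band[2]),
             qc = tibble::tibble(total_epochs = NA_integer_,
                                 rejected_epochs = NA_integer_,
                                 retained_epochs = NA_integer_,
                                 retained_seconds = ncol(rec$data) / rec$srate,
                                 interpolated_n = 0L,
                                 interpolated_channels = "",
                                 included = TRUE))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sid)
      qc[[i]] <- tibble::tibble(subject_id = sid, included = FALSE,
                                reason = conditionMessage(res))
      next
    }
    recs[[i]] <- res$rec
    qc[[i]] <- dplyr::mutate(res$qc, subject_id = sid, reason = "")
    g <- compute_gfp(res$rec)
    pk <- find_gfp_peaks(g, config$min_sep_ms)
    pm <- peak_maps(res$rec, pk, max_maps = config$max_peak_maps,
                    seed = subjects[[i]]$seed)
    subj_templates[[i]] <- list(
      fit = taahc(pm, config$k, weights = attr(pm, "gfp")),
      maps = pm
    )
  }
  ok <- which(!vapply(recs, is.null, logical(1)))
  if (length(ok) == 0) stop("no subject survived preprocessing", call. = FALSE)

  groups <- vapply(subjects, `[[`, "", "group")
  group_templates <- list()
  for (g in unique(groups)) {
    gi <- intersect(ok, which(groups == g))
    tpl <- if (backfit_truth) {
      study$templates
    } else if (config$template_level == "pooled") {
      pooled <- do.call(rbind, lapply(gi, function(i) subj_templates[[i]]$maps))
      w <- unlist(lapply(gi, function(i) attr(subj_templates[[i]]$maps, "gfp")))
      canonical_labels(taahc(pooled, config$k, weights = w))
    } else {
      stacked <- do.call(rbind,
                         lapply(gi, function(i) subj_templates[[i]]$fit$maps))
      canonical_labels(taahc(stacked, config$k))
    }
    group_templates[[g]] <- tpl
  }

  params <- list(); transitions <- list()
  for (i in ok) {
    sid <- subjects[[i]]$subject_id
    g <- groups[i]
    tpl <- group_templates[[g]]
    lab <- backfit(recs[[i]], tpl)
    lab <- smooth_labels(lab, recs[[i]], tpl, window_ms = config$smooth_ms,
                         besag = config$besag)
    lab <- drop_short_segments(lab, recs[[i]], tpl, min_ms = config$min_ms)
    par <- microstate_parameters(lab, recs[[i]], tpl)
    params[[sid]] <- dplyr::mutate(tidy(par), subject_id = sid, group = g,
                                   .before = 1)
    transitions[[sid]] <- dplyr::mutate(par$transitions, subject_id = sid,
                                        group = g, .before = 1)
  }
  params <- dplyr::bind_rows(params)
  transitions <- dplyr::bind_rows(transitions)

  stats <- compare_groups(params, transitions)
  corr <- tryCatch({
    bc <- dplyr::filter(transitions, .data$from == "B", .data$to == "C")
    d <- dplyr::inner_join(bc, study$design, by = c("subject_id", "group"))
    dplyr::bind_rows(
      dplyr::mutate(ms_correlate(d, "lsas_total", "probability", "group"),
                    score = "lsas_total", .before = 1),
      dplyr::mutate(ms_correlate(d, "lsas_avoidance", "probability", "group"),
                    score = "lsas_avoidance", .before = 1)
    )
  }, error = function(e) NULL)

  structure(
    list(params = params, transitions = transitions,
         group_templates = group_templates,
         qc = dplyr::bind_rows(qc), stats = stats, correlations = corr,
         failed = failed, config = config),
    class = "ms_group_analysis"
  )
}

#' @export
print.ms_group_analysis <- function(x, ...) {
  cat("<ms_group_analysis> ", length(unique(x$params$subject_id)),
      " subjects analyzed (", length(x$failed), " failed)\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Run the full simulate-and-analyze pipeline into a directory
#'
#' Simulates a two-group study, runs [run_group_analysis()], and writes
#' a deterministic layout: `qc/qc.tsv`, `templates/templates_<group>.tsv`,
#' `params/params.tsv`, `params/transitions.tsv`, `stats/stats.tsv`,
#' `stats/correlations.tsv`, `design.tsv` and `config.json`. Reruns
#' with the same seed produce identical tables.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the whole run.
#' @param n_per_group,effect_spec,duration_s,srate,snr Passed to
#'   [make_group_study()].
#' @param config Analysis settings from [default_config()].
#' @return The `ms_group_analysis`, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_per_group = c(23, 18),
                         effect_spec = c(C = 20, D = -25),
                         duration_s = 16, srate = 250, snr = 4,
                         config = default_config()) {
  study <- make_group_study(n_per_group = n_per_group,
                            effect_spec = effect_spec, seed = seed,
                            srate = srate, duration_s = duration_s,
                            snr = snr)
  ana <- run_group_analysis(study, config = config)
  for (d in c("qc", "templates", "params", "stats")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  w <- function(x, ...) readr::write_tsv(x, file.path(out_dir, ...))
  w(study$design, "design.tsv")
  w(study$truth, "truth.tsv")                  # ground-truth sidecar
  w(ana$qc, "qc", "qc.tsv")
  for (g in names(ana$group_templates)) {
    tpl <- ana$group_templates[[g]]
    w(tidy(tpl), "templates", paste0("templates_", g, ".tsv"))
  }
  w(ana$params, "params", "params.tsv")
  w(ana$transitions, "params", "transitions.tsv")
  w(tidy(ana$stats), "stats", "stats.tsv")
  if (!is.null(ana$correlations)) w(ana$correlations, "stats",
                                    "correlations.tsv")
  cfg <- c(config, list(seed = seed, n_per_group = n_per_group,
                        effect_spec = as.list(effect_spec),
                        duration_s = duration_s, srate = srate, snr = snr))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ana)
}

#' Bundled published group summary statistics
#'
#' Group-level means and standard deviations (high vs low social
#' anxiety, n = 23/18) for scale scores, microstate parameters and
#' transition probabilities, as printed in a published two-group
#' resting-state microstate comparison. Used to recompute t statistics
#' with [t_from_summary()].
#'
#' @return Tibble: `measure`, `state`, `m_high`, `sd_high`, `n_high`,
#'   `m_low`, `sd_low`, `n_low`, `variant`.
#' @export
group_summary_stats <- function() {
  path <- system.file("extdata", "group_summary_stats.tsv", package = "msdyn")
  readr::read_tsv(path, show_col_types = FALSE)
}
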