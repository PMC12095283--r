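# msdyn — resting-state EEG microstate dynamics

`msdyn` analyzes the millisecond-scale dynamics of resting-state EEG as
a sequence of **microstates**: brief (tens to hundreds of ms) periods
during which the scalp voltage topography stays quasi-stable,
classically labeled A–D. It is aimed at researchers comparing
microstate temporal parameters between groups — for example high
versus low trait social anxiety — and at methodologists who need a
fully synthetic, ground-truth-verifiable version of that entire
analysis chain.

The package covers:

* **Synthetic ground truth** — a semi-Markov generator (gamma dwell
  times over a zero-diagonal jump chain) producing 64-channel EEG whose
  instantaneous map is one of K templates carrying a 10 Hz oscillation
  with random per-segment polarity, plus white sensor noise at a chosen
  SNR, with truth sidecars for every downstream check, and a two-group
  study builder with configurable dwell contrasts and anxiety-like
  scale scores.
* **Preprocessing** — zero-phase FIR band-pass (0.5–80 Hz) with FIR
  notch (50 Hz), 2 s epoching, spherical-spline interpolation of bad
  channels, amplitude-based epoch rejection (more than 10 channels over
  80 µV), average reference, 2–20 Hz microstate band.
* **The microstate engine** — global field power (GFP) and peak
  extraction, T-AAHC clustering (atomize-and-agglomerate, polarity
  invariant), seven cluster-validity criteria with a modal
  meta-criterion, canonical A–D labeling, GMD backfitting
  (GMD² = 2(1 − |r|)), 30 ms window smoothing (Besag factor 10), short
  segment removal, and per-state duration / occurrence / coverage /
  GEV / transition probabilities.
* **Group inference** — pooled/Welch/Levene-gated t-tests, Cohen's d
  (raw and small-sample corrected), Bonferroni families (0.05/4 for
  parameters, 0.05/12 for transitions), within-group Pearson
  correlations with scale scores, and a summary-statistics mode that
  recomputes published t-values directly from group means and SDs.

## Worked example

Recompute a published group row from its summary moments — state-C
duration, high group 83.64 ± 13.56 ms (n = 23) versus low group
62.23 ± 10.17 ms (n = 18):

```r
library(msdyn)
t_from_summary(83.640, 13.560, 23, 62.230, 10.170, 18, "pooled")
#> # A tibble: 1 × 4
#>       t    df          p variant
#>   <dbl> <dbl>      <dbl> <chr>
#> 1  5.58    39 0.00000200 pooled
effect_size(5.577, 23, 18, corrected = TRUE)
#> [1] 1.721093
```

The t of 5.58 with 39 df and corrected Cohen's d of 1.72 say the
high-anxiety group dwells about 21 ms longer in microstate C, a very
large standardized difference.

Simulate a full two-group study with the built-in contrast (+20 ms
C dwell, −25 ms D dwell in the high group) and run the whole chain —
per-subject synthesis, preprocessing, GFP-peak clustering, group
templates, backfitting, parameters, statistics:

```r
study <- make_group_study(n_per_group = c(23, 18), seed = 7,
                          srate = 125, duration_s = 8)
ana <- run_group_analysis(study,
        config = default_config(band = c(0.5, 55), max_peak_maps = 100))
dplyr::filter(tidy(ana$stats), measure == "duration_ms")
#> # A tibble: 4 × 6
#>   state      t    df         p d_corrected significant
#>   <chr>  <dbl> <dbl>     <dbl>       <dbl> <lgl>
#> 1 A      0.652    39 0.518           0.201 FALSE
#> 2 B     -1.34     39 0.187          -0.414 FALSE
#> 3 C      4.42     39 0.0000769       1.36  TRUE
#> 4 D     -3.33     39 0.00188        -1.03  TRUE
```

The pipeline recovers the generated contrast: C duration significantly
longer and D duration significantly shorter in the high group, with the
other states null — the same pattern the generator was asked to
produce. `glance(ana$stats)` summarizes the design;
`autoplot(ana$group_templates$high)` draws the four group topographies;
`run_pipeline(out_dir, seed)` writes the whole run (QC, templates,
parameters, transitions, statistics, resolved config) as TSV/JSON.

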