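---
title: "Microstate dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdyn)
```

## The model

EEG microstate analysis treats the multichannel resting EEG as a
sequence of brief, quasi-stable scalp topographies. At any instant the
measured map $v_t \in \mathbb{R}^C$ (average-referenced across $C$
channels) is modeled as one of $K$ templates $a_k$ (unit-norm,
zero-mean) scaled by a waveform and corrupted by sensor noise:

$$ v_t = s_t \, a_{z_t} + \varepsilon_t, $$

where $z_t$ is the active state, $s_t$ an oscillatory amplitude whose
sign is not informative (the polarity of an EEG map flips with the
oscillation phase), and $\varepsilon_t$ sensor noise. Everything
downstream is therefore polarity-invariant: similarity between maps is
the absolute spatial Pearson correlation $|r|$, equivalently the global
map dissimilarity $\mathrm{GMD} = \sqrt{2(1-|r|)}$.

The canonical summary statistics per state are the mean segment
**duration** (ms), **occurrence** rate (segments/s), time **coverage**
(% of assigned samples), the **global explained variance**

$$ \mathrm{GEV} = \frac{\sum_t (\mathrm{GFP}_t\, r_t)^2}{\sum_t \mathrm{GFP}_t^2}, $$

with $\mathrm{GFP}_t$ the spatial standard deviation of the map and
$r_t$ the correlation with the assigned template, and the 12-cell
**transition matrix** of ordered segment adjacencies $x \to y$,
normalized by the total number of adjacencies (so the 12 off-diagonal
cells sum to 1; per-row normalization is deliberately not used, matching
the near-unit total of published pooled tables).

## The processing chain

The chain is fixed: broadband filter (0.5–80 Hz zero-phase FIR plus a
50 Hz FIR band-stop, both applied in one FFT pass to the continuous
signal) → 2 s epoching → spherical-spline interpolation of flagged
channels (order-4 splines, at most 5 channels; 6 or more excludes the
subject) → epoch rejection (an epoch is dropped when *more than* 10
channels exceed 80 µV in absolute amplitude; peak-to-peak is available
behind a flag) → optional external artifact hook (ICA-style cleaning is
delegated to the caller; the synthetic generator produces artifact-free
data) → average reference → 2–20 Hz microstate band.

Two reading choices deserve a note. The 80 µV criterion is read as
absolute amplitude, the common convention in EEGLAB-style thresholding;
peak-to-peak is supported as an option. And the microstate band filter
defaults to filtering the concatenated retained signal rather than each
epoch separately: retained epochs are contiguous 2 s blocks, and
per-epoch reflection padding re-introduces an edge transient at every
boundary (measured 30 Hz residual around 15 % of input amplitude versus below
0.1 % for the concatenated pass). Per-epoch filtering remains available via
`per_epoch = TRUE`.

## Clustering and backfitting

Template estimation uses only the maps at GFP peaks, where the
signal-to-noise ratio is highest. The clustering is a topographic
atomize-and-agglomerate hierarchy (T-AAHC): every peak map starts as a
singleton cluster; at each step the cluster contributing least GEV is
dissolved and its members are reassigned to the remaining cluster of
highest $|r|$; affected centroids are recomputed as polarity-aligned
means (each member flipped to positive correlation with the current
centroid, averaged, renormalized — a first-principal-pattern centroid
is available behind a flag). The "worst cluster" criterion is the GEV
contribution; the exact criterion used by closed-source implementations
is not published, and GEV is the quantity the final solution reports.

Group-level templates follow a two-level scheme by default: each
subject is clustered to $K$ templates, then a second T-AAHC across the
subjects' templates per group gives the group set; a pooled-peaks
alternative is available. Templates are labeled A–D by exhaustively
matched assignment (all $K!$ permutations) against built-in archetype
maps: A and B are opposite diagonal dipoles (lateral axis weighted
double the anterior axis, which keeps all pairwise $|r| \le 0.7$ even
on sparse montages), C a focal anterior-central Gaussian, D an
anterior–posterior gradient.

Backfitting assigns every sample to the template of maximal $|r|$
(minimal GMD); zero-GFP samples stay unassigned. Smoothing is windowed
nonsmoothness-penalized relabeling: the score of state $k$ at sample
$t$ is $r_{tk}^2 + \lambda\, n_{tk}$, with $n_{tk}$ the fraction of
samples in the 30 ms window already labeled $k$, iterated to a fixed
point. The mapping from the conventional Besag factor to $\lambda$ is a
genuine free parameter; it was calibrated once on synthetic recordings
so that the canonical factor of 10 balances the two opposing error
modes — boundary erosion/fragmentation (too little smoothing, biasing
durations down) against short-segment erasure (too much, biasing the
shortest state's duration up). The calibrated value is $\lambda = 0.15$
per Besag unit; with it, mean durations recover the generative dwell
means within ±10 % at SNR 4. Segments shorter than 30 ms are then
dissolved, each split at the cut maximizing the fit of the prefix to
the left neighbor and the suffix to the right; epoch-edge segments are
exempt since their dwell is censored.

Duration and occurrence statistics use interior segments only (edge
segments are truncated by the epoch boundary and would bias durations
down); coverage includes all assigned samples, and unassigned samples
are excluded from the coverage denominator.

## The synthetic generator

The generator emulates 64-channel eyes-closed recordings whose
instantaneous topography is one of the four archetypes. State dynamics
are semi-Markov: a zero-diagonal jump chain (uniform by default) with
gamma-distributed dwell times, shape 2 — the shape is a stand-in choice
(sub-exponential, so one-sample dwells are rare); the source literature
characterizes dwell only by its mean. Within a segment the map carries
a 10 Hz sinusoid with an independent random phase per segment, so
polarity flips across segments and any polarity-sensitive step
downstream would fail loudly. Noise is spatially white Gaussian after
average reference, scaled so the ratio of state-signal RMS to noise
RMS equals the requested SNR (default 4); spatially correlated noise is
deferred. An optional 50 Hz sinusoid exists solely to exercise the
notch.

The two-group study generator anchors baseline dwell means at
(70, 70, 62, 110) ms for A–D — the low-group durations of the published
comparison — and applies the high-group contrast (+20 ms to C, −25 ms
to D by default) on top of between-subject variation (SD 10 ms for A–C,
18 ms for D, within the published per-state spread). Anxiety-like
scores use group anchors 82.17/27.83 with SD ≈ 12.5 and a configurable
within-group correlation (0.5) to the subject's true C dwell, with fear
and avoidance subscales at roughly half the total each. What the
generator does *not* emulate: ocular/muscle artifacts, bad channels,
spatially structured noise, inter-individual topography differences,
and any deviation of real microstate syntax from the semi-Markov
assumption — so passing recovery tests demonstrates correctness of the
estimator chain under the model, not fidelity of the model to real EEG.

## Statistics

Group comparisons are independent-sample t-tests, high minus low. The
default variant is Levene-gated (`auto`): a two-group Brown–Forsythe
style test on absolute deviations at the 0.05 level selects Welch when
variances differ, pooled otherwise. This matters for faithfulness: the
published state-C rows are internally consistent only under the pooled
formula and the state-D rows only under Welch (their printed df of 39
notwithstanding — the reported df here follows the computed variant).
Moment-based recomputation (`t_from_summary`) applies the same formulas
to published means/SDs and is tested to agree with the raw-sample path
to floating tolerance. Cohen's d is $t\sqrt{1/n_1+1/n_2}$, reported
both raw and with the small-sample correction $1 - 3/(4\,df - 1)$; the
published effect sizes match the corrected value for some rows and the
raw one for others, so neither convention is asserted globally.
Bonferroni families are 0.05/4 for the four-state parameter families
and 0.05/12 for the twelve transitions, strict inequality. Correlations
between scale scores and microstate features are Pearson, computed
within group and uncorrected (an FDR flag exists for users).

## Numerical and scale choices

Problem sizes were chosen as the package's own test design points. The
replicated two-group studies use 41 subjects (23/18) with 8 s of
synthetic EEG at 125 Hz per subject and a 100-map cap on clustered GFP
peaks; 100 replicates verify sign recovery of the C/D duration
contrast and 500 null replicates (evaluated on the generator's
ground-truth subject parameters, where the inference layer operates)
verify the type-I error of the parameter family. Single-subject
recovery checks use 120 s at 250 Hz, equal 80 ms dwells, SNR 4.
Duration recovery is evaluated on the smoothed, unpruned sequence: the
30 ms minimum-duration rule censors short dwells by design and inflates
mean durations by roughly a third under gamma-2 dwell laws, for real
data exactly as for synthetic — a property of the published estimator,
not a defect of the implementation.

Tie-breaks are deterministic throughout: equal-fit backfitting takes
the lowest template index, equal GFP peaks keep the earlier sample,
equal label assignments in canonical labeling resolve by total
assignment score. Degenerate inputs (zero-GFP maps, identical maps with
k > 1, zero-variance score vectors) are either excluded with a flag or
raise an informative condition, as exercised in the test suite.

## Known limitations

The montage is schematic (ring/column construction of the 10-10
layout), adequate for smooth archetypes, spline interpolation and
display but not for source-space claims. EDF input is not implemented;
BrainVision triplets and in-memory objects are the supported formats.
The modified k-means alternative to T-AAHC is not shipped. Correlation
analyses replicate the published within-group, uncorrected convention;
with n of 18–23 per group those r values carry wide confidence
intervals and should be read accordingly.
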