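---
title: "Detecting transfer-competent subpopulations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transfer-competent subpopulations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpopq)
```

## The biological problem

Integrative and conjugative elements (ICEs) are mobile DNA elements that
excise from a bacterial chromosome and transfer to recipient cells by
conjugation. In the ICEclc system of *Pseudomonas*, transfer initiates only
in a small, differentiated subset of cells — transfer-competent (tc) cells —
that arises in stationary phase in 1–10% of an isogenic population. With a
single-copy fluorescent promoter fusion, this bistability shows up as a
*bimodal* per-cell fluorescence distribution: a dominant main population at
low, background-level expression, and a rare bright subpopulation.

`subpopq` implements the computational side of quantifying this phenotype
from segmented single-cell measurements: subpopulation detection from
snapshots, two-reporter colocalization, time-lapse activation-onset calling,
count-matrix normalization and differential comparison, and the
replicate-level statistics used to report such experiments. Everything is
exercised end to end against synthetic data with known ground truth.

## The qq-plot subpopulation estimator

Per-cell fluorescence values $F$ are first normalized by the local image
background $I$ as $(F - I)/I$ (`normalize_background()`), which makes
expression comparable across images, strains and exposure settings.

`qq_fit()` then works on the quantile–quantile plot of the normalized values
against the standard normal: sorted observations are paired with
$\Phi^{-1}\!\big((i - 3/8)/(n + 1/4)\big)$ (Blom plotting positions; any
continuous rule differs negligibly at $n \approx 1000$). The main population
is defined as the points whose empirical quantile lies between the first and
third quartiles; an ordinary least-squares line through those points
estimates its location and scale. A genuine second mode departs abruptly
from this line in the upper tail, so cells are classified as subpopulation
when they lie **beyond the third quartile** and **above an upper confidence
threshold** of the main-population fit. The detected fraction is the
subpopulation share of all cells.

### Why the threshold is a residual band

Two threshold constructions are implemented:

* `threshold_type = "band"` (default): the fit line raised by
  $t_{1-\alpha}\,s$, where $s$ is the root-mean-square residual of *all*
  points around the main-population line. Under a clean unimodal sample the
  residuals — and hence the band — are small; a real second mode inflates
  $s$ together with its own departure, which keeps the threshold between
  the two modes. This self-scaling is what makes the method insensitive to
  absolute intensity differences between reporters.
* `threshold_type = "slope-ci"`: the fit line recomputed with the slope
  raised to its upper confidence bound, pivoting at the centroid of the
  fitted points.

The slope-CI construction is provided for completeness, but it is **not**
the default for a measurable reason: the standard error of a slope fitted
to several hundred extremely smooth inter-quartile order statistics is far
smaller than the sampling fluctuation of tail order statistics, so the
raised line hugs the data and roughly half of the upper-tail points of a
*pure normal* sample end up above it (about 9% of cells flagged in our
calibration runs, versus ~0.5% for the band). The band construction is the
one whose null behavior matches what the method is supposed to deliver.

### Skewed fluorescence and the log scale

Microbial reporter fluorescence is strongly right-tailed; on a normal
qq-plot a smooth lognormal-like null curves upward and would mimic a
subpopulation (≈5% median false detection in our calibration). With
`transform = "auto"` (default) the fit therefore runs on the log scale
whenever all values are positive and the moment skewness exceeds 0.5;
classification is reported on the original scale. This brings the
lognormal-null false-detection median below 1% without affecting mixture
recovery. Two consequences are documented deliberately:

* `transform = "none"` is exactly shift- and scale-equivariant (adding or
  multiplying by a constant leaves the classified cells unchanged);
  `"auto"` keeps scale equivariance but gives up shift equivariance,
  because the skew decision adapts to the shape of the data.
* The switch is discontinuous at the skewness cutoff; for a pipeline in
  which this matters, fix `transform` explicitly.

### Known limitations

The estimator targets *rare* subpopulations. Once the true fraction grows
toward ~30%, the bright mode reaches into the quartile window and biases
the main-population fit; `qq_fit()` then warns (a gap larger than the
window spread inside the quartile window, or a saturated upper quartile)
but still returns a result. The hard geometric ceiling of the
classification rule is $1 - Q_3 = 25\%$ of cells. There is deliberately no
mixture-model (EM) alternative: the package reproduces this estimator, with
its documented bias.

## Colocalization of two reporters

For paired-channel snapshots, each channel is thresholded by its own
`qq_fit()` on the same cells and every cell falls in exactly one quadrant
(`classify_quadrants()`; values exactly on a scalar threshold count as
low). `overlap_percent()` defaults to the *union* (Jaccard) reading,
$100\,|A \cap B| / |A \cup B|$, because published overlap figures shade the
intersection of two marked subpopulations; conditional modes
(`"given-gfp"`, `"given-mcherry"`) are provided to reproduce either
conditional reading, and the union overlap is provably never larger than
either conditional one. Reported results should state the mode.
`scale_to_max()` implements the percent-of-maximum scaling
$(F - I)/(F_{max} - I) \times 100$ used for such scatter plots.

## Time-lapse onset analysis

The trace pipeline (`timelapse_analysis()`) follows five steps:

1. **Growth curve** — live-cell counts per frame from lineage-linked traces
   (`growth_curve()`); orphan cells warn and are counted from first
   appearance.
2. **Carry-over removal** — cells already activated in the preceding
   stationary-phase preculture are bright from the start of the movie. A qq
   threshold is derived from the pooled 0–10 h (exponential-phase)
   observations; a cell classified above it in at least 3 frames of that
   window is removed whole-trace. Multi-frame evidence distinguishes a
   genuinely pre-activated cell (bright throughout) from single-frame fit
   noise. The rule is applied per channel with a combined (either-channel)
   removal; cells first appearing after 10 h are never touched.
3. **Length filter** — traces with fewer than 10 time points are dropped.
4. **Moving qq threshold** — `qq_fit()` on the cross-section of live-cell
   values at every frame gives the tc subpopulation size over time
   (`moving_qq_threshold()`); the per-channel tc cell sets are combined by
   union, since tc classification on one fluorophore need not overlap the
   other.
5. **Onset detection** — for each tc cell and channel, an ordinary
   least-squares regression slides over every window of 5 consecutive
   observed frames (gaps break windows). A window qualifies when its total
   fluorescence rise exceeds 8 camera units *over the window* and its
   $r^2$ exceeds 0.9800; the onset is the first point of the first run of
   at least 2 consecutive qualifying windows. If no window qualifies the
   onset is the sentinel value 1, stored together with a logical
   `detected` flag so numeric summaries can never mistake the sentinel for
   a real time.

Design choices worth recording:

* "8 fluorescence units over five consecutive time points" is read as the
  *total rise across the window* (slope × window span), not a per-frame
  slope of 8; both readings are available via `slope_mode`.
* The onset is anchored at the *window start*; with a 5-point window at
  30-min intervals a noiseless ramp is recovered frame-exactly, because the
  window straddling the kink fails the $r^2$ criterion
  ($r^2 \approx 0.94 < 0.98$ for four ramp points plus one flat point).
* The requirement of ≥ 2 consecutive qualifying windows replaces
  interactive confirmation of single-window slopes in small datasets with
  a deterministic rule.
* `slope_null_threshold()` offers a data-driven alternative to the fixed
  threshold 8: the pooled window-rise distribution is trimmed of outliers
  beyond 1.5 IQR (so genuine ramps do not inflate the null) and the
  threshold is placed at the 0.99 quantile of the remaining bulk.

## Count normalization and differential comparison

`pseudoreference_normalize()` implements median-of-ratios normalization:
per-gene geometric means across samples form the pseudoreference; a
sample's size factor is the median ratio of its counts to the
pseudoreference, over genes with a positive geometric mean (genes with a
zero anywhere are excluded from the factor computation but still
normalized — the standard convention). Normalized data are `log2(x + 1)`
transformed to deal with zeros. `region_log2fc()` reports per-gene and
per-region log2 fold changes both as the ratio of mean normalized counts
and as the difference of mean `log2(x+1)` values (published figures rarely
state which; both are emitted, and genes with a zero group mean fall back
to the log-space difference, flagged).

The published analog of this pipeline used a MATLAB "t-test with
bootstrapping (n = 1000)" without further specification;
`bootstrap_ttest()` re-specifies it precisely as a pooled-variance
two-sample t statistic per gene calibrated against a null built by
centering each group, pooling, and resampling both groups with replacement
1000 times, with the add-one p-value correction
$(1 + \#\{|t^*| \ge |t|\})/(B + 1)$. Degenerate-variance genes fall back
to a label-permutation test on the mean difference and are flagged. Type-I
error at $\alpha = 0.05$ measures 0.05–0.06 on 500 null genes in the
acceptance script.

For induction experiments with strongly tailed distributions,
`percentile95_compare()` compares the 95th percentile of
background-subtracted per-cell fluorescence between paired induced/control
replicates with a one-sided paired t-test.

## Replicate statistics

`anova_tukey_letters()` runs one-way `aov()` plus `TukeyHSD()` and derives
a compact letter display by insert-and-absorb over the pairwise
non-significance graph, inserting groups in decreasing mean order and
naming letters by factor-level order (so a forced separation of two low
groups from one high group reads "a, a, b"). The partition agrees with
`multcomp::cld()` on random group sets (tested). `bartlett_groups()` wraps
`stats::bartlett.test()` and flags the all-constant degenerate case.
`transfer_frequency()` computes conjugation frequencies as
background-corrected exconjugant CFU per donor CFU with dilution scaling;
non-positive corrected counts report "below detection" with the limit set
by one colony at the plated dilution per donor CFU.
`paired_main_vs_sub_test()` is the one-sided paired t-test that sub
exceeds main expression, with documented edge behavior at zero-variance
differences (p = 0.5 for identical pairs; 0 or 1, flagged degenerate, for
a uniform shift).

## What the synthetic generators emulate — and what they do not

* `simulate_snapshot()`: ~1000 cells over 5–10 images, per-image Gaussian
  background, lognormal (default) or normal main population above
  background, Bernoulli-labelled high cells. Defaults (background 100 ± 5,
  main 20 ± 8, sub 200 ± 40 a.u., 5% subpopulation) were chosen once as a
  realistic, well-separated reporter scenario; real distribution parameters
  for specific strains are not published, so these defaults are for
  separability, not strain mimicry.
* `simulate_paired_snapshot()`: realizes a designed Jaccard overlap between
  the two channels' true high sets exactly up to rounding, with independent
  intensities per channel.
* `simulate_timelapse()`: 96 frames at 30 min (≈48 h), four jittered
  divisions before a 20 h stationary point, uniform activation onsets in a
  20–30 h window, linear ramps of 10 ± 2 a.u./frame on a baseline of 100
  with 1 a.u. additive noise, a truncated-Gaussian inter-channel onset
  delay, and a carried-over pre-activated founder fraction. Carried-over
  cells do not divide — tc cells arrest division in this system — which is
  also what lets the 0–10 h filter remove the whole carried-over lineage.
* `simulate_counts()`: negative-binomial counts with lognormal per-gene
  base means, known size factors and designed log2 fold changes;
  dispersion 0 degenerates to Poisson.

None of the generators model pixel-level images, segmentation error,
fluorophore maturation kinetics, cell-size effects, or photobleaching.
Passing the pipeline's recovery tests therefore shows correctness of the
*statistical procedures* under the stated assumptions, not robustness to
segmentation artifacts or maturation delays in real movies.

## Numerical conventions

* Ties in sorted fluorescence are broken by cell id, so classifications are
  deterministic; all generators are byte-reproducible given a seed.
* Degenerate inputs fail loudly (`< 4` values, zero variance in the
  quartile window, missing backgrounds, zero donor CFU) rather than
  returning silent zeros; empty subpopulations report missing means, not 0.
* Frames with fewer than 4 live cells yield missing moving-qq thresholds
  and are logged, not interpolated.
* Problem sizes in the test-suite and acceptance script (10,000-cell
  snapshots × 50 seeds, ~500-cell movies, 500-gene bootstrap runs) were
  chosen as the smallest designs at which the binomial/Monte-Carlo error of
  each checked quantity is comfortably below its tolerance.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_snapshot(snapshot_params(seed = 1))
norm <- normalize_background(sim$cells)
fit <- qq_fit(norm$gfp, ids = norm$cell_id)
fit
subpop_means(norm$gfp, fit, ids = norm$cell_id)
plot(fit)
```
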