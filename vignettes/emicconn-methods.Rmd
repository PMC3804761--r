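---
title: "Non-linear functional connectivity with the extended maximal information coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear functional connectivity with the extended maximal information coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emicconn)
```

## The problem

Resting-state functional connectivity is usually summarized by the Pearson
correlation (PCC) between two regions' BOLD time series, which captures only
the linear part of their coupling. The BOLD signal, however, is the output
of a non-linear hemodynamic response, and non-linear dependence between
regional series is plausible and has been reported. `emicconn` implements a
measure of the *non-linear component* of an association and a complete
discriminative pipeline around it: given a two-group cohort of regional time
series it builds connectivity matrices, ranks edges by how well they
separate the groups, classifies subjects with a cross-validated linear SVM,
and extracts the network of edges that drive the classification.

## The association measures

For a paired sample $(x_i, y_i)$, $i = 1..n$:

* **PCC** — the product-moment correlation $r$; $r^2$ is the share of
  variance explained by the best linear fit.
* **MIC** — the maximal information coefficient. For a grid with $x$
  columns and $y$ rows laid over the scatterplot, the plug-in mutual
  information $I_g$ of the binned distribution measures how much the grid
  "captures" the relationship. The characteristic score of a grid shape is
  $m_{x \times y} = \max_g I_g / \log_2 \min\{x, y\}$, the maximum taken
  over all cut placements; MIC is the maximum of $m_{x \times y}$ over all
  shapes with $x y \le B$, $B = \lfloor n^{0.6} \rfloor$. MIC lies in
  $[0, 1]$, is symmetric, depends only on ranks, and reaches 1 for any
  noiseless functional relationship.
* **eMIC** — the extended MIC, $\mathrm{eMIC} = \mathrm{MIC} - r^2$. Since
  MIC responds to *any* functional association and $r^2$ to the linear part,
  their difference isolates the non-linear component: a noiseless line gives
  eMIC $= 0$, a noiseless symmetric parabola gives eMIC $= 1$.

```{r measures}
x <- seq(-1, 1, length.out = 200)
emic(x, 2 * x + 3)  # purely linear: mic 1, emic 0
emic(x, x^2)        # purely non-linear: pcc 0, mic 1, emic 1
```

### The partition search

Maximizing mutual information over all grids is combinatorial, so `mic()`
uses the standard two-stage heuristic: one axis is equipartitioned into $y$
rows on ranks (tied values are never split), and an exact dynamic programme
places column cuts to maximize the grid MI, with candidate cut positions
restricted to *clump* boundaries (runs of consecutive points in the same
row). Both axis orientations are evaluated, and all shapes within the
budget $B$. Three numerical choices matter:

* **Clump budget** (`clumps`, default 15): at most `clumps * x` candidate
  boundaries are kept per shape, merged by size when there are more. This
  is the usual speed/exactness dial of MIC implementations; `clumps = Inf`
  switches to an exhaustive search that also enumerates every admissible
  row partition, exact but limited to $n \le 12$.
* **Budget floor**: $B = \lfloor n^{0.6} \rfloor$ is floored at 4 so the
  $2 \times 2$ grid is always admissible.
* **Logarithms** are base 2 throughout; MI is reported in bits (the base
  cancels in the normalization).

Correctness of the search is pinned by an independent oracle:
`mic_oracle()` enumerates every placement of row and column cuts between
consecutive distinct values and scores grids by direct plug-in entropy on
binned counts, sharing no code path with the dynamic programme. The test
suite asserts agreement to $10^{-12}$ on hundreds of small samples.

Two properties of the estimator are worth knowing. First, eMIC is reported
*signed*: the search returns a heuristic maximum, so at finite $n$ MIC can
fall below $r^2$ and eMIC below zero; clipping would bias group means, so
values are never clipped. Second, at odd $n$ even a perfect line scores
marginally below 1 (no split of an odd sample has exactly uniform margins);
this is a property of the statistic, not of the implementation.

Degenerate input (a constant vector) raises a typed condition
(`emicconn_degenerate`) rather than returning 0; `build_connectivity()`
catches the situation up front and maps such edges to 0 with a warning, so
a flat region cannot silently poison a cohort analysis.

## Temporal preprocessing

`preprocess_subject()` applies, in fixed order: discard of the first 5
volumes (magnetic saturation), per-region linear detrending, a band-pass to
0.01–0.08 Hz, and regression on six head-motion parameters. The band-pass
is a Chebyshev Type I design, order 4, 0.5 dB passband ripple, applied
forward–backward (`signal::filtfilt`). The filter family and the zero-phase
application are our choices where convention leaves them open: zero-phase
filtering introduces no lag, which matters because a lag-sensitive
association measure is exactly what this pipeline feeds. Spatial steps
(realignment, normalization, smoothing, atlas masking) are out of scope;
`regional_average()` accepts any voxel-to-region labelling computed
elsewhere.

## Connectivity, ranking, classification

For $R$ regions the $R(R-1)/2$ upper-triangle entries (row-major, diagonal
excluded) form the feature vector; 116 regions give 6670 edge features.
Edges are ranked by the group-label Kendall tau: with $m$ controls (label
$+1$) and $n$ patients ($-1$), only cross-group pairs are counted,
$\tau = (n_c - n_d)/(m n)$, where a pair is concordant when the control has
the larger edge value. Tied cross-group pairs count toward neither term
(the denominator stays $m n$), making $\tau$ a pure function of the data;
ties in $|\tau|$ are broken by canonical edge order for determinism.
$\tau > 0$ means the edge is weaker in patients. Discriminative power is
$|\tau|$; selection is top-$k$ (the threshold variant is available via
`select_by_threshold()`, but fixed counts are what make results comparable
across measures).

Classification is a leave-one-out cross-validated linear SVM with $C = 1$
(LIBSVM via `e1071`). Each fold re-ranks edges on its training subjects
only — feature selection never sees the held-out subject, and a dedicated
test plants a subject that would flip the ranking to prove it. Features are
standardized with training-fold statistics (the measures already live on
comparable scales; the switch is exposed). A decision score of exactly 0
predicts control, a fixed rule instead of platform-dependent behaviour.
Reported rates: GR (overall accuracy), SS (patient accuracy), SC (control
accuracy). The whole procedure is deterministic given the feature table.

## Consensus networks

Because fold rankings differ slightly, the edges selected in *every* fold —
the consensus connections — are the stable core of the classifier.
`consensus()` reports, per consensus edge: mean $|\tau|$ across folds
(mean discriminative power), the direction of the group difference
(majority sign of $\tau$ across folds, `tied` on exact balance, with a
warning when any fold disagrees in sign), and a *normalized strength*,
a display quantity mapping the best mean rank to 1 and the worst to a
floor of $\varepsilon = 0.05$ by a linear min–max transform so that all
rendered strengths stay positive. Region weights are consensus degrees;
their sum is always twice the number of consensus edges.

## The synthetic cohort generator

No clinical data ship with the package; every stage is validated on
synthetic cohorts whose ground truth is known. Base signals are independent
Gaussian processes band-passed to 0.01–0.08 Hz (unit variance, 175
timepoints at TR = 2 s by default — the dimensions of a typical 6-minute
resting-state acquisition after volume discard; 32 + 32 subjects at full
scale). A coupling $(i \to j, s)$ replaces the target by
$\sqrt{1 - s^2}\, b_j + s\, f(z_i)$ with $f$ the identity (linear), the
centered square (quadratic), or $\sin(2 z)$ (sinusoidal), standardized;
the target keeps unit variance and a linear coupling yields
$\mathrm{cor} = s$ in expectation. The centered square of a symmetric
signal is uncorrelated with the signal, so quadratic couplings have
near-zero PCC by construction — they are visible to eMIC only, which is
precisely what a validation of the measure needs. Observation noise
(sd 0.1 by default, a small fraction of the unit signal variance) is added
last.

The `"paper-like"` preset encodes the qualitative clinical finding the
pipeline is meant to detect: 5 linear couplings that weaken from control to
patient (strength 0.6 → 0.3) and 5 quadratic couplings that strengthen
(0.2 → 0.6), on disjoint region pairs among the first 20 regions. Under
this preset, linear (PCC) connectivity drops in patients while non-linear
(eMIC) connectivity rises — so consensus PCC edges should come out
"decreased in patients" and consensus eMIC edges "increased", and each
measure should recover its own planted couplings at the top of the
ranking. The test suite checks both over 20 seeded replicates at a reduced
scale (20 regions, 16 + 16 subjects, selection size $k = 20$, about 10% of
the 190 edges — a slightly larger fraction than 200/6670, because small
edge counts need more headroom for sampling noise around the selection
boundary).

What the generator does *not* emulate: hemodynamic response functions
(couplings act in signal space; squaring a band-limited signal spreads some
power outside the band, which is why the spectral concentration property is
asserted on uncoupled signals), physiological noise, scanner drift beyond a
linear trend, spatial structure, or voxel-level data. Passing tests
therefore demonstrate that the pipeline recovers association structure of
the planted kind — not that it is robust to everything clinical data can
contain.

Seeding: one master seed; subject $i$'s stream is
`(seed + 7919 * i) mod (2^31 - 1)`, so enlarging a cohort never changes
existing subjects.

## Reproducibility and problem sizes

Every stage is deterministic given its inputs; `run_pipeline()` writes its
resolved configuration (and an FNV-1a hash of it) next to the outputs, logs
carry no wall-clock times, and all numeric output uses 17 significant
digits, so identical configurations reproduce byte-identical artifacts.
The test suite runs at deliberately reduced problem sizes — cohorts of
12–32 subjects with 10–20 regions, a few hundred Monte-Carlo draws where a
distributional property is asserted — chosen so the full suite completes in
a couple of minutes while leaving each check ample statistical margin.

## Known limitations

* The MIC value depends (slightly) on the search heuristic; different
  implementations can disagree at identical inputs. The exhaustive mode and
  the oracle bound that disagreement for small $n$, but at $n = 175$ the
  default clump budget is a calibrated approximation, not an exact maximum.
* eMIC inherits MIC's upward noise bias at small $n$: independent pairs at
  $n = 175$ have a MIC noise floor around 0.2–0.3, so raw eMIC values are
  comparable *between groups* but are not unbiased estimates of non-linear
  dependence.
* The group Kendall tau ignores within-group ordering by design; it cannot
  distinguish a location shift from any other stochastic-dominance pattern.
* LOOCV with fold-internal selection is unbiased for generalization but has
  high variance at these sample sizes; sweep curves over $k$ should be read
  as trends, not point estimates.
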