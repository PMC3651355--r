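---
title: "Pair-wise iterative rank-order normalization: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-wise iterative rank-order normalization: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironnorm)
```

## The problem

Two hybridizations of the same biological sample rarely produce the
same intensities: scanner gain, labeling efficiency and saturation
impose a smooth, usually nonlinear, response difference between chips.
Global methods that force whole distributions to agree (quantile
normalization, global median scaling) assume that differential
expression is symmetric — as much up as down.  When a large block of
features moves in one direction only (a third of the transcriptome
up-regulated is not unusual in spike-in designs or perturbation
experiments), that assumption actively corrupts the unchanged
features.

This package normalizes each sample chip *pair-wise* against one
common reference chip, training the correction only on features whose
rank order agrees between the two chips.  Because every chip is a pure
function of itself, the reference and the configuration, datasets can
grow incrementally without any previously produced value changing.

## The procedure

For a sample vector $Y$ and reference vector $X$ (linear intensities,
same feature order):

1. **Candidate selection.**  Features with no probeset assignment and
   masked features are dropped (when a layout is available), as are
   all features tied at either chip's minimum or maximum and features
   saturated above 64 000 (16-bit scanners) on either chip.
   Saturation is judged on raw, pre-background-subtraction values.
2. **Iterative rank-order pruning.**  Within the current set, both
   vectors are ranked (average ranks on ties) and each feature's rank
   difference is expressed as a percentage of the current set size,
   $\%\Delta_i = 100\,|r_X(i) - r_Y(i)|/n$.  If
   $\max_i \%\Delta_i \le 1\%$ the set has converged; otherwise every
   feature above $(\max_i \%\Delta_i - 0.5)$ is removed and the set is
   re-ranked.  The cutoff trails the current maximum rather than being
   fixed, which is what lets a 30–35% one-sided block of
   differentially expressed features be peeled away over many
   iterations without dragging concordant features out with it.
3. **Density weighting.**  With training points sorted by
   $A = \log_2(XY)$, a short sliding window (1% of the set) computes
   the standard deviation of the $A$ values it contains; each point's
   $\sigma_{avg}$ is the mean over all windows containing it and its
   fitting weight is $\sigma_{avg}^4$.  Sparse regions — chiefly high
   intensities — thus dominate their own windows instead of being
   averaged away by the dense bulk.
4. **Sliding-window weighted least squares.**  A window 10% of the
   set slides one point at a time over the $A$-sorted training set;
   each window contributes a weighted least-squares line of
   $M = \log_2(X/Y)$ on $A$.  A point's fitted log-ratio is the
   averaged slope and offset of every window containing it, evaluated
   at its own $A$.  This piece-wise averaged fit behaves like a LOESS
   smoother but is deterministic, cheap, and degrades gracefully
   (windows without $A$-variance or weight fall back to the weighted
   mean of $M$).
5. **Projection and curve construction.**  With
   $d_i = \hat M_i - M_i$, each training point is projected onto the
   fitted trend along the ratio axis:
   $x_{proj} = x + d/2$, $y_{proj} = y - d/2$, preserving its average
   intensity $A$.  Points landing on the same $y_{proj}$ are merged by
   averaging their corrections.
6. **Application.**  Every feature on the chip — including those
   excluded from training — receives the correction interpolated
   linearly over the curve's $y_{proj}$ grid; below or above the
   trained range, the mean correction of the first or last 10 curve
   points is used.  The corrected log intensity is exponentiated back
   to linear scale.

Out-of-range queries use a constant by construction, so the correction
has a small step at the range boundary whenever the boundary point's
own correction differs from the 10-point mean; we follow that
definition rather than smooth it, since extrapolating the fitted slope
into untrained territory is riskier than a visible constant.

### Surrounding pipeline

* **Background subtraction.**  Each chip is modeled as
  $O = B + S$ with $B \sim N(\mu, \sigma^2)$ and
  $S \sim \mathrm{Exp}(\alpha)$, and replaced by
  $E[S \mid O] = a + \sigma\,\phi(a/\sigma)/\Phi(a/\sigma)$ with
  $a = O - \mu - \sigma^2\alpha$ — strictly positive, strictly
  increasing, rank-preserving, and computed per chip with no
  information from other chips.
* **Reference selection.**  The chip minimizing the mean
  root-mean-squared distance of raw $\log_2$ intensities to all other
  chips (QC and unassigned probes excluded) is the reference: median
  brightness, minimal relative curvature.  Ties break to the
  lexicographically smallest sample ID.
* **Summarization.**  Probesets are condensed per sample by a
  one-step Tukey biweight of the $\log_2$ member intensities
  ($c = 5$, $\epsilon = 10^{-4}$, as in the classical single-chip
  signal algorithm), reported on the linear scale.
* **Second pass.**  After summarization, the probeset matrix receives
  one more round of pair-wise normalization against the reference's
  own summarized vector, with the layout-based exclusions disabled
  (probesets have no masks or memberships) but the min/max/saturation
  rules kept.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `convergence_pct` | 1 | % of set size | rank-invariance tolerance; larger keeps more features but admits mild differential expression into training |
| `prune_decrement_pct` | 0.5 | % | how far the cutoff trails the worst offender each iteration; smaller is slower and gentler |
| `window_frac_fit` | 0.10 | fraction | fit smoothness; smaller follows sharper curvature but amplifies noise |
| `window_frac_sigma` | 0.01 | fraction | scale on which density is measured |
| `weight_exponent` | 4 | – | strength of sparse-region up-weighting; small homogeneous training sets may prefer 1–2 |
| `saturation_threshold` | 64000 | linear intensity | 16-bit detector ceiling |
| `extrapolation_points` | 10 | points | how many terminal curve points define out-of-range corrections |
| `min_training_size` | 100 | points | below this a stable curve cannot be fitted; the fit aborts |

## Estimating the background model

The classical recipe initializes $\mu$ at the mode of a kernel density
estimate of the lower half of the data, $\sigma$ from the spread of
values below the mode, and $\alpha$ from the reciprocal mean excess
above it.  The mode of the normal–exponential convolution, however,
sits *above* the background mean by
$\sigma^2\alpha + \sigma z^\*$ where $\phi(z^\*)/\Phi(z^\*) =
\alpha\sigma$ — about 29 intensity units for
$\mu = 100, \sigma = 15, \alpha = 0.005$ — so the raw mode is a biased
estimate of $\mu$.  We therefore invert that relation analytically to
de-bias the initial $\mu$, then refine all three parameters by maximum
likelihood on the closed-form convolution density.  The refinement is
box-constrained around the initial estimates because the likelihood
has a degenerate ridge when one component vanishes (pure-normal data
would otherwise push $\alpha \to \infty$).  On simulated mixtures at
$n = 50{,}000$ this recovers $\mu$ to within a fraction of an
intensity unit and $\alpha$ to within ~1%.

## Numerical choices

* All log-space computation uses base 2 (`log_base`); corrections are
  ratios, so the base affects reported curves, not results.
* Non-positive intensities are replaced by the chip's smallest
  positive value before any log transform; real scanner exports
  contain zeros and the replacement is strictly per-chip.
* Ranks use average tie handling, symmetric in the two chips.
* Pruning removes all features above the cutoff in one pass and
  re-ranks; each iteration removes at least the current worst
  offender, so termination is guaranteed within the initial set size.
* Sliding windows advance by stride 1 and are truncated at the ends:
  terminal points belong to fewer windows, never to shrunken ones.
* Window sums use exact per-window summation for small problems and
  prefix sums for large ones, where the window population (thousands
  of points) makes the prefix-sum rounding negligible.
* The inverse Mills ratio is evaluated through `pnorm(log.p = TRUE)`
  so background correction stays finite arbitrarily far below the
  background mean.
* Degenerate fit windows (zero weight or zero $A$-variance) fall back
  to the weighted mean of $M$ with slope 0.
* The whole normalization path is deterministic; seeds exist only in
  the synthetic generator.

## What the synthetic generator emulates

`simulate_chip_set()` draws latent probeset expression once
(log-normal, `meanlog = log(500)`, `sdlog = 2` — roughly three decades
of dynamic range, as real arrays show), multiplies per-probe
log-normal affinities (`sdlog = 0.4`), adds an exponential signal
component (rate 0.005), and observes each chip through its own
strictly monotone distortion plus an independently drawn truncated
normal background ($\mu = 100, \sigma = 15$) and a small multiplicative
measurement noise (0.02 log2-sd, the level of a re-scan technical
replicate), clipped at 64 000.  A designated fraction of probes can be
shifted uniformly upward on chosen chips to emulate asymmetric
differential expression.

Two constructions are used in testing:

* **Independent chips** share the latent signal but draw background
  and noise independently — the right setting for reference selection,
  summarization and pipeline plumbing.  Note that independent additive
  background draws place a floor of roughly 0.02–0.03 on the median
  absolute log2 ratio between two chips at this signal-to-background
  ratio; no normalization can remove noise that is independent per
  chip, so recovery there is measured against that floor.
* **Warped replicates** (`warp_chip()`) pass one observed chip through
  a distortion plus measurement noise — the direct analogue of
  re-scanning the same hybridization under a different response curve,
  and the setting in which distortion recovery can be measured
  cleanly.  The distortion-recovery and asymmetry studies use this
  construction.

What passing these tests does *not* show about real data: the
generator has no probe-sequence effects (GC content), no spatial
artifacts, no batch structure, and its distortions are smooth and
strictly monotone.  Chips whose response curves cross or fold cannot
be corrected by any monotone intensity map.

## Problem sizes and study conditions

The packaged studies use 20 000-probe chips (4 000 probesets of 5) for
the recovery and asymmetry scenarios, 50 000 probes by 20 chips for
the full-pipeline throughput exercise (which completes in about a
minute), 100 random instances for pruning-termination properties, and
$n = 50{,}000$ draws over 10 seeds for background parameter recovery.
The asymmetry study places 34% of probes in a +1 to +3 log2 arm, the
fraction at which symmetric methods break down visibly; the global
median-scaling comparator fails its error bound on exactly the data
where the rank-order training set stays clean.

## Design choices where the design was open

* **Aggregate for reference selection** — the mean of pair-wise RMSDs
  (mean and sum have the same argmin).
* **Distances on raw intensities** — reference choice should not
  depend on a tunable correction step.
* **"Undefined" probes** — read as probes with no probeset assignment;
  they are excluded from distances and training when a layout exists,
  retained otherwise (the generic, layout-free pipeline).
* **Cutoff floor** — the pruning cutoff is *not* clamped at the
  convergence threshold; the loop exits only through the ≤ 1% test.
* **Extreme-value exclusion** — all features attaining a chip's
  minimum or maximum are excluded, not just one representative.
* **$\sigma$ in density weighting** — the deviation of $A$ values
  within the window (its stated purpose is density adjustment, and
  $A$ is the axis on which density varies), not of $M$ values.
* **Probeset-level pass** — normalizes against the reference chip's
  own summarized vector; with one reference there is no other natural
  choice.
* **Linear-space background correction** — the conditional-expectation
  formula operates on linear intensities (the distributions are
  conveniently *visualized* in log space, but the convolution model is
  additive and linear).
* **Probeset output scale** — linear by default with a `log2_output`
  switch.

## Known limitations

* A single reference chip anchors the whole dataset; a pathological
  reference (chosen manually) propagates its quirks to every sample.
  `find_median_chip()` exists precisely to avoid this.
* Corrections outside the trained intensity range are constant; chips
  whose range extends far beyond the reference's are extrapolated
  coarsely.
* The rank-invariant training assumption fails if *most* features are
  differentially expressed in one direction; the iterative pruning is
  robust to ~35% one-sided arms, not to 80%.
* Tukey-biweight summarization needs several probes per probeset to
  down-weight outliers; with 1–2 probes it reduces to (nearly) the
  mean.
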