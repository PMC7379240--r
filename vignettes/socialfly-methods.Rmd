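---
title: "Methods: quantifying social feeding behavior and comparative expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying social feeding behavior and comparative expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialfly)
```

This vignette is the package's own account of its models and the choices
behind them: what each statistic assumes, which parameters matter, what
the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The imaging model

Frames are grayscale images of a chamber filmed from above: fly bodies are
dark, the background light, and the food dish is a known circle. The
conventions used everywhere are: pixel-centered 0-based coordinates, x
rightward, y downward, lengths in pixels, times in minutes.

`detect_flies()` applies a global intensity threshold (fixed by
configuration, or chosen automatically by the inter-class-variance
criterion), labels connected dark components, and summarizes each
component by its equivalent ellipse: centroid = pixel mean, full axis
lengths = $4\sqrt{\lambda_i}$ for the eigenvalues $\lambda_i$ of the
$2 \times 2$ central second-moment matrix, orientation = principal
eigenvector angle reported modulo $\pi$ (a fly's head and tail are not
distinguished). For a uniformly filled ellipse this recovers the true
axes; for a filled $w \times h$ rectangle it gives $2w/\sqrt{3}$, the
closed forms the test suite checks against at sizes of 15 px and up,
where rasterization error is below 2%.

A fixed global threshold is appropriate because chamber videos are scaled
and lit uniformly; the automatic mode exists mainly so synthetic tests
need no tuning. Area bounds are expressed relative to the expected body
area (debris below 25%, merge above 180%): components above the merge
bound — touching flies — are emitted once with `merged_flag = TRUE`
rather than split, because nothing downstream requires resolving
occlusions and any splitting heuristic would inject assumptions the data
cannot check. Degenerate components (single pixel, collinear) have their
axes floored at 1 px so body-size normalization never ingests a zero.

Paint marks are detected by color thresholding: pixels within a Euclidean
RGB tolerance of a reference color form groups, and the largest group per
label wins, giving at most one position per label per frame. The default
tolerance is 0.15: tight enough that a light gray background (intensity
0.85–0.9, distance ≈ 0.17–0.26 from pure white) is not confused with the
white paint used for control flies, loose enough to tolerate mild pixel
noise.

## Behavioral statistics

**Windowed counts.** On-food and near-food counts are averaged over a
10-s window at every 45-s stride (both configurable). ROI membership uses
closed boundaries; the proximal radius defaults to 1.5× the on-food
radius, a configuration choice since "proximal" has no canonical value.
A stride whose window contains no frames yields a missing record, never a
zero — absence of frames is not absence of flies.

**T-40** is the first *sampled* time at which the on-food count meets the
closed threshold $n_{on} \ge 0.4 \cdot N$. No interpolation: the sampling
stride is much finer than any effect of interest, and interpolation would
manufacture precision. A series that never reaches 40% has an undefined
T-40, which is a legal outcome (poorly aggregating groups), and such
densities are excluded from the cooperativity regression.

**The cooperativity coefficient** is the OLS slope of T-40 on chamber
density, in min/fly. With exactly two densities the fit is a line through
both points and $R^2 = 1$ by construction; with a constant response the
slope is exactly 0 and $R^2$ is reported as 0 (there is no variance to
explain — the numerically unstable 0/0 from the general formula is
handled explicitly).

**Social space** is computed per frame in three steps: nearest neighbor
for every fly by center-to-center distance; mutual nearest-neighbor pairs
contribute their shared distance *once*; the mean of the resulting values
is then reduced by the frame's mean pooled body extent (the mean over all
fitted major *and* minor axes). The subtraction converts a
center-to-center distance into an approximately edge-to-edge one, making
the statistic independent of body size — the suite verifies that doubling
all body axes at fixed gaps moves the normalized value by under 5%.
Coincident flies legally give zero or negative normalized values. Because
social space shrinks as flies crowd the food, interspecies comparisons
are made within density bins: half-open bins of 10 flies anchored at 5
(so a 25-fly frame belongs to bin 25, not 15), with a convenience
selector for the 15–25-fly band. Density here means flies *detected in
the frame*, not flies loaded in the chamber.

**Z-score positioning** deliberately uses a different distribution from
social space: for each sampled frame (every 40 s, independently of the
45-s count stride), the per-fly nearest-neighbor distances of *all* flies
— without mutual-pair deduplication, since this is a per-fly
distribution, not a frame mean — give the frame's mean and SD, and the
focal painted fly's distance becomes
$z = (d_{painted} - \bar d)/s$. The SD uses the population ($n$)
denominator by default (the frame *is* the population of interest;
switchable to $n-1$). Frames with fewer than 3 flies or zero spread are
skipped and counted. For an exchangeable (unremarkable) focal fly the
z-distribution is centered at zero, which is the calibration the tests
enforce over 250 independently generated frames.

One subtlety the null-calibration tests respect: in the synthetic
generator the *first-placed* fly is structurally central (its nearest
neighbor sits exactly at the placement target), so a truly exchangeable
focal fly must be chosen uniformly at random among ids, not always id 1.

**Group comparisons** use the two-sided Mann–Whitney/Wilcoxon rank-sum
test. For combined samples up to 20 the null distribution of U is
enumerated exactly over all group assignments of the midranks — valid
under ties, where the textbook exact distribution is not — and the
two-sided p doubles the smaller tail, capped at 1. Larger samples use the
normal approximation with tie-corrected variance and no continuity
correction (checked against `wilcox.test(correct = FALSE)`).

## The cooperative search simulator

The simulator is a minimal agent-based model of food search: agents
perform a correlated random walk in bouts (draw an exponential bout
length, walk straight, turn), inside a closed arena with reflecting
walls and a circular food patch. The food exerts an attractiveness

$$A = \mathrm{clamp}\!\left(a_0\, e^{-d/\lambda}\,
      \bigl(1 + c \cdot \min(n_{on}, n_{sat})\bigr),\ 0,\ 1\right)$$

which does two things at each turn: it shrinks the turning noise (SD
$\sigma_{turn}(1-A)$) and steers the new heading toward the food by a
circular blend with weight $A$. With cooperativity $c > 0$ the patch
becomes more attractive as flies accumulate, up to a saturation count
$n_{sat}$ beyond which additional flies add nothing — the clamp is exact,
so counts at $n_{sat}$ and $2 n_{sat}$ give identical attractiveness.
Arrived agents are frozen on the food by default (sticky), so occupancy
is non-decreasing. Time is unitless ticks; T-40 is the first tick with
at least 40% of agents arrived.

Parameter defaults (arena 400 × 400, food radius 25, $a_0 = 0.25$,
$\lambda = 120$, $c = 0.4$, $n_{sat} = 12$, step 3, bout mean 8, turn SD
2 rad, 3000 ticks) were chosen once to reproduce the qualitative contrast
that motivates the model: with cooperativity on, mean T-40 declines
steadily over densities 25–200; with $c = 0$ it is flat. The bout length
and turning SD matter more than they look: a highly persistent walk
produces a strongly right-skewed arrival-time distribution whose
empirical 40%-quantile carries a small density-dependent finite-sample
bias, which can masquerade as a trend in the diffusive control. The
shorter, less persistent default walk keeps that bias negligible relative
to between-replicate noise. This is a property of T-40 as an
order-statistic, worth knowing when interpreting shallow slopes.

Every functional form (exponential proximity kernel, linear-then-clamped
social term, exponential bouts, reflecting walls, sticky food) is a
modeling choice exposed through `sim_params()`; none is claimed to match
any particular prior implementation — only the qualitative
density-dependence contrasts are treated as reproduction targets.

## The comparative-transcriptome stage

**TPM.** Each sample column is rescaled by $10^6 / \sum_g x_g$; the
invariant (every column sums to one million within $10^{-6}$ relative)
is asserted in tests. A zero-sum column is an error naming the sample.

**Ortholog joining.** The map is keyed by reference-species gene ids with
at most one assignment per (gene, species). Cross-species operations use
complete cases: a gene lacking an assignment in *any* required species is
dropped for those operations, regardless of how significant it looks
elsewhere.

**Clustering.** Species are clustered on $d = 1 - \rho$ where $\rho$ is
the Spearman rank correlation of per-species mean expression (means over
replicates by default; a concatenated-replicates mode exists for equal
replicate counts). Rank correlation makes the result invariant to gene
order and to any monotone transform of expression. The linkage is
`ward.D` — the classic (legacy) Ward update applied to the dissimilarity
matrix as provided — with `ward.D2` switchable; ties in ranks use average
ranks. A constant expression profile makes correlation undefined and is
an error naming the species. Pairwise least-squares $R^2$ of the mean
profiles is returned alongside for heatmap display.

**Consensus DE.** A gene is called relative to a species set only when
padj ≤ α (default 0.05) in *every* pairwise comparison *and* an ortholog
exists in every set member. The call is monotone in α by construction.
Direction is the sign of the log2 fold change; cross-pair direction
conflicts are flagged rather than dropped, since dropping would silently
bias the set toward consistent genes. The DE test itself is out of scope:
adjusted p-values are inputs. A gene tested in some pairs but missing its
padj in others despite full ortholog coverage indicates corrupted input
and is an error, not a silent exclusion.

**Overlap permutation.** The null draws $|A|$ genes uniformly without
replacement from the universe and counts the overlap with $B$, 10,000
times by default; $p = (1 + \#\{null \ge obs\})/(n_{perm} + 1)$. The
add-one estimator never returns exactly zero — an overlap beyond every
draw is a bound, not a zero — and the estimator is held to the exact
hypergeometric tail within Monte-Carlo error in tests. Which universe to
draw from (full ortholog list vs pairwise complete cases) is not
canonical; it is an explicit argument.

## What the synthetic generator emulates — and what it does not

`gen_scene()` places elliptical bodies at a target mean nearest-neighbor
*gap* (centers at gap + mean pooled extent, the same quantity the
social-space normalization subtracts), optionally confined to the food
circle, and records per-frame brute-force bookkeeping (NN distances,
on-food counts, mutual-pair social space) for parameter recovery.
`render_frames()` draws flies as uniformly filled ellipses with optional
Gaussian pixel noise and 5-px paint disks. `gen_aggregation_series()`
produces arrivals with per-capita hazard
$r (1 + n_{on})^{\gamma}$ — the minimal process whose $\gamma$
knob produces the cooperativity the metrics must detect — with per-fly
uniforms fixed by the seed so that raising $\gamma$ accelerates arrivals
*pathwise*, making ordered comparisons exact. `gen_expression()` builds
log-normal expression with a planted block structure
($\sqrt{\rho}\, z_{block} + \sqrt{1-\rho}\, z_{species}$), planted DE
sets with a controllable shared pool, and an ortholog map with
configurable dropout.

Passing tests on these data shows the *machinery* is correct: that
detection recovers known poses, that the statistics equal their
brute-force definitions, that estimators recover planted parameters. It
does not show robustness to what real videos contain — motion blur,
uneven lighting, wing postures, partial occlusions beyond simple merges,
tracking identity errors — nor to the mean-variance structure of real
RNA-seq counts. Conclusions about real data still require the usual
visual spot checks.

All generators are pure functions of their arguments including the seed;
the full pipeline from one configuration (`run_pipeline()`) writes
provenance-stamped TSVs (tool version + configuration hash, no
timestamps) and is byte-identical across reruns.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen to exercise every code path
with comfortable statistical margins: 1,000 random frames (2–50 flies)
for the social-space oracle, 100 rendered scenes for detection
recall/precision, 100 seeds for clustering recovery, 250 frames for
Z-score calibration, a 25–200 × 20-replicate simulation sweep, and
10,000-draw permutation tests on universes of up to 50 genes. Nearest-
neighbor ties are broken by first index (ties affect pair identity, never
the distance value); the mutual-pair rule is applied per unordered pair.
Floats serialize at 6 significant digits in TSVs by default, with a
full-precision option where byte-stable round trips matter.

## Known limitations

- No multi-frame identity tracking of unpainted flies; lunges are scored
  externally and ingested as counts.
- Merged components are flagged, not split, so per-fly statistics
  undercount flies in heavy crowding; frames where this matters should be
  filtered on `merged_flag`.
- The simulator's forms are minimal by intent; its T-40 values are in
  model ticks and only density *contrasts* are meaningful.
- The expression generator's replicate noise is log-normal and
  homoscedastic on the log scale, which is simpler than real RNA-seq
  count noise; it suffices for rank-based clustering and set-overlap
  machinery but not for benchmarking DE tests (which are out of scope).
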