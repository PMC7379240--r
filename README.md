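# socialfly

Quantitative tools for comparative studies of *Drosophila* social feeding
behavior, with a matched synthetic-data generator and an
agent-based cooperative food-search simulator.

When groups of flies are filmed from above in a chamber containing a
circular food dish, a handful of statistics capture most of what differs
between species and rearing conditions:

- **Aggregation kinetics** — the number of flies on (and proximal to) the
  food, counted for every frame over a 10-second window and averaged at
  each 45-second increment.
- **T-40** — the first sampled time at which at least 40% of the flies in
  the chamber are on the food; undefined when the group never reaches 40%.
- **Cooperativity coefficient** — the OLS slope of T-40 on fly density
  (min/fly). A negative slope means denser groups find food *faster*,
  cooperativity in the binding-kinetics sense; zero is the
  density-independent signature.
- **Social space** — per frame, each fly is an ellipse fitted from the
  second-order moments of its pixel set; the statistic is the mean minimum
  nearest-neighbor center distance, with mutual nearest-neighbor pairs
  counted once, minus the frame's mean pooled major/minor axis length
  (body-size normalization: center-to-center becomes edge-to-edge,
  independent of fly size).
- **Z-score positioning** — a paint-marked fly's nearest-neighbor distance
  expressed in SDs from the frame-wide nearest-neighbor distribution,
  sampled every 40 s; the distribution over frames shows whether a focal
  fly sits tighter or looser than its group.
- **Aggression regression** — per-condition OLS of lunge counts (first
  150 s after arrival) on the fly density at arrival, with Wilcoxon
  rank-sum comparisons between rearing conditions.

The comparative-transcriptome stage covers the expression side of such
studies: RPKM → TPM renormalization (every sample rescaled to sum to one
million), ortholog-joined cross-species matrices with the
missing-ortholog exclusion rule, Spearman/Ward clustering of species by
global expression, consensus differential-expression calls (padj ≤ 0.05
in *every* pairwise comparison), and a 10,000-draw permutation test for
the overlap of DE gene sets against the hypergeometric null.

Because raw videos and sequencing reads are not needed to validate any of
this machinery, the package ships a first-class synthetic-data generator:
chamber frames with ground-truth fly poses (dark ellipses, colored paint
marks, controllable clustering and spacing), stochastic aggregation series
with a tunable cooperativity exponent, and multi-species orthologous
expression matrices with planted correlation blocks and planted DE sets.
Every quantity a downstream stage estimates is recomputed inside the
generator by brute force and stored for parameter-recovery tests.

## Worked example

```r
library(socialfly)

## a synthetic chamber: 10 flies at a planted 30 px edge-to-edge spacing,
## half of them clustered on the food dish
ar  <- arena_spec(500, 500, food_radius = 80)
sc  <- gen_scene(ar, n_flies = 10, spacing_px = 30, clustering = 0.5,
                 seed = 1, body_major = 24, body_minor = 10)
r   <- render_frames(sc)
roi <- food_roi(ar$food_center, ar$food_radius)
det <- detect_flies(r$images[[1]], threshold = 0.5,
                    expected_body_area_px = pi * 24 * 10 / 4, roi = roi)
social_space(det)
#> # A tibble: 1 × 5
#>   raw_px normalized_px mean_body_extent_px n_flies frame_index
#>    <dbl>         <dbl>               <dbl>   <int>       <int>
#> 1   47.0          30.0                17.0      10           1
```

The detected flies' mean nearest-neighbor distance is 47.0 px between
centers; subtracting the frame's mean pooled axis length (17.0 px)
recovers the planted 30 px edge-to-edge social space.

```r
## T-40 across densities and the cooperativity coefficient
t40s <- sapply(c(25, 50, 75, 100), function(d) {
  t40(gen_aggregation_series(d, rate_per_min = 0.004, coop_exponent = 1,
                             t_end_min = 180, seed = d))$t40_min
})
fit <- cooperativity_coefficient(
  data.frame(density = c(25, 50, 75, 100), t40_min = t40s))
glance(fit)
#> # A tibble: 1 × 4
#>    slope intercept r_squared n_densities
#>    <dbl>     <dbl>     <dbl>       <int>
#> 1 -0.744      74.3     0.756           4
```

The negative slope (−0.74 min/fly) is the cooperative signature: the
generator's arrival hazard scales with the on-food count, so denser
chambers reach the 40% threshold sooner. `autoplot(fit)` draws the
regression; `run_simulation()` / `density_sweep()` reproduce the same
contrast in the mechanistic agent-based model, and `run_pipeline()`
executes every stage from one configuration into provenance-stamped TSVs.

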