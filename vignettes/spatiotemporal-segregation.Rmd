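---
title: "Mapping significant land-cover change with a spatio-temporal segregation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping significant land-cover change with a spatio-temporal segregation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dixonscan)
```

## The problem

Classical land-cover change analysis intersects two classified maps and
tabulates a transition matrix. That answers *how much* changed but not
*where the change is statistically distinguishable from noise*, nor how
intense it is locally. `dixonscan` addresses this by extending Dixon's
nearest-neighbour segregation index — originally a global, purely spatial
statistic for two-class point patterns — to the temporal domain and to a
local, moving-window estimator, so that every grid cell receives an index
value, a Monte Carlo significance and an uncertainty score.

The temporal extension rests on one idea: the "nearest neighbour" of a cell
at the first date is the *same cell at the second date*. A two-date binary
map (target class vs everything else) then yields, inside any neighbourhood,
a 2×2 space–time contingency table

|                | t2 target | t2 other | total |
|----------------|-----------|----------|-------|
| **t1 target**  | `Naa`     | `Nab`    |       |
| **t1 other**   | `Nba`     | `Nbb`    |       |

with label totals taken over *both* dates: `Na = 2 Naa + Nab + Nba`,
`Nb = 2 Nbb + Nab + Nba`, `N = Na + Nb = 2 m` for `m` cells. (The totals
over both dates — rather than single-date row sums — are what make
`(Na − 1)/Nb` the correct odds that a randomly labelled neighbour of a
target point is itself target; the single-date row totals are kept in the
table object for reporting.)

## The index and its test

The segregation index for the target class is the log odds ratio

$$
S_{aa} \;=\; \ln\!\left(\frac{N_{aa}/N_{ab}}{(N_a-1)/N_b}\right),
$$

the observed odds of target persistence against the odds expected when all
`N = 2m` space–time labels in the window are assigned by uniform random
permutation (random labelling, with the cell-to-cell temporal pairing held
fixed). `Saa > 0` means segregation — the target class persists or expands
beyond random expectation; `Saa < 0` means association — erosion of the
target class; `Saa ≈ 0` is compatible with random labelling.

Significance uses the standardized persistence counts
`z_aa = (Naa − E(Naa))/sd(Naa)` and `z_bb` analogously, combined into a
chi-square-type statistic

$$
C \;=\; \frac{z_{aa}^2 + z_{bb}^2 - 2 r\, z_{aa} z_{bb}}{1 - r^2},
$$

where `r` is the null correlation of `Naa` and `Nbb`. All moments are
estimated from the same Monte Carlo null ensemble, and all p-values are
add-one permutation p-values, `p = (1 + #{sim ≥ obs})/(1 + nsim)`; the C
test is upper-tailed, z tests are two-sided through the replicate
distribution of `|z|`.

### A degeneracy, and how `C` is computed

Under the within-window permutation null the margins are fixed, and the
identity `Nbb = Naa + m − Na` holds in every replicate (it follows from the
table closing to `m` cells). `Naa` and `Nbb` are therefore *perfectly*
correlated: `r = 1`, and the textbook formula for `C` is 0/0. `dixonscan`
computes `C` as the generalized-inverse quadratic form obtained from the
eigendecomposition of the correlation matrix,

$$
C \;=\; \frac{(z_{aa}+z_{bb})^2}{2(1+r)} \;+\; \frac{(z_{aa}-z_{bb})^2}{2(1-r)},
$$

dropping a term when its eigenvalue is numerically zero. For `|r| < 1` this
is algebraically identical to the formula above; at `r = 1` it degrades
continuously to `C = z_aa²` (a 1-df rather than 2-df quadratic form). Because
the p-value is Monte Carlo — observed and replicate `C` are computed by the
same rule — the test remains exact either way, and the machinery stays
correct for any null scheme in which `|r| < 1`.

### The null ensemble

`null_ensemble()` realizes the uniform permutation of the `2m` window labels
through its exact combinatorial law: given the margins, the whole table is
determined by `Naa` and the orientation of the discordant cells, with

$$
P(N_{aa}=k) \propto \binom{m}{k}\binom{m-k}{N_a-2k} 2^{\,N_a-2k},
\qquad
N_{ab}\mid N_{aa} \sim \mathrm{Binomial}\!\left(N_a-2N_{aa},\ \tfrac12\right).
$$

Sampling from this law is distributionally identical to shuffling label
vectors but costs O(nsim) per window instead of O(nsim·m). The test suite
verifies the law against exhaustive enumeration of all
$\binom{2m}{N_a}$ labellings for small windows, including the closed form
`E(Naa) = m·Na(Na−1)/(N(N−1))`.

## Edge correction

Following the windowed design, a window whose counts are too small to carry
the index (`Naa ≤ 4` or `Nab ≤ 4`) is enlarged one cell ring at a time until
both counts exceed 4 or the window covers the whole map; a cell for which
the condition is unreachable (e.g. a map with no loss anywhere) is labelled
`undefined` and excluded from significance counts, with its count reported.
The correction is pure enlargement; no distance weights are applied (a
weighting scheme would slot into the window-counting step, but none is
defined here). Two consequences are worth knowing:

* at 50 m resolution a 100 m (3×3) window can never satisfy the condition —
  it needs at least 10 cells — so a requested `d = 100` m is always analyzed
  at an effective 250 m or more; candidates 100 m and 250 m therefore
  produce identical maps, which is why `select_window()` breaks count ties
  by the *least mean enlargement* (the window actually used) before falling
  back to the smaller candidate;
* under the null, windows with small observed `Naa` are preferentially
  enlarged, which removes part of the lower (association-side) rejection
  region and makes the cell-level test conservative at small windows (see
  *Calibration* below).

## Calibration of the local test

The per-cell statistic is an integer count in a 25–50-cell window, so its
permutation distribution is discrete: the attainable two-sided size at
`alpha = 0.05` is below nominal, and the edge-correction censoring pushes it
further down. On random-labelling landscapes the measured rejection rate at
the 250 m window is about 0.03 (see the calibration check recomputed by
`scripts/acceptance.R`); it approaches the nominal 0.05 as windows grow.
The test is conservative, never anti-conservative, at the default settings.

Two practical notes follow. First, neighbouring cells share almost all of
their windows, so significant cells arrive in spatial clumps; the *fraction*
of significant cells on one map has an effective sample size of roughly
`n / window cells`, not `n`. Calibration experiments should therefore use
spatially thinned cells with disjoint windows (the `at` argument of
`local_dixon_map()`), which is how the package's own calibration check is
run. Second, no multiple-testing correction is applied across cells — the
test is local at `alpha = 0.05`, and maps should be read accordingly.

## Window-size selection

`select_window()` repeats the analysis over a candidate ladder (the study
ladder 100/250/500/1000/1500 m by default) and returns the candidate with
the most cells significant at `alpha`. A caveat this package documents
explicitly: under the within-window permutation null, *any* space–time
structure — including spatial clustering of the first-date map alone —
registers as significant once the window is large enough to span it, and
the catchment of a change patch grows with the window area. On landscapes
whose structure extends beyond the window scale, the raw significant-cell
count therefore tends to increase with `d` rather than peak at the patch
scale. The `changed_only` flag restricts counting to cells that changed
between the dates, which focuses the criterion on change rather than
standing structure; the count-tie rule above handles the 100/250 m
degeneracy. When candidates tie in substance, prefer the smallest window
that needed no systematic enlargement — it is the most local statement of
the evidence.

## Uncertainty

The uncertainty score of a cell is the width of the central 95% interval of
the replicate `Saa` values in its null ensemble, standardized by the
maximum width over all analyzed cells, so the most uncertain cell of a map
scores 1. The interval is taken from the null ensemble (rather than from a
resampling distribution centred on the observed table): it measures how
tightly the randomization pins down the index in that window — small, pure
or data-poor windows yield wide, unstable intervals. Non-finite replicate
values (a replicate with `Naa = 0` or `Nab = 0`) are excluded from the
quantiles.

## The synthetic generator

`gen_null_pair()` draws every space–time label independently with
probability `p_target` — exactly the random-labelling null, used for
calibration. `gen_patch_change_pair()` builds the first date as a
box-smoothed Gaussian field thresholded to the target fraction (smoothing
keeps windows mixed, which the edge-correction condition needs), optionally
forces stated regions to target, copies it to the second date, and then
applies circular conversion patches (loss or gain) with a stated per-cell
conversion probability; map-wide "patches" with complementary loss/gain
rates (`1 − p` and `p`) turn the background into an exact random-labelling
pair, which is how the detection fixtures isolate a patch signal on a
calibrated background.

Defaults mirror a 50 m raster of a ~100 km² Mediterranean forest landscape:
200×200 cells, `p_target = 0.45` (a realistic cover fraction for a
forest-dominated study region), smoothing radius 4 cells. What the
generator does *not* emulate: classification error, polygon-to-raster
boundary effects, autocorrelated conversion risk, and multi-class dynamics
— passing tests on these landscapes show the statistical machinery behaves
as designed, not that any particular real map is free of those effects.

## Numerical and design choices

* Natural logarithm throughout; `Saa` is a log odds ratio.
* `d` is the full side of the square window: 250 m → 5×5 cells at 50 m.
  Cell centres on the window boundary are included.
* Cells are centre-registered; cell (1,1) is the map's upper-left; areas are
  `cells × resolution² / 10⁴` hectares.
* Per-cell random streams are derived from the master seed and the cell's
  index, so results are identical across visiting orders and worker counts,
  and any single cell can be reproduced in isolation (`dixon_local()` with
  the recorded `cell_seed`).
* Degenerate windows (zero null variance, or index undefined after maximal
  enlargement) propagate as the `undefined` label rather than errors.
* The number of points sharing a nearest neighbour (the `Q` of the analytic
  variance formulas in the spatial literature) does not appear: the temporal
  pairing fixes the neighbour graph to a perfect matching, and all moments
  come from the Monte Carlo/enumeration law of that matching.
* Raster I/O is plain-text ESRI ASCII grid; categorical bands must be
  integer-valued. Inputs must share one coordinate system and lattice;
  reprojection is out of scope.

## Problem sizes used by the test suite

The suite runs windows up to 21×21 cells on landscapes up to 360×360 cells,
with 99–999 Monte Carlo replicates per cell and 4000-replicate ensembles
against exhaustive enumeration for windows of up to four cells; the
calibration check uses 2025 disjoint windows. These sizes exercise every
code path at full fidelity; study-scale runs (~40 000 cells, nsim = 5000)
use the same code with `workers > 1` if desired.

## Limitations

* Two dates only; multi-temporal sequences need repeated pairwise runs.
* Binary class contrast (target vs rest), as the method defines it; run the
  analysis once per class of interest.
* The within-window random-labelling null conditions on the window's own
  margins. It is sensitive to any local space–time structure, which is the
  point of a local statistic, but it cannot separate "the first-date map is
  clustered here" from "change clustered here" — interpretation should lean
  on the classification (segregation vs association) and on the transition
  matrix.
* Monte Carlo p-values are granular at `1/(nsim+1)` and the local test is
  conservative at small windows, as quantified above.
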