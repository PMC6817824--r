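---
title: "Measuring slime-mold exploration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring slime-mold exploration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

slimeTrace quantifies the exploration behavior of a *Physarum polycephalum*
plasmodium from time-lapse photographs of a circular arena. This vignette
is the package's own account of the method: the model behind each stage,
the parameters that matter, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open.

## The three-state pixel model

The central object is a per-pixel, per-frame label in {SLIME, MUCUS,
UNEXPLORED}. The biological rationale: the plasmodium secretes an
extracellular slime layer wherever it has been, so the substrate itself
records history. The model's one hard rule is that history is
irreversible — once a pixel has carried slime (and therefore mucus after a
withdrawal), it can never be unexplored again. All downstream quantities
are defined on transitions of this label field:

* primary growth: UNEXPLORED → SLIME;
* secondary growth: MUCUS → SLIME;
* refinement: SLIME → MUCUS.

Per interval these satisfy, exactly and by construction,
`Δslime = primary + secondary − refinement` (a pixel-counting identity the
test suite asserts at tolerance 1e-12). We count the inoculated disc as
primary coverage already present at time zero, so cumulative primary growth
equals the explored (slime-or-mucus) fraction at every frame and is bounded
by the arena area; cumulative secondary growth is unbounded and measures
the cyclic, pulsatile component of exploration.

## Segmentation

Frames are converted to the ab\* chromatic plane — CIELAB (sRGB, D65)
with the lightness channel discarded. Dropping L\* removes most of the
effect of uneven illumination across a photographed dish: two pixels that
differ only in brightness coincide in ab\*.

Each frame is then binarized independently by two-cluster k-means over the
in-arena ab\* values. Two details are deliberate:

* **Cluster identity.** k-means labels clusters arbitrarily, so the slime
  cluster is the one whose centroid is nearer (Euclidean in ab\*) to the
  mean ab\* of the known initial slime disc in frame 1. This makes the
  output invariant to cluster permutation and hence to the k-means seed
  (asserted in tests by running with two seeds).
* **Per-frame fits.** The clustering could be fit once globally instead;
  per-frame fitting was chosen because it tolerates slow color drift over a
  35-hour recording and matches a frame-by-frame processing model. Nothing
  downstream depends on centroids being comparable across frames.

The raw mask is cleaned by removing 8-connected foreground components and
filling enclosed holes smaller than `min_blob_frac` (default 1e-4) of the
arena area. The threshold is deliberately tiny: its purpose is stability of
the erosion-based pseudopod count against single-pixel speckle, not
denoising. Degenerate frames — chromatic range below 0.5 ab\* units, or
k-means centroids closer than 1 ab\* unit — raise a "no chromatic
contrast" error rather than returning an arbitrary mask.

Trinarization then walks the mask sequence with one bit of state per pixel
(ever occupied), emitting MUCUS for currently-empty-but-visited pixels.
Legal-transition checking is fuzz-tested over random mask sequences and
over full synthetic pipelines.

## Growth, migration, and the secondary-growth bias

Distances are computed with an exact Euclidean distance transform between
pixel centers and reported in millimetres via the arena scale
(`mm_per_px = arena_diameter_mm / (2 · radius_px)`; the arena circle itself
is supplied by configuration, mirroring manual dish masking — an automatic
circle-detection helper exists but is never the default).

* **Extent of growth**: for every primary- or secondary-growth pixel, the
  distance to the nearest previous-frame slime pixel.
* **Migration rate**: maximum extent / sampling interval (mm/min); 0 when
  nothing grew. We use the maximum over growth pixels rather than a
  contour-to-contour construction: the two coincide for pure outward
  growth, and the pixel definition remains well defined under retraction
  and fragmentation.
* **Expansion region**: non-slime arena pixels within the interval's
  maximum extent of the previous slime set — the area the cell could have
  reached. The *expected* secondary-growth fraction is the mucus share of
  this region; the *observed* fraction is secondary/(secondary+primary).
  Both are undefined (NA) for degenerate intervals with empty denominators;
  a pooled version over a sliding window (default 60 min) is provided for
  plotting because single 5-min intervals are frequently degenerate.

## Shape indices

* **Circularity** C = P²/(4πA). The perimeter estimator is the total
  length of the 0.5-level marching-squares iso-contours of the mask after
  Gaussian pre-smoothing with σ = 1 px. Raw marching squares on a hard 0/1
  raster systematically overestimates curved contours by ~6%, which would
  put a perfect disc at C ≈ 1.12; σ = 1 px brings a rasterized disc to
  within 1% of C = 1, a square to within 2% of 4/π, and two disjoint discs
  to within 2% of C = 2 (all asserted in tests). σ is exposed as
  `smoothSigma` for masks at unusual scales.
* **Eccentricity** E = √(1 − (b/a)²) from the ellipse with the same second
  central moments as the full foreground pixel set; each pixel contributes
  its unit-square extent (+1/12 to the diagonal), which keeps moments
  positive for thin masks and makes a single pixel E = 0 by convention.
  Multi-component masks use the union of components, consistent with the
  pseudopod count coexisting with a single shape measure.
* **Solidity** = pixel count / pixel count of the rasterized convex hull of
  the foreground. Rasterizing the hull with the same pixel-center rule as
  the mask cancels the sub-pixel hull bias, so convex masks score 1 up to
  chord effects (a corner-polygon hull would be biased by ~0.7/r for a
  radius-r disc).
* **Pseudopod count**: 8-connected components remaining after an exact
  Euclidean erosion (distance-transform threshold, matching a brute-force
  disc erosion pixel for pixel). The erosion radius is unspecified in the
  underlying method description; the default is 2% of the arena radius,
  configurable. Radius 0 degrades gracefully to the plain component count;
  an erosion that empties the mask returns 0.

Connectivity is 8 for foreground throughout (and 4 for background when
identifying enclosed holes, the standard complementary pairing).

## Spot experiments

Distance to the attractant is measured from slime pixels to the *edge* of
the circular glucose spot, clamped at 0 on overlap, so "reached" is
unambiguously distance 0. Whether a described spot separation is
edge-to-edge or center-to-center is ambiguous in general; the synthetic
generator therefore exposes the edge-to-edge gap (`spotGapMm`, default
45 mm) as an explicit parameter rather than guessing. The survival curve is
the plain empirical step function P(t) = fraction of replicates without
contact by t, censored replicates counting as not-reached through the
horizon; no regression-based survival modeling is included (tests
cross-check against the Kaplan–Meier estimate, which coincides when all
censoring is at the horizon).

Replicate summaries report the across-replicate mean with first/third
quartiles using the linear-interpolation convention (`quantile` type 7).

## The synthetic generator

`generateSynthetic()` simulates a lattice plasmodium with known ground
truth. Defaults encode the reference experimental geometry: a 14.5 cm
arena with a 2.5 cm central slime disc, sampled every 5 min for 35 h
(420 frames). Each step:

1. the reachable band — non-slime arena pixels within
   `growthRateMmMin × intervalMin` of the slime front — is computed by
   distance transform; a sub-pixel carry accumulates unspent advance so the
   front moves at the nominal speed even when one step is below one pixel;
2. a fraction `fillFrac` (default 0.6) of the band is claimed, sampled
   without replacement with weight `mucusBias` on mucus pixels versus 1 on
   unexplored pixels, plus an exponential directional weight toward the
   glucose spot when `chemoStrength > 0`;
3. pseudopod lobes (Poisson, `pseudopodRate` per hour) claim small discs
   beyond the band — a deliberately non-random, directed growth mode;
4. with probability `retractionProb` a peripheral patch of established
   slime (slime in the previous frame too, so ground truth respects the
   irreversible-history rule) retracts to mucus;
5. a sealing pass applies the same speckle/hole cleanup rule the
   segmentation uses to the truth itself — a plasmodial sheet has no
   sub-threshold vacuoles at this resolution — which makes the truth a
   fixed point of mask cleanup, and noise-free renders recoverable exactly.

The per-interval log (event pixel counts, true maximum extent, true
migration rate) is derived from the realized label difference, so it equals
by construction what the analysis pipeline measures on the truth. Rendering
assigns each class its mean RGB color plus i.i.d. Gaussian noise
(`noiseSigma`, 8-bit units; default 4), clipped to 0–255; the default
palette (yellow slime, pale beige mucus, light gray substrate) keeps every
class pair ≥ 20 ab\* units apart with mucus chromatically nearer the
substrate than the slime, as in photographs, so the two-cluster split
separates slime from everything else. All draws consume a single stream
seeded from `seed`, in the order above, with render noise drawn after the
simulation in frame order; identical seeds give bit-identical output.

Presets `control`, `nutritive`, `highly-nutritive`, `adverse` and
`spot-experiment` bundle parameters that reproduce the qualitative
orderings of those conditions (e.g. `adverse`: 3-h start delay, high
retraction, `mucusBias = 5`). Growth speeds of 0.1–0.25 mm/min sit in the
range of plasmodial migration of a few centimetres per hour. The values are
illustrative, not fitted.

What the generator does **not** emulate: protoplasmic streaming and
oscillatory shuttle flows, vein-network topology, illumination gradients or
drift, lens distortion, specular highlights, and mass conservation (area is
gained and lost freely). Passing tests therefore demonstrate correctness of
the measurement pipeline on geometry- and color-realistic inputs, not
biological fidelity of the simulation itself.

## Calibration of the secondary-growth estimator

Under a null in which regrowth is a uniform draw over the reachable band,
the observed secondary-growth fraction should match the expected fraction
on average. Two generator mechanisms intentionally violate that null and
are switched off for the calibration check: pseudopod lobes (directed
growth claiming 100% of a disc, which also stretches the expansion region),
and the sealing pass (deterministic claims; inert below one pixel, so the
check runs at a resolution where the cleanup threshold is sub-pixel). Under
these conditions the test suite requires the mean observed−expected
difference over ≥ 200 informative intervals to lie within 3 Monte-Carlo
standard errors of zero at `mucusBias = 1`, and observed > expected in
≥ 95% of informative intervals at `mucusBias = 5` — the adverse-substrate
signature. An interval is informative when both growth pixels and a mixed
(mucus and unexplored) expansion region exist.

## Problem sizes and numerical conventions

The test and acceptance runs use 64–160 px grids with 20–80 frames
(full-scale 256 px, 420-frame runs are exercised for the frame-budget
check without rendering); these sizes were chosen so the whole suite
completes in a few minutes while every criterion retains its meaning — all
thresholds (1-px-equivalent rate recovery, 2–3% shape tolerances, 3 SE
calibration) are resolution-aware rather than tuned to a size.

Other conventions: coordinates are (row, col), 0-based distances between
pixel centers; frame order is the lexicographic file order (an explicit
path vector overrides); k-means uses 10 restarts and a config seed purely
for determinism of iteration order; mask PNGs store the literal codes 0/1/2
and round-trip exactly; empty masks raise errors in shape and spot
functions rather than returning sentinels, while degenerate intervals in
the bias estimate return NA.

## Known limitations

* Two-cluster chromatic segmentation assumes the slime is the chromatic
  outlier; on substrates where mucus is more saturated than the cell, the
  reference-color rule still anchors the slime cluster but the
  mucus/substrate distinction relies entirely on pixel history.
* The migration rate is an extreme-value statistic; a single mislabeled
  pixel far from the front inflates it. The speckle cleanup bounds this
  failure mode but cannot eliminate it at high noise.
* Perimeter, and hence circularity, depends mildly on the smoothing σ;
  comparisons should fix σ across treatments (the default does).
* The expansion-region discretization error scales like 1/(2r+k) for a
  radius-r front and offset k; at very coarse resolutions expected
  fractions are correspondingly noisy.
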