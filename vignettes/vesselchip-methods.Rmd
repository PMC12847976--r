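---
title: "Quantifying tumor-associated vascular networks on chip: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-associated vascular networks on chip: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselchip)
```

# Overview

`vesselchip` quantifies the microvascular networks that endothelial cells
form in the tumor compartment of organ-on-chip cultures, and runs the
statistics layer of a phenotypic drug screen on top of the resulting
morphometry. The image path is:

1. **Background subtraction** — rolling-ball removal of slowly varying
   background (`rolling_ball_subtract()`).
2. **Segmentation** — a three-class vessel mask: background, thin vessel,
   thick vessel (`segment_vessels()`, `classify_thickness()`).
3. **Cleanup** — signal outside the tumor compartment and connected
   components below a size threshold are removed (`postprocess_mask()`).
4. **Skeletonization and graph extraction** — a one-pixel medial skeleton,
   its branch/junction graph, and short-spur pruning
   (`skeletonize_mask()`, `build_graph()`, `prune_spurs()`).
5. **Morphometry** — fifteen per-chip descriptors
   (`compute_descriptors()`).

The screen path covers vehicle-control plate normalization, replicate
reproducibility, PCA/t-SNE phenotypic embedding, normality-gated group
comparisons (ANOVA + Tukey HSD or Kruskal–Wallis + Dunn), per-analyte
Wilcoxon rank-sum tests with Benjamini–Hochberg control, and Welch
t-tests.

Because real chip images carry no usable ground truth, the package ships a
synthetic generator for both single chip images
(`generate_network()`, `rasterize_network()`, `corrupt_image()`) and whole
screens (`screen_design()`, `generate_screen()`), with exact generating
truth stored alongside. Every pipeline stage is validated against that
truth.

# The image model

A chip image is a single-channel 16-bit intensity grid with a fixed
geometry: the tumor compartment (region of interest, by default the full
frame) and a central circular region — the area within the glass hole of
the tumor compartment — against which vessel densities and the
inside/outside area ratios are defined. The glass-hole radius is a
required configuration value (default 300 px on a 1024×1024 frame, scaled
proportionally in the examples here); it is deliberately not inferred from
the image.

## Rolling-ball background subtraction

The background estimate is the grayscale morphological opening of the
image with a disc structuring element of radius $r$ (default 50 px):
erosion followed by dilation, i.e. the classic rolling-ball family on the
raw intensity scale. Structures wider than roughly $2r$ are treated as
background; narrower structures (vessels, up to ~20 px here) pass through
essentially unchanged. The default radius exceeds the widest expected
vessel by more than a factor of two. Light pre-smoothing is available but
off by default; no sliding-paraboloid variant is provided. Opening is
idempotent, so the subtraction is stable under repetition, and the
background estimate is pixelwise non-increasing in the radius.

## Segmentation and the thick/thin split

The default backend thresholds the background-subtracted image with Otsu's
method computed over the compartment interior. It replaces the trainable
pixel classifier used interactively in image-analysis suites: a
deterministic default keeps every result bit-reproducible, while the
`backend` argument of `segment_vessels()` accepts any function honouring
the three-class contract, so a trained classifier can be plugged in for
real data.

The thick/thin partition is width-based: the local vessel width at a
skeleton point is twice its Euclidean distance to the background, and that
width is propagated from the skeleton to every vessel pixel by wavefront
(nearest-skeleton) assignment. Pixels at or above the cutoff (default
4 px, `thick_width_px`) are thick. The cutoff matches the synthetic
generator's stroke-width classes so that truth and estimate are
commensurable. The split conserves the binary vessel area exactly, by
construction.

Post-processing zeroes all signal outside the compartment and removes
8-connected components smaller than `min_object_px` (default 50 px; the
threshold is a free parameter because no principled value exists — it must
sit above the size of speck artifacts and below the smallest true vessel
fragment). Post-processing is idempotent.

## Skeleton, graph, and descriptors

Skeletonization is iterative Guo–Hall thinning of the union of both vessel
classes: two directional subiterations per pass, deleting simple boundary
pixels until stable. It preserves topology (components and holes): an
annulus thins to a single closed cycle, a disk to a near-point.

Graph extraction classifies skeleton pixels by 8-neighbour count: pixels
with ≥3 neighbours are junction pixels, and 8-adjacent junction pixels are
merged into **one** junction node — otherwise an X-crossing, which thins
into a small cluster of junction pixels, would be counted several times.
Pixels with one neighbour are endpoints. The remaining pixels form branch
paths; each path becomes an edge whose geometric length sums its steps —
1 per axial step, $\sqrt 2$ per diagonal step — plus the step connecting
each path end to its incident node. Terminal spurs shorter than
`spur_prune_px` (default 3 px) are removed before descriptors are
computed; they are thinning artifacts at vessel ends, not biology.

The fifteen descriptors per chip:

| descriptor | definition |
|---|---|
| explant_area | area of the convex hull of all vessel pixels |
| thick/thin/total_area | per-class vessel pixel counts |
| thick/thin/total_density | class area ÷ central-circle area |
| n_junctions | merged junction nodes of the skeleton |
| branching_index | junctions ÷ total vessel area |
| total_length | sum of all skeleton branch lengths |
| avg_branch_length | mean branch length (per branch, within chip) |
| avg_width | total area ÷ total length |
| thick_total_area_ratio | thick area ÷ total area |
| inout_total_ratio, inout_thick_ratio | class area inside ÷ outside the central circle |

Numerical conventions: pixel units throughout, with an optional
micrometre conversion applied only at output; branch length is geometric
($\sqrt 2$-weighted), not a raw pixel count; average branch length
averages over branches within a chip. Degenerate cases are explicit: an
empty mask yields all-zero descriptors with an `empty` flag; if the
class area outside the circle is zero the inside/outside ratio is
reported missing (`NA`) rather than infinite, and flagged, and flagged
columns are dropped from standardization before embedding; if total
length is zero, average width is zero.

# The synthetic generator

## Chip images

The growth model is entirely ours — real vessels grow by angiogenic
sprouting; we need something *analytically bookkeepable*. Branches are
persistent random walks seeded on the compartment border and directed
inward: per step, a Gaussian heading perturbation (persistence 0.7), a
step of 3 px, and a Bernoulli branching draw (default probability 0.05
per step). Each branch carries a stroke width drawn from a thin
(1.5–2.5 px) or thick (4.5–7 px) class; widths near the 4 px classifier
cutoff are deliberately absent so the truth labels are unambiguous.

What makes the truth *pixel-faithful* rather than merely nominal:

* **Collision corridors.** A tip terminates rather than step within
  8 px of another branch's centerline, so strokes only ever meet at true
  branching junctions — random crossings would otherwise create raster
  junctions the ground truth knows nothing about.
* **Escape grace.** A daughter ignores only its parent's corridor (and
  vice versa) for the few steps it needs to clear it, and both hold a
  straight course during that window, so the two strokes separate
  monotonically instead of laddering against each other.
* **Junction retraction.** A branching event only counts as a junction if
  its daughter establishes at least 20 px of centerline *and* the parent
  continues past the junction; a parent that dies within 10 px of its
  last junction is trimmed back to it. Both rules mirror what a raster at
  this resolution can resolve: a 3 px stub is a corner, not a Y.
* **Junction spacing.** Successive junctions on one parent are at least
  12 px apart, so their skeleton junction clusters cannot merge.

Rasterization strokes each polyline at its width (thick wins where
strokes overlap) and sets the per-class truth areas from the label grid
itself, so area truth is exact by construction. The generator also logs
every Bernoulli draw; the junction count must equal the number of
successful branching events, which the tests verify by replaying the log.

Corruption adds, in order: a smooth background field (planar gradient or
Gaussian blobs), i.i.d. Gaussian noise, and compact bright specks of
3–8 px placed off-vessel — exactly the defects that rolling-ball
subtraction and small-object removal are meant to undo. All randomness
derives from one explicit seed.

What the generator does **not** emulate: out-of-focus blur, uneven
staining along a vessel, lumenized (hollow) vessels, touching vessels
that merge into sheets, and 3-D stack projection artifacts. Passing the
recovery tests therefore shows the morphometry is correct *given a
segmentable image*; it does not certify the Otsu default against every
real staining condition — that is what the pluggable backend is for.

## Screens

A screen is donors × treatments × replicate chips across plates. Readouts
follow a multiplicative model: per-chip viability equals a plate baseline
× a lognormal donor effect × a lognormal plate effect × the treatment's
scripted multiplier × lognormal replicate noise; analytes and descriptors
are analogous with per-readout multipliers. All lognormal effects have
mean exactly 1, which has a useful consequence: with zero replicate noise,
vehicle-control normalization recovers scripted multipliers *exactly*,
because donor and plate effects cancel within a plate. The default layout
(replicates per treatment per plate, six vehicle chips per plate) mirrors
a realistic automation-plate screen; effect sizes used in the validation
suite (e.g. a 0.47 viability multiplier, a halving of density, length and
junction descriptors for an anti-angiogenic treatment) are scripted study
conditions, not empirical claims.

# Statistics layer

* **Normalization**: per plate, each chip's viability becomes
  $100 \times \mathrm{raw} / \mathrm{mean}(\text{vehicle raws})$. A plate
  without vehicle chips is an error naming the plate.
* **Group comparisons** (`compare_groups()`): in `auto` mode a
  Shapiro–Wilk test per group at $\alpha = 0.05$ gates the path — all
  groups compatible with normality goes one-way ANOVA with Tukey HSD,
  otherwise Kruskal–Wallis with Dunn's post-hoc z tests (implemented from
  the mid-rank formulas with tie correction, and verified against hand
  rank arithmetic). Post-hoc p-values are then Bonferroni-adjusted across
  the pairwise family (the screening convention adopted here applies
  Bonferroni on top of the post-hoc test; the doubled correction costs
  power but never inflates error, and the scripted effects in the
  validation suite remain comfortably detectable). A zero-variance group
  under the parametric path falls back to nonparametric with a warning.
* **Analyte tests** (`analyte_tests()`): per analyte × treatment, a
  two-sided unpaired Wilcoxon rank-sum test against control ("Wilcoxon"
  is read as rank-sum, not signed-rank: chips are independent), with
  Benjamini–Hochberg adjustment across the full analyte × treatment
  family by default (`family = "per_analyte"` is available; the family
  choice is a genuine open point and is therefore configurable). Exact
  p-values are used for small tie-free samples, the normal approximation
  with tie correction otherwise.
* **Welch** (`welch_compare()`): unequal-variance t with Satterthwaite
  degrees of freedom.
* **Embedding** (`embed_descriptors()`): columns are standardized;
  missing-flagged and zero-variance columns dropped. PCA is made fully
  deterministic by a sign convention (largest-magnitude loading
  positive). t-SNE requires an explicit seed and perplexity below
  $n/3$ (default $\min(30, n/4)$).
* **Stars**: \*\*\*\* < 0.0001, \*\*\* < 0.001, \*\* < 0.01, \* < 0.05 on
  adjusted p-values.
* **Exclusions**: none automatic; an explicit chip list in the config is
  the only mechanism.

# Validation suite and problem sizes

The test suite regenerates everything from code; there are no stored
fixtures. The heavier simulations use sizes chosen to make the checks
statistically meaningful while keeping the whole suite in the
ten-minute range on one core: 50 synthetic networks on 384×384 frames
(central circle 110 px) for ground-truth recovery, clean and corrupted;
200 all-null screens for the Benjamini–Hochberg calibration; 1000 null
replicates of 5 groups × n = 8 for the family-wise error of the
auto-gated procedure; 100 screens of n = 30 vehicle vs n = 10 treated
chips for the power of detecting a scripted anti-angiogenic effect, and
20 for its PCA-plane silhouette. `scripts/acceptance.R` recomputes the
same quantities at slightly reduced counts and writes them as JSON.

# Known limitations

* Guo–Hall thinning, like every directional-subiteration thinning, is not
  exactly equivariant under 90° rotation: pixel-count descriptors are
  bit-stable under rotation, skeleton-derived ones move by well under 1%.
* Skeleton length of a stroked branch is measured along the thinned
  centerline; free branch ends retract by roughly half the local width,
  a bias of a few percent that the recovery tolerances absorb.
* The Otsu backend assumes a roughly bimodal intensity histogram inside
  the compartment; weakly stained images should use a custom backend.
* Descriptor units are pixels unless a pixel size is supplied; no
  physical calibration is inferred from image metadata.
* Donor heterogeneity is modelled (and generated) as a random multiplier
  but the statistics layer deliberately offers no mixed-effects model;
  chips are pooled across donors per treatment, and the pooling rule is
  configurable rather than hard-coded.
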