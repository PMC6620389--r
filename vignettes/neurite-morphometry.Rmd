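---
title: "Quantifying age-related morphology of C. elegans touch receptor neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying age-related morphology of C. elegans touch receptor neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritemorph)
```

## The measurement problem

Aging *C. elegans* touch receptor neurons (ALM and PLM) do not degenerate,
but they accumulate subtle, stochastic morphological abnormalities: new
processes sprouting from the soma or from the sensory dendrite, focal
enlargements (beads/blebs) along the dendrite, abrupt sharp bends
("kinks"), and shrinkage of the cell body. These features are scored from
confocal stacks of GFP-labelled neurons after automated tracing (APP2 in
Vaa3D), which yields one rooted tree per neuron in SWC format: nodes with
3D position, an in-plane radius estimate, and parent links.

`neuritemorph` takes such trees (plus, for ALM somas, the image stacks)
and turns them into per-neuron feature tables and cohort statistics. All
thresholds below are exposed in configuration objects
(`classify_config()`, `morph_config()`, `segment_config()`,
`run_config()`), and every output row records a configuration hash.

## Compartment classification

Every node receives one of seven labels: `mainbranch`, `soma`,
`neuriteoutgrowth`, `somaoutgrowth`, `pvm`, `vnc_connection`,
`blob_artifact`.

* The **main branch** (the sensory dendrite) is the root-to-endpoint path
  of maximal arclength, with arclength the sum of Euclidean distances
  between consecutive nodes. Ties break to the smallest endpoint id so
  runs are reproducible.
* The **ALM soma** is the maximal connected set of nodes containing the
  root whose radii exceed `soma_radius_threshold` (default 2 µm; traced
  dendrites run ~0.3–0.8 µm and somas ~2.5–4 µm, so the default separates
  them cleanly, but the threshold is per-dataset configurable because it
  depends on the tracer's radius calibration). Side branches attached to
  soma nodes are **soma outgrowths**; those attached to main-branch nodes
  are **neurite outgrowths**. Each side branch's cable length and the
  arclength of its attachment point are recorded.
* PLM traces frequently co-capture a piece of the crossing **PVM** neuron.
  A side branch containing a node above the soma radius threshold is taken
  to hold the PVM soma; that branch and every side branch attaching within
  ±`pvm_window` (4 µm) of its attachment point are labelled `pvm` and
  excluded from outgrowth counts. If several side branches carry
  large-radius nodes, the single largest radius wins and the rest fall
  back to neurite outgrowths (with a message) — a deliberate tie-break for
  a situation the original procedure did not need to handle.
* `vnc_connection` (SWC type code 7) and `blob_artifact` (code 8) are
  manual annotations made in external editors such as neuTube; the
  pipeline honours them and never infers them.

Branches that themselves branch are treated as one side structure whose
length is the total cable length of the subtree (including the edge to the
attachment node).

## Sharp bends

For every main-branch node, nodes within 2 µm of *accumulated arclength
per side* (`bend_window`) are collected upstream and downstream. A
total-least-squares direction (first principal component) is fitted to
each side — ordinary regression would be axis-dependent — both directions
are oriented away from the node, and the angle between them is computed as
`atan2(‖u×v‖, u·v)`, which is numerically stable across the whole 0–180°
range (a pure arcsine of the cross product is ambiguous beyond 90°). A
straight polyline scores 180°. Nodes within 2 µm of either end are
excluded: one-sided fits bias angles.

Nodes with an angle below `bend_threshold` (155°) are candidates. To
prevent double counting, bends are selected sequentially starting with the
sharpest, and each selection suppresses candidates within `bend_nms`
(4 µm) of arclength — non-maximum suppression. Suppression removes
candidates only; angles are never recomputed. Bend density is the count
divided by the main-branch length, and `threshold_sweep()` recomputes the
density across thresholds (135–165° by default). Density is provably
non-decreasing in the threshold: raising it only adds weaker candidates,
which cannot alter the greedy selection of stronger ones.

A smoothing-spline curvature profile (`spline_curvature()`) is included as
a diagnostic only; curvature-based bend counting is noticeably less robust
to tracing noise and is not used for any reported count.

## Beads and blebs

The traced radius along the main branch is compared with a local thickness
estimate: the mean radius over an 8 µm arclength window
(`thickness_window`). Residual maxima are counted sequentially (4 µm
suppression) while they exceed `bead_sd_multiplier` (2) standard
deviations of the residuals over the whole branch. The SD is taken over
residuals rather than raw radii — raw radii mix the bead signal with
genuine taper — but `bead_sd_source = "raw"` is available. Note the
statistical character of the 2-SD rule: on a branch whose radii carry pure
measurement noise it will, by construction, flag the occasional noise
exceedance; it is silent only on noise-free constant radii. Counts are
therefore comparisons between conditions, not absolute bead numbers.

## ALM soma volume

The soma is segmented in the 3D stack by seeded region growing
(`confidence_connected()`): starting from the traced soma node, the
region's intensity mean µ and SD σ are estimated, a flood fill
(26-connectivity) accepts voxels within µ ± 2.5σ, and statistics and fill
are iterated 4 times. Stacks are pre-smoothed with an anisotropic Gaussian
(sigma 0.7, 0.7, 0.52 voxels), mirroring the standard pre-tracing
denoising, and a morphological opening (ball of radius 1 voxel in index
space; anisotropy deliberately ignored for this cleanup step) strips thin
attachments such as the dendrite before the volume is summed over voxels.

One design choice deserves emphasis. The confidence band tracks the
*statistically homogeneous core* of the soma: on denoised data the band is
narrow, the cut sits near 90% of the interior intensity, and volumes of
PSF-blurred objects come out 25–40% low; widening the band is not a fix,
because once the edge ramp enters the statistics the band swallows the
background (the iteration is bistable). The unbiased boundary of a blurred
object is its half-intensity surface, which the point-spread function
preserves. `segment_soma()` therefore refines the grown region by
re-flooding at the level midway between the region-core median and the
background median (`boundary = "halfmax"`, the default;
`boundary = "confidence"` reports the raw region). On rendered test
spheres of radius 1.5–3.5 µm with Poisson noise this removes the bias
(mean error ≈ −1%, worst case < 6%); a noiseless digitized sphere is
recovered within ~1%.

`find_boundary_seed()` supports PLM tracing setup: it returns the
brightest voxel on the six stack faces (where the dendrite enters the
field of view), with lexicographic tie-breaking, as a Vaa3D `.marker`
seed.

## Spatial statistics of bends and outgrowths

The dendrite is stretched onto one dimension; every sharp bend and every
outgrowth attachment becomes a point at its arclength distance from the
most distal main-branch point. Distances are along the dendrite, not 3D
chords. For the bend pattern of each neuron the empty-space function
F(r) — the fraction of dendrite length within r of a bend — is computed
exactly from interval unions, no sampling. F(r) is what the fraction of
outgrowths within r of a bend would be if outgrowths ignored bends.

The association test pairs, per neuron, the observed fraction of
outgrowths within r = 1 µm of a bend with F(1 µm), and applies a Wilcoxon
signed-rank test to the differences (one-sided "greater" by default, since
the scientific claim is directional; two-sided is available). Zero
differences are dropped. The null distribution of W is computed exactly by
dynamic programming over all sign assignments, handling tied ranks — an
in-package implementation because `stats::wilcox.test()` declines exact
p-values under ties, and ties are the norm for k/m-type fractions. Neurons
lacking either bends or outgrowths cannot contribute a pair and are
excluded (with a count in the result).

Two properties of this test are worth knowing. Power against genuine
coupling is excellent: with 80% of outgrowths placed within 0.5 µm of a
bend in cohorts of 19 neurons, rejection at α = 0.05 occurs in essentially
every simulated cohort. Calibration under the null, however, is
conservative at realistic event counts: with ~2 outgrowths per neuron the
paired differences k/m − F(r) are coarse, right-skewed quantities with a
negative median, and the signed-rank test — a test of symmetric
location — rejects at well below nominal rate (~0.01 at α = 0.05 in our
simulations; the effect shrinks only slowly as counts grow). Conclusions
drawn from small p-values are therefore on the safe side; the test does
not over-reject.

Cohort utilities include the two-sided two-sample Kolmogorov–Smirnov
comparison of event-position distributions between groups and percentile
bootstrap confidence intervals of group means (10 000 resamples by
default, seeded for exact reproducibility).

## The synthetic-data generator

`make_neuron()` builds trees with fully known ground truth: a main
dendrite of given length and node spacing (0.25 µm by default, matching
unresampled tracing output), planted bends of specified interior angle at
specified arclengths (each bend turns the travel direction about a random
axis perpendicular to it, so geometry is genuinely 3D rather than planar),
side branches with planted labels (including a PVM-like branch carrying a
3 µm-radius node), Gaussian radius bumps for beads, per-node coordinate
jitter (σ = 0.05 µm default) and radius noise, and optionally a spherical
soma carried by the root node. `render_stack()` rasterizes a tree into an
anisotropic voxel grid (0.223 × 0.223 × 0.3 µm), applies a Gaussian PSF
(0.7, 0.7, 0.52 voxels) and Poisson photon noise (expected interior count
100 ≈ SNR 10; background 2% of it).

Ground truth is recorded in the *realized* geometry: coordinate jitter
lengthens the traced polyline (about 10% at the default spacing and
noise), so positions planted in the ideal geometry would disagree with any
arclength-based detector by several µm on a 100 µm dendrite. Truth tables
carry both the realized and the nominal values.

`cohort_spec()`/`make_cohort()` emulate age/genotype contrasts at the
distribution level: bend counts from a density (0.1 µm⁻¹ echoes day-8
wild-type dendrites), Poisson outgrowth counts (mean 2), log-normal
outgrowth lengths, and a coupling knob that places outgrowths within a
given distance of a bend with given probability — the generative effect
the association test must detect. `simulate_position_cohort()` draws the
same point patterns directly on the 1D neuron without building trees; it
is the fast path used for the calibration and power studies (2000 + 500
cohorts run in under two minutes on one CPU).

What the generator does *not* emulate: stitching artifacts, depth-dependent
attenuation, tracing topology errors (broken or merged branches), and
autofluorescent clutter. Passing recovery tests on synthetic data
therefore validates the measurement chain, not robustness to every failure
mode of real acquisitions.

## Problem sizes and numerical choices

The validation studies use 100 synthetic branches for bend recovery (0–10
bends each, angles 90–150°, separations > 6 µm), 10 branches × 3 planted
beads for bead recovery, 100 trees for classification recovery, 20
rendered spheres for volume recovery, and 2000/500 cohorts for the
association test's operating characteristics — sizes at which every check
runs comfortably on a single CPU while keeping Monte-Carlo error small
relative to the asserted margins.

Degenerate inputs are handled explicitly: single-node trees refuse a main
branch; branches shorter than three nodes refuse angle and bead
computation; coincident points yield undefined angles (logged as `NA`)
rather than spurious bends; constant radii yield no beads (the 2-SD cut is
floored at 1 nm so float round-off cannot fire); a segmentation growing
past half the stack aborts with a "segmentation overflow" error, which is
what a mis-placed seed looks like in practice.

## A worked example

```{r example}
spec <- neuron_spec(
  main_length = 100,
  bends = data.frame(arclength = c(25, 50, 75), angle = c(120, 135, 110)),
  branches = data.frame(arclength = 50.5, length = 6,
                        label = "neuriteoutgrowth"),
  seed = 7)
nt <- make_neuron(spec)
ct <- classify_plm(nt$tree)
ct
bends <- detect_bends(main_branch_geometry(ct))
bends
ep <- positions_from_distal(ct, bends, branch_inventory(ct))
nearest_bend_distances(ep)
```

The detected bend arclengths sit within a micrometre of the planted ones
(in the realized metric), and the outgrowth planted 0.5 µm from the middle
bend shows a sub-micrometre nearest-bend distance.
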