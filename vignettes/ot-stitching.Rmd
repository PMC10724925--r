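---
title: "Stitching 2D cell masks into 3D instances with optimal transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching 2D cell masks into 3D instances with optimal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otstitch)
```

## The problem

Volumetric fluorescence microscopy rarely comes with enough annotated 3D
training data to segment cells directly in 3D, while 2D segmentation of
individual optical sections is mature and accurate. The gap between the
two is *stitching*: given a z-stack of label masks in which every layer
was segmented independently (so the integer labels carry no meaning
across layers), assign globally consistent labels so that the 2D slices
of the same 3D cell share one label. Stitching is hard for two reasons.
First, simple overlap thresholding between consecutive layers is
sensitive to the threshold and ignores the global arrangement of cells.
Second, distinct cells frequently sit directly on top of each other
along Z, so two slices can overlap almost perfectly and still belong to
different cells. A further practical complication is *anisotropy*:
z-spacing is typically several times the in-plane pixel size, so a
faithfully stitched volume still misrepresents cell morphology unless
the missing internal layers are reconstructed.

This package implements a three-part answer: (1) an exact
optimal-transport (OT) formulation of the layer-correspondence problem,
(2) a per-pixel rejection vote using 2D segmentations of the orthogonal
(YZ and XZ) planes that keeps stacked cells apart, and (3) a
2-Wasserstein boundary interpolation that morphs matched slices to fill
in the internal layers of anisotropic volumes. Everything operates on
label masks; producing the 2D masks in the first place is the job of
whatever 2D segmentation model the user prefers.

## The transport model

Let layer $z$ contain labels $\{0, 1, \dots, m\}$ and layer $z+1$ labels
$\{0, 1, \dots, n\}$, with 0 reserved for background. Each layer is
summarized by the discrete distribution of its label masses,

$$P(x) = \frac{\#\text{pixels of } x \text{ in layer } z}{\#\text{pixels in layer } z},$$

and analogously $P'(y)$ for layer $z+1$; background is a full
participant, so both distributions live on $m+1$ (resp. $n+1$) bins and
sum to one. The cost of sending mass from label $x$ to label $y$ is

$$C_{x,y} = 1 - J(x, y), \qquad J(x,y) = \frac{|x \cap y|}{|x \cup y|},$$

the complement of the Jaccard index of the two pixel supports at
identical image coordinates. Overlap, not centroid distance, is the
right notion of affinity here: in densely packed tissue, the centroid of
a large cell slice can easily be nearer to a neighboring small cell's
slice than to its own continuation, whereas the supports of consecutive
slices of one cell overlap heavily. The Kantorovich problem

$$\hat M = \arg\min_{M \in \Pi(P, P')} \langle C, M\rangle$$

is solved exactly (`solve_transport()`): a transportation-simplex solver
with Bland-style anti-cycling finds a vertex optimum. Exactness matters
because the next step reads the *argmax structure* of $\hat M$, which an
entropically smoothed plan would blur; the problems are tiny (one bin
per label), so a dense exact solver costs nothing.

From the plan, the tracing function $T(x) = \arg\max_y \hat M_{x,y}$
sends every source cell to the target receiving most of its mass
(`trace_cells()`). Each target $y$ is then matched to its least-cost
tracer $\arg\min_{x \in T^{-1}(y)} C_{x,y}$ (`best_tracer()`), or
declared a new cell when no source traces to it. Because each source
relabels at most one target, an over-segmented source layer heals
automatically: the spurious fragment loses the competition, relabels
nothing, remains confined to isolated layers, and is deleted by the
final cleanup pass (`remove_isolated_cells()`, default minimum span 2
layers).

## The rejection vote

An OT match only says two slices overlap well; stacked cells overlap
well too. The vote (`rejection_fraction()`) consults independent 2D
segmentations of the orthogonal planes: every pixel $(r, c)$ of the
candidate target slice casts one vote per orthogonal stack, rejecting
when the YZ-plane at $X = c$ (resp. the XZ-plane at $Y = r$) assigns
different labels to layers $z$ and $z+1$ at that position. If two cells
are stacked, any orthogonal section through them shows two different 2D
cells at the interface, so the votes reject en masse; within one cell
the orthogonal labels are constant and the votes accept. The match is
stitched only when the rejection fraction is *below*
`rejection_threshold` (default 0.5, i.e. a majority must reject to
split). Two design points deserve note:

* Background-background comparisons (0 = 0) count as non-rejecting:
  equal labels are equal. The alternative (discounting them) would
  change little in packed tissue, where a pixel's orthogonal
  counterpart is almost always inside some cell.
* Setting the threshold to 1 accepts any match not unanimously
  rejected, and `use_orthogonal_vote = FALSE` (or omitting the
  orthogonal masks) disables the vote entirely; both reduce stitching
  to pure OT matching.

The full pass (`stitch_volume()`) runs top to bottom: the first layer's
partition is mapped to fresh global labels, each following layer is
stitched onto its already-relabeled predecessor, and the isolated-cell
cleanup runs last. Fresh labels come from one counter starting above the
maximum input label, so output labels never collide with input ones.

## Wasserstein interpolation of internal layers

For a volume with anisotropy $N$ (z-spacing $N$ times the pixel size),
`interpolate_volume()` rebuilds the $N-1$ missing layers between each
adjacent pair. For a cell present on both sides, the 4-connectivity
contours of the two slices (`extract_boundary()`) are coupled by exact
OT between uniform distributions under squared-Euclidean cost
(`boundary_coupling()`) — the coupling that realizes the 2-Wasserstein
distance. The internal contour at fraction $\alpha = k/N$ consists of
the points $(1-\alpha)p + \alpha q$ over all coupled pairs, rounded
half-away-from-zero per axis (deterministic across platforms, unlike
banker's rounding). Rounding can perforate a discrete curve, so the
rasterized contour is closed with a 3x3 structuring element before the
enclosed holes are filled (EBImage's morphology); when source and
target supports are identical the transported contour is the original
one at every $\alpha$ and the common support is returned exactly.
Original layers are copied bit for bit into every $N$-th output slot.
Voxels claimed by several cells' interpolants are resolved first-wins
in ascending label order — deterministic and auditable, and rare in
practice because interpolants of well-separated cells stay separated.

Cells without a partner on one side of a pair (births, deaths,
terminations) get no internal voxels: there is no target shape to
transport toward, so the cell stops at its last original layer. The
practical consequence is visible on strongly curved cell ends (see
*Limitations*).

## Evaluation metrics

`match_instances()` matches predicted to ground-truth cells one-to-one
among pairs with 3D IoU strictly greater than a threshold $t$, greedily
in descending IoU. For $t \ge 0.5$ each instance has at most one
candidate partner (two bodies cannot both claim more than half of the
same union), so the greedy matching is provably optimal; at lower
thresholds it is the standard convention. From the counts,

$$\text{precision}_t = \frac{TP}{TP+FP}, \quad
  \text{recall}_t = \frac{TP}{TP+FN}, \quad
  AP_t = \frac{TP}{TP+FN+FP},$$

with $0/0$ reported as 0, and mAP averages $AP_t$ over
$t \in \{0.25, 0.5, 0.75\}$ (`metric_report()`).

## The synthetic scene generator

`generate_scene()` produces ground-truth volumes with the structure the
method assumes, so every pipeline stage is testable without external
data. Seeds are placed by uniform rejection sampling with a minimum
pairwise distance (bounded retries); cells are either the Voronoi
regions of the seeds (densely packed convex cells) or solid balls
clipped against neighbors. Scenes are validated: every cell must be
6-connected and span at least two layers. `slice_masks()` then emulates
a per-plane 2D segmenter by renumbering every plane independently, with
optional corruption (chord splits through the slice centroid at a
uniform angle, boundary erosion/dilation, dropped planes), and
`subsample_z()` emulates anisotropic acquisition by keeping every
$N$-th layer. All outputs are pure functions of (configuration, seed).

One generator parameter encodes a deliberate modeling choice:
`seed_z_band` confines Voronoi seeds to a central z-slab. With seeds
spread over the full depth, Voronoi cells taper to a point at their
z-ends, and a tapering tip can change its footprint by more than half
between consecutive layers — at which point the rejection vote, exactly
as designed, refuses the stitch. Layer-wise stitching fundamentally
assumes locally cylindrical cells (cross-sections that change slowly
relative to the z-step). The perfect-recovery experiments therefore use
columnar scenes (`seed_z_band = 0.1`, cross-sections shifting by a
pixel or two per layer), which represent the epithelium-like tissue
this class of method targets; wide-band scenes are still useful
precisely because they exercise the vote's splitting behavior.

What the generator does *not* emulate: intensity images, point-spread
functions, noise-induced 2D segmentation errors beyond the parametric
perturbations above, or under-segmentation (merged 2D masks). The
method cannot repair under-segmentation by construction — it relabels
masks, never reshapes them — so passing tests here say nothing about
that failure mode.

## Study sizes and numerical choices

The bundled experiments run on `32 x 64 x 64` scenes with 20 Voronoi
cells (stitching recovery) or 5 balls of radius 8 (interpolation
recovery at $N = 4$), sizes at which every cell still spans dozens of
layers-worth of structure while a full pipeline run takes seconds.
Tolerances: marginal feasibility of every transport plan is checked to
$10^{-8}$; simplex pricing uses a $10^{-10}$ threshold on reduced
costs; coupling support uses $10^{-12}$. Ties in argmax/argmin
(tracing, least-cost tracer, greedy matching) always resolve to the
lowest label, making every result independent of input label
permutations. Degenerate inputs are defined, not special-cased: an
all-background layer has distribution $\{0 \mapsto 1\}$ and every cell
of the next layer starts fresh; volumes shallower than the isolated-cell
minimum span skip the cleanup (a single-layer stack would otherwise be
erased entirely).

## Limitations

* **Cell terminations under interpolation.** A shrinking cell whose next
  slice holds less than roughly half its mass traces to background (the
  argmax of its transport row), ending the chain; together with the
  hard stop at the last original layer, this truncates strongly curved
  cell caps. On subsampled-sphere experiments the reconstruction is
  near-exact inside each cell's recovered z-extent (per-cell IoU
  0.88-0.97) while cap truncation dominates the remaining error; the
  aggregate per-cell 3D IoU depends on where cell poles fall relative
  to the kept layers, ranging roughly 0.7-0.85 over random scenes.
* **Under-segmentation** of the input 2D masks propagates; only
  over-segmentation is repaired.
* The rejection vote needs orthogonal-plane segmentations of usable
  quality; without them stacked cells merge (by design, matching the
  vote-disabled mode).
* The exact solver is quadratic per pivot in the label count and meant
  for the tens-of-labels-per-layer regime of tissue microscopy, not for
  thousands of instances per plane.

## A worked example

```{r example, eval = FALSE}
gt <- generate_scene(scene_config(c(32, 64, 64), 20, seed = 7,
                                  min_seed_distance = 10, seed_z_band = 0.1))
z_masks <- slice_masks(gt, "z")
ortho <- orthogonal_masks(slice_masks(gt, "x"), slice_masks(gt, "y"))
stitched <- stitch_volume(z_masks, ortho, stitch_config())
evaluate_segmentation(stitched, gt)$map
#> [1] 1
```
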