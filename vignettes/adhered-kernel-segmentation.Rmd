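---
title: "Segmenting adhered maize kernels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting adhered maize kernels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`maizeseg`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic scene generator does and does not emulate, and
the numerical choices a maintainer would want to know about. It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

## The problem and the method

Maize kernels scattered on a dark matte plate touch and partially occlude
one another; a binarized image fuses each cluster into one connected blob.
The package resolves blobs into individual kernels with a two-stage
"coarse segmentation, fine optimisation" scheme and then classifies each
kernel as intact or mechanically damaged from eight shape descriptors.

**Preprocessing.** RGB frames are converted with the luma weights
`Gray = 0.299 R + 0.587 G + 0.114 B` (rounded half-up: the image is stored
in 8 bits, so a deterministic integer convention is needed and half-up is
the common one). The binarization threshold is Otsu's: the exhaustive
argmax of the inter-class variance over all 256 thresholds, with ties
broken to the smallest threshold so results are deterministic. The
low class is `[0, t]` and the high class `[t+1, 255]`, which fixes the
threshold convention: foreground is *strictly above* `t` for bright
kernels (a `polarity` flag serves inverted scenes). A 3×3 opening-then-closing pass
removes specular speckles and fills pinholes; the element size is exposed
because the appropriate scale depends on image resolution. Pixels outside
the image are background throughout — the standard convention, which
prevents phantom foreground at the frame. One consequence worth noting:
morphological duality (complement of dilation equals erosion of the
complement by the reflected element) holds exactly only away from the
image border, because complementing flips the out-of-image convention; the
test suite therefore verifies the identity on the interior.

**Coarse segmentation: marker-controlled watershed.** The Euclidean
distance transform (EDT) of the foreground is computed exactly with the
two-pass lower-envelope algorithm. Kernel cores are EDT peaks; necks
between touching kernels are saddles. Marker extraction is
persistence-based: pixels are processed in decreasing distance order and
grown into peak regions; two regions merge when the saddle between them is
at least `saddle_ratio` (default 0.95) of the lower peak, or when the lower
peak's prominence falls below `prominence_min` (default 3 px, which
absorbs the spurious ridge maxima digitisation creates). Each surviving
region contributes one marker: its pixels at or above `peak_fraction`
(default 0.4) of the region peak, clipped strictly above the region's
highest separating saddle — without that clip, a marker core can annex the
neck between two kernels before flooding starts, and the basin boundary
lands far from the pinch. Flooding is a priority flood over the negated
EDT (4-connected frontier): pixels pop in increasing height, ties resolved
ring-by-ring so that two fronts meeting in a band divide it equidistantly,
then by insertion order for exact determinism. Pixels reached by two
basins simultaneously carry a reserved boundary code and are afterwards
merged into the adjacent basin with the lower label so that basins are
closed regions for contour extraction.

Two design choices deserve justification:

* *Why flood the distance field rather than the gradient?* Both surfaces
  are implemented (`height = "gradient"` floods a Gaussian-smoothed,
  σ = 1.5, Sobel magnitude instead). For convex blobs the inverted EDT is
  what makes separation work: its saddles sit exactly at the necks. The
  gradient surface is kept as a configuration alternative.
* *Why persistence markers instead of thresholding each component at a
  fraction of its maximum?* The simpler rule (kept as
  `marker_method = "component_max"`) cannot serve both of two needs at
  once. The saddle of two disks with ~30% area overlap lies at about 0.8
  of the peak, so any global threshold that splits such pairs must exceed
  0.8 of the component maximum — but in a mixed-size cluster the smaller
  kernel's peak can be only ~0.67 of the component maximum, and such a
  threshold erases its marker entirely. A per-peak relative criterion
  resolves both cases.

Basins are additionally re-examined recursively (up to `max_rounds = 3`):
a basin cut free of its cluster is re-analysed with its own EDT, in which
the cut faces count as background. This matters because inside dense
clusters the EDT at a neck is inflated by neighbouring kernels (the
nearest background is farther away), hiding saddles from the first pass.

**Fine optimisation: convexity-defect splitting.** For every contour
(Moore boundary tracing on 8-connected components, counter-clockwise in
image coordinates) the convex hull is computed, and for each hull edge AB
the deepest contour point C on the subtended arc is found via the cross
product `|AB⃗ × AC⃗| / ||AB⃗||`. Defects at least `depth_threshold = 8` px
deep mark candidate adhesion points; wrinkle-scale surface concavities
stay below ~5 px, so the band between 5 and 8 px is treated as plausible
but not sufficient evidence. Cuts are made iteratively, deepest defect
first: the defect is paired with the nearest other defect point of the
same contour such that (i) the connecting segment lies entirely inside the
foreground, (ii) the two defects point towards each other rather than
sharing a single notch, (iii) the cut continues both intrusion directions,
and (iv) the segment's midpoint has interior clearance (a cut should pass
through a pinch, not hug the background). Partners may come from the 5–8 px
band; cuts are only ever *initiated* at ≥ 8 px defects. The cut is a
one-pixel 4-connected line, which an 8-connected foreground cannot bridge;
a cut that would create a fragment smaller than `min_piece` (in the
pipeline: 15% of the median basin area, the same floor used for counting)
is rejected. A defect with no admissible partner is cut along its depth
direction to the nearest boundary point only when that cut is shorter than
`fallback_len_factor = 0.8` times the defect depth: an isolated concavity
— in particular a damage bite on a single kernel — must not bisect the
object. Iteration stops when no actionable defect remains or after a cap
of 10 rounds per contour.

**Shape features.** Eight descriptors per kernel: pixel-count area;
chain-length perimeter (1 per axial, √2 per diagonal step); major axis
(largest hull-vertex distance, i.e. the rotating-calipers diameter); minor
axis (maximal extent perpendicular to the major direction); elongation
(major/minor); rectangularity (area over the minimum-area rotated
enclosing rectangle, computed by rotating calipers over hull edges);
eccentricity `sqrt(1 − minor²/major²)`; compactness `4π·area/perimeter²`
(1 for an ideal circle), with its reciprocal also reported as `roughness`.
Axes are measured by calipers rather than moment-based ellipse fitting
because the caliper reading matches the verbal definitions ("largest axial
dimension", "maximum dimension perpendicular to it") and reproduces the
reference descriptor rows exactly. Rectangularity measures numerator and
denominator in one geometry — the polygon through boundary pixel centres —
so a filled rectangle scores exactly 1 and the ratio never exceeds 1; the
record's `area` field remains the pixel count. Reference descriptor values
are displayed with 4-decimal *truncation*; the package reproduces them
under that convention.

**Classifier.** A soft-margin SVM (solver: libsvm via e1071; kernels,
feature protocol and class conventions live in this package). `damaged` is
the positive class. Features are standardized by default: they span four
orders of magnitude (area ~8000 px² versus eccentricity ~0.5), so
unstandardized RBF distances would be area-only. Defaults: RBF kernel with
γ = 0.1, polynomial degree 3 with offset r = 1 (the inhomogeneous form,
whose expansion retains all lower-order terms — with r = 0 the cubic
kernel discards them and underperforms the linear kernel on these
features), `C = 1` (unstated in the source method; exposed).
`train_and_evaluate()` trains on the pipeline's *own* segmentations of the
training images (labels transferred from ground truth by IoU matching):
kernels separated from a cluster carry watershed cut faces, and a
classifier trained on pristine masks would see a different feature
distribution at prediction time. The ground-truth-mask protocol remains
available (`train_on = "truth"`, and `generate_feature_dataset()` always
measures ground-truth masks).

## Ablation variants

`pipeline_config(variant = ...)` switches stages off to quantify each
stage's contribution. Two wordings needed a decision:

* `raw_wc_svm` ("skip preprocessing") retains grayscale conversion and
  Otsu — without *some* binarization there are no contours to count at
  all — and skips only the morphological cleanup. Speckles and debris then
  survive into the contour stage and, with the area floor disabled, appear
  as false contours.
* `c_svm` ("skip watershed") removes the watershed pre-segmentation but
  keeps convexity-defect splitting, applied directly to the binarized
  blobs; counting would otherwise be impossible. Hull splitting alone
  handles pairwise necks but degrades on large clusters, which is exactly
  the gap the watershed stage fills.
* `w_svm` ("skip convexity defects") floods but never cuts residual
  merges, so it can only undercount relative to the full pipeline.

## The synthetic scene generator

The generator stands in for a bench acquisition: 2000×1500 px frames,
~80–150 bright elliptical kernels (semi-axes 40–60 px) on a dark
background (level 30), grey levels 140–200 so the histogram is strongly
bimodal, a mild horizontal illumination ramp (0.008 grey/px) and sparse
specular salt-and-pepper speckles (density 5·10⁻⁴, 80% bright). Placement
is sequential: with probability `adhesion_probability` a kernel is placed
against a random existing kernel, at a centre distance bisected so the
pixel overlap hits a target drawn uniformly between 2% and `overlap_cap`
(default 0.45; the benchmark conditions use 0.3) of the smaller kernel's
area; otherwise it is placed clear of all existing kernels. Placement
failure after 200 attempts raises an explicit capacity error. All
randomness flows from one integer seed; scenes are bytewise reproducible.

Damage is a concave flank bite: an ellipse subtracted at a boundary point
on the kernel's side, with mouth 0.65–0.85 of the semi-major axis along
the kernel and inward depth drawn from `bite_depth_range = c(22, 42)` px
(curvature-compensated so the drawn depth is what a convexity-defect
detector measures, and capped at 1.15× the semi-minor axis so the kernel
stays connected). This models mechanically broken kernels: about a third
to a half of the area is lost, elongation and eccentricity rise and
compactness falls — the direction and rough magnitude of reference
measurements of damaged versus normal kernels. The long mouth keeps the
bitten kernel's EDT ridge single-peaked, which is also geometrically
honest: a broken kernel is missing a flank, not pierced through the
middle. Earlier in development a shallow "surface chip" model (depths
9–14 px) was tried and discarded: it neither matched the reference damaged
kernel morphology nor produced statistically separable classes.

What the generator does **not** emulate: kernel surface texture and
wrinkles, colour variation between kernels, 3-D stacking and perspective
occlusion, shadows, or camera noise beyond salt-and-pepper speckles.
Passing the synthetic benchmark therefore demonstrates the geometric
correctness of the separation-and-measurement chain under controlled
adhesion and damage, not robustness to photometric variation in real
images.

## Benchmark problem sizes

The acceptance suite runs the full pipeline on twenty 2000×1500 scenes of
100 kernels each (adhesion probability 0.5, overlap cap 0.3, damage
fraction 0.3, seeds 0–19), with the classifier trained on ten separate
800×600 scenes of 25 kernels; the kernel-ranking comparison uses fifteen
800×600 scenes of 20 kernels with a 12/3 image-level split. Unit and
property tests use smaller fixtures (two-kernel scenes, 32×32 oracle
masks, 1000 random triples).

## Numerical choices and degenerate inputs

* Otsu on a constant image, an all-foreground distance transform, an empty
  marker set, single-class training data and an empty post-binarization
  foreground all raise explicit errors rather than returning defaults.
* Undefined evaluation metrics (zero denominators) are `NA`, never 0 or
  100.
* Contours with fewer than 3 points, or collinear point sets, are rejected
  by the hull and axis computations and skipped by feature extraction
  (counting handles them through the area floor instead).
* The area floor for counting (and the fragment floor for cuts) defaults
  to 15% of the median contour area in the scene — relative, so no
  absolute kernel size is assumed.
* Instance matching is greedy one-to-one by descending IoU with a 0.5
  floor, the standard instance-segmentation convention; unmatched
  ground-truth kernels are tallied as missed detections and never enter
  the confusion counts.
* Determinism: the generator restores the caller's RNG state; the flood
  breaks priority ties by insertion order; libsvm is deterministic for
  fixed inputs.

## Known limitations

* Pairs overlapping near the 30% cap produce necks whose notch depth falls
  toward the 8 px threshold and whose EDT saddle approaches the peak;
  some such pairs stay merged. This is the method's stated operating
  boundary, not an implementation artefact.
* A collinear tip-to-tip chain of three kernels can present both necks
  under a single hull edge, in which case only the deeper notch is seen
  per iteration and the pairing rule may find no admissible cut; staggered
  chains (the generic case for scattered kernels) split correctly.
* The damage classifier learns the generator's bite morphology; on real
  images it should be retrained on features extracted from the pipeline's
  segmentation of annotated frames, exactly as `train_and_evaluate()`
  does.
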