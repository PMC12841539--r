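# maizeseg

Instance segmentation of **adhered (touching) maize kernels** in 2-D images
and per-kernel **mechanical-damage classification**, for quality control in
corn processing and breeding laboratories where kernels are scattered on a
dark matte background and naturally stick together in clusters.

Touching kernels binarize into a single connected blob, so a plain
threshold-and-count approach under-counts and mis-measures every kernel in a
cluster. Deep networks solve this only with large annotated datasets, which
small labs rarely have. `maizeseg` implements a classical hybrid that needs
no annotated images at all for segmentation and only a small labelled sample
for damage classification:

1. **Preprocessing** — grayscale conversion
   (`Gray = 0.299 R + 0.587 G + 0.114 B`), Otsu binarization by maximising
   the inter-class variance
   σ²_B(t) = ω₁(μ₁ − μ)² + ω₂(μ₂ − μ)² over all 256 thresholds, then a
   morphological opening and closing (3×3 element) to remove specular
   speckles and fill pinholes.
2. **Coarse segmentation** — a marker-controlled watershed. Markers are
   peaks of the exact Euclidean distance transform
   `D(x,y) = min over background (x',y') of ||(x,y) − (x',y')||`,
   found by persistence analysis (two peaks stay distinct when the saddle
   between them is low relative to the lower peak); flooding runs over the
   negated distance field with a priority queue (a smoothed Sobel gradient
   surface is available as the alternative height). Basins are re-examined
   recursively so necks hidden inside dense clusters are still found.
3. **Fine optimisation** — convexity-defect splitting. For each contour and
   each convex-hull edge AB, the deepest contour point C has depth
   `|AB⃗ × AC⃗| / ||AB⃗||`; defects deeper than 8 px mark adhesion necks
   (surface wrinkles stay below ~5 px). Matching defect pairs are joined by
   a one-pixel cut, separating kernels the watershed left merged.
4. **Shape features** — per separated kernel: area, perimeter, major and
   minor axis, elongation (major/minor), rectangularity (area over the
   minimum-area rotated rectangle), eccentricity √(1 − minor²/major²) and
   compactness 4πA/P².
5. **SVM damage classification** — a soft-margin SVM on the 8 standardized
   features with linear, RBF (`exp(−γ||x₁−x₂||²)`, γ = 0.1) or polynomial
   (`(γ x₁·x₂ + r)^d`, d = 3) kernels; `damaged` is the positive class.

A seeded synthetic scene generator (`scene_spec()` / `generate_scene()`)
produces adhered-kernel scenes with exact per-kernel ground truth and
drives the evaluation suite: counting accuracy, per-kernel confusion
metrics (Acc/P/R/F1), IoU and Dice, and greedy one-to-one instance
matching. Pipeline ablation variants (`raw_wc_svm`, `c_svm`, `w_svm`)
switch individual stages off.

## Worked example

```r
library(maizeseg)

# one synthetic acquisition: 20 kernels, half placed touching a neighbour,
# 30% with a mechanical-damage bite
spec  <- scene_spec(image_width = 800, image_height = 600, n_kernels = 20,
                    adhesion_probability = 0.5, damage_fraction = 0.3,
                    overlap_cap = 0.3, rng_seed = 7)
scene <- generate_scene(spec)

# train the damage classifier on six other seeded scenes, using the
# pipeline's own segmentations for the training features
train_specs <- lapply(1:6, function(s)
  scene_spec(image_width = 800, image_height = 600, n_kernels = 20,
             adhesion_probability = 0.5, damage_fraction = 0.3,
             overlap_cap = 0.3, rng_seed = 100 + s))
train <- do.call(rbind, lapply(train_specs, function(sp)
  scene_pipeline_features(generate_scene(sp), pipeline_config())))
model <- svm_fit(train, svm_config("rbf", gamma = 0.1))

res <- run_pipeline(scene, pipeline_config(), model = model)
res$count
#> [1] 20
head(res$records[, c("id","area","perimeter","elongation","compactness","label")], 5)
#>   id area perimeter elongation compactness   label
#> 1  1 8305     341.9      1.295      0.8925  intact
#> 2  2 2630     215.4      1.417      0.7125 damaged
#> 3  3 9088     372.6      1.171      0.8227  intact
#> 4  4 8077     337.6      1.025      0.8907  intact
#> 5  5 6947     314.2      1.077      0.8840  intact
```

All 20 kernels are separated (`count` = 20, counting accuracy 100%); each
record is one kernel with its eight descriptors and the classifier's
verdict — record 2 is a bitten kernel: one third the area of its intact
neighbours, more elongated, and clearly less compact. Scoring against the
generator's ground truth:

```r
pc <- rep("unknown", max(res$labels)); pc[res$records$id] <- res$records$label
mi <- match_instances(res$labels, scene$truth, pred_classes = pc)
unlist(confusion_metrics(mi$confusion))
#> Acc   P   R  F1
#> 100 100 100 100
mean(mi$iou)
#> [1] 0.896
```

## Command line

A thin CLI over the same functions ships in `inst/cli/maizeseg`
(subcommands `generate`, `segment`, `train`, `evaluate`, `ablate`;
configuration via a YAML file mirroring `pipeline_config()` and
`scene_spec()`).

## Limitations

The method assumes bright, convex-ish kernels on a dark background.
Collinear tip-to-tip chains whose necks share a single hull edge, and pairs
overlapping beyond ~30% of the smaller kernel's area, may stay merged; see
the methods vignette for the full discussion.
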