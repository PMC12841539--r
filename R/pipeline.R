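#' Pipeline configuration and ablation variants
#'
#' The full pipeline (`"wc_svm"`) runs: preprocessing (grayscale, Otsu,
#' opening/closing), marker-controlled watershed on the distance transform,
#' convexity-defect refinement of the basins, feature extraction and (when a
#' model is supplied) SVM classification. The ablation variants switch
#' stages off:
#' * `"raw_wc_svm"` skips the morphological cleanup (speckles and debris
#'   survive into the contour stage);
#' * `"c_svm"` skips the watershed pre-segmentation (defect splitting runs
#'   directly on the binarized blobs);
#' * `"w_svm"` skips the convexity-defect refinement (residual adhesions
#'   stay merged).
#'
#' @param variant one of `"wc_svm"`, `"raw_wc_svm"`, `"c_svm"`, `"w_svm"`.
#' @param se structuring element for the cleanup (default 3x3 cross).
#' @param sigma Gaussian sigma for gradient smoothing (used when
#'   `height = "gradient"`).
#' @param height flooding surface: `"distance"` (negated distance transform,
#'   default) or `"gradient"` (smoothed Sobel magnitude).
#' @param peak_fraction,marker_method,saddle_ratio,prominence_min,marker_min_area
#'   marker extraction settings, see [extract_markers()].
#' @param depth_threshold convexity-defect depth threshold in px (default 8).
#' @param min_area contour area floor for counting; NULL = 15% of the median
#'   contour area (see [count_objects()]).
#' @param svm an [svm_config()].
#' @param iou_floor IoU floor for instance matching (default 0.5).
#' @param seed integer seed for any stochastic step.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = c("wc_svm", "raw_wc_svm", "c_svm", "w_svm"),
                            se = se_cross(3L), sigma = 1.5,
                            height = c("distance", "gradient"),
                            peak_fraction = 0.4, marker_method = "peaks",
                            saddle_ratio = 0.95, prominence_min = 3,
                            marker_min_area = 5L, depth_threshold = 8,
                            min_area = NULL, svm = svm_config(),
                            iou_floor = 0.5, seed = 1L) {
  structure(
    list(
      variant = match.arg(variant), se = se, sigma = sigma,
      height = match.arg(height), peak_fraction = peak_fraction,
      marker_method = marker_method, saddle_ratio = saddle_ratio,
      prominence_min = prominence_min, marker_min_area = marker_min_area,
      depth_threshold = depth_threshold, min_area = min_area, svm = svm,
      iou_floor = iou_floor, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the segmentation pipeline on one image
#'
#' Executes the stages selected by the configuration variant and returns the
#' instance label map, one kernel record per separated contour (classified
#' when a model is supplied) and the object count.
#'
#' @param x an image array, a `maize_scene`, or a path readable by
#'   [read_image()].
#' @param config a [pipeline_config()].
#' @param model optional [svm_fit()] model for damage classification.
#' @return list of class `pipeline_result`: `labels` (instance map),
#'   `records` (kernel features, with predicted labels if a model was
#'   given), `count` (objects above the area floor), `contours`, `mask`,
#'   `timings` (seconds per stage) and `config`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), model = NULL) {
  if (is.character(x)) x <- read_image(x)
  if (inherits(x, "maize_scene")) x <- x$image
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pp <- preprocess_image(x,
    se = config$se,
    morphology = config$variant != "raw_wc_svm"
  )
  mask <- pp$mask
  if (!any(mask == 1L)) stop("empty foreground after binarization [stage: preprocess]")
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  if (config$variant %in% c("wc_svm", "raw_wc_svm", "w_svm")) {
    hgt <- if (config$height == "gradient") {
      smooth_gradient(sobel_gradient(pp$gray), sigma = config$sigma)$g
    } else {
      NULL
    }
    ws <- watershed_segment(mask,
      peak_fraction = config$peak_fraction, method = config$marker_method,
      saddle_ratio = config$saddle_ratio,
      prominence_min = config$prominence_min,
      min_area = config$marker_min_area, height = hgt
    )
    labels <- ws$labels
  } else {
    labels <- cpp_label_components(mask, 8L)
  }
  timings["watershed"] <- tic() - t0

  t0 <- tic()
  if (config$variant != "w_svm") {
    labels <- refine_labels(labels, depth_threshold = config$depth_threshold)
  }
  timings["hull_refine"] <- tic() - t0

  t0 <- tic()
  contours <- extract_contours(labels)
  records <- extract_features(contours)
  count <- count_objects(contours, min_area = config$min_area)
  if (!is.null(model) && nrow(records) > 0L) {
    records$label <- svm_predict(model, records)
  }
  timings["features"] <- tic() - t0

  structure(
    list(
      labels = labels, records = records, count = count, contours = contours,
      mask = mask, timings = timings, config = config
    ),
    class = "pipeline_result"
  )
}

#' Features of pipeline-segmented kernels, labelled from ground truth
#'
#' Runs the segmentation pipeline on a synthetic scene and labels every
#' segmented kernel that matches a ground-truth kernel (IoU matching) with
#' the true intact/damaged class. Training a classifier on these records --
#' rather than on pristine ground-truth masks -- keeps the training and
#' prediction feature distributions identical: separated kernels carry
#' watershed cut faces in both.
#'
#' @param scene a `maize_scene`.
#' @param config a [pipeline_config()].
#' @return data frame of labelled kernel records (unmatched segments are
#'   dropped).
#' @export
scene_pipeline_features <- function(scene, config = pipeline_config()) {
  res <- run_pipeline(scene, config)
  mi <- match_instances(res$labels, scene$truth, iou_floor = config$iou_floor)
  recs <- res$records[res$records$id %in% mi$matches$pred_id, , drop = FALSE]
  recs$label <- scene$truth$damage_labels[
    mi$matches$truth_id[match(recs$id, mi$matches$pred_id)]
  ]
  recs
}

#' Train on synthetic scenes and evaluate on a held-out split
#'
#' Generates the scenes, assigns whole images to an 80/20 train/test split,
#' fits the damage classifier on kernel features of the training images,
#' then runs the full pipeline on each test image and scores it against the
#' ground truth: counting accuracy, per-kernel confusion metrics over
#' IoU-matched instances, and mean matched IoU/Dice.
#'
#' By default training features come from the pipeline's own segmentation of
#' the training images (see [scene_pipeline_features()]); `train_on =
#' "truth"` uses pristine ground-truth masks instead.
#'
#' @param spec_list list of [scene_spec()] objects.
#' @param config a [pipeline_config()].
#' @param split_fraction training fraction of images (default 0.8).
#' @param train_on `"pipeline"` (default) or `"truth"`.
#' @return list of class `metric_report`: `Acc`, `P`, `R`, `F1` (percent),
#'   `counting_accuracy` (mean percent over test images), `IoU`, `Dice`
#'   (mean over matched kernels), `confusion`, `n_matched`, `n_missed`,
#'   `per_image` (data frame) and `model`.
#' @export
train_and_evaluate <- function(spec_list, config = pipeline_config(),
                               split_fraction = 0.8,
                               train_on = c("pipeline", "truth")) {
  train_on <- match.arg(train_on)
  if (length(spec_list) < 2L) stop("need at least 2 scenes (one per split)")
  ds <- generate_feature_dataset(spec_list,
    split_fraction = split_fraction,
    rng_seed = config$seed
  )
  train_tab <- if (train_on == "truth") {
    ds$train
  } else {
    do.call(rbind, lapply(ds$train_scenes, function(i) {
      scene_pipeline_features(generate_scene(spec_list[[i]]), config)
    }))
  }
  model <- svm_fit(train_tab, config$svm)
  agg <- confusion_counts()
  iou_all <- numeric(0)
  dice_all <- numeric(0)
  per_image <- NULL
  n_missed <- 0L
  for (i in ds$test_scenes) {
    scene <- generate_scene(spec_list[[i]])
    res <- run_pipeline(scene, config, model = model)
    pred_classes <- rep("unknown", max(res$labels, 1L))
    pred_classes[res$records$id] <- res$records$label
    mi <- match_instances(res$labels, scene$truth,
      iou_floor = config$iou_floor,
      pred_classes = pred_classes
    )
    if (!is.null(mi$confusion)) {
      for (f in c("TN", "TD", "FN", "FD")) agg[[f]] <- agg[[f]] + mi$confusion[[f]]
    }
    iou_all <- c(iou_all, mi$iou)
    dice_all <- c(dice_all, 2 * mi$iou / (1 + mi$iou))
    n_missed <- n_missed + length(mi$missed_truth)
    per_image <- rbind(per_image, data.frame(
      scene = i, actual = scene$truth$true_count, detected = res$count,
      counting_accuracy = counting_accuracy(scene$truth$true_count, res$count),
      matched = nrow(mi$matches), missed = length(mi$missed_truth)
    ))
  }
  cm <- confusion_metrics(agg)
  structure(
    c(cm, list(
      counting_accuracy = mean(per_image$counting_accuracy),
      IoU = if (length(iou_all)) mean(iou_all) else NA_real_,
      Dice = if (length(dice_all)) mean(dice_all) else NA_real_,
      confusion = agg, n_matched = sum(per_image$matched),
      n_missed = n_missed, per_image = per_image, model = model
    )),
    class = "metric_report"
  )
}

#' Run all four ablation variants on the same scenes
#'
#' Produces a counting comparison across the pipeline variants, one row per
#' variant with the pooled actual and detected counts and the mean
#' per-image counting accuracy.
#'
#' @param spec_list list of [scene_spec()] objects.
#' @param config base [pipeline_config()] (its variant field is ignored).
#' @param model optional classifier to attach damage predictions.
#' @return data frame with columns `variant`, `actual`, `detected`,
#'   `counting_accuracy`.
#' @export
ablate <- function(spec_list, config = pipeline_config(), model = NULL) {
  variants <- c("wc_svm", "raw_wc_svm", "c_svm", "w_svm")
  scenes <- lapply(spec_list, generate_scene)
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    det <- vapply(scenes, function(sc) {
      run_pipeline(sc, cfg, model = model)$count
    }, numeric(1))
    acc <- 100 * det / vapply(scenes, function(sc) sc$truth$true_count, numeric(1))
    data.frame(
      variant = v,
      actual = sum(vapply(scenes, function(sc) sc$truth$true_count, numeric(1))),
      detected = sum(det),
      counting_accuracy = mean(acc)
    )
  })
  do.call(rbind, rows)
}
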