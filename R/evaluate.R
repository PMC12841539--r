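#' Confusion counts for damage classification
#'
#' The 2x2 confusion matrix in the TN/TD/FN/FD labelling: rows are the real
#' class, columns the predicted class, with `damaged` as the positive class.
#' `TN` = true normal (intact predicted intact), `TD` = true damaged,
#' `FD` = intact predicted damaged, `FN` = damaged predicted intact.
#'
#' @param TN,TD,FN,FD non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TN = 0L, TD = 0L, FN = 0L, FD = 0L) {
  v <- c(TN = TN, TD = TD, FN = FN, FD = FD)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(as.integer(v)), names = names(v), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1, all as percentages:
#' `Acc = (TN+TD)/total`, `P = TD/(TD+FD)`, `R = TD/(FN+TD)`,
#' `F1 = 2PR/(P+R)`. A metric whose denominator is zero is undefined and
#' reported as `NA`, never coerced to 0 or 100.
#'
#' @param counts a [confusion_counts()].
#' @return named list `Acc`, `P`, `R`, `F1` (percent, or `NA` if undefined).
#' @export
confusion_metrics <- function(counts) {
  tn <- counts$TN; td <- counts$TD; fn <- counts$FN; fd <- counts$FD
  total <- tn + td + fn + fd
  acc <- if (total > 0) 100 * (tn + td) / total else NA_real_
  p <- if (td + fd > 0) 100 * td / (td + fd) else NA_real_
  r <- if (fn + td > 0) 100 * td / (fn + td) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  list(Acc = acc, P = p, R = r, F1 = f1)
}

#' Counting accuracy
#'
#' `100 * detected / actual`: the percentage of the manual ground-truth count
#' recovered by the detector.
#'
#' @param actual true object count (> 0).
#' @param detected detected object count.
#' @return percentage.
#' @export
counting_accuracy <- function(actual, detected) {
  if (actual <= 0) stop("actual count must be positive")
  100 * detected / actual
}

#' Mask overlap: IoU and Dice
#'
#' `IoU = |A n B| / |A u B|`; `Dice = 2 |A n B| / (|A| + |B|)`. Two empty
#' masks overlap perfectly by convention (both metrics 1).
#'
#' @param pred,truth 0/1 matrices of equal size.
#' @return named numeric vector `c(iou, dice)`.
#' @export
mask_overlap <- function(pred, truth) {
  pred <- pred != 0
  truth <- truth != 0
  if (!all(dim(pred) == dim(truth))) stop("mask sizes differ")
  inter <- sum(pred & truth)
  a <- sum(pred)
  b <- sum(truth)
  uni <- a + b - inter
  c(
    iou = if (uni == 0) 1 else inter / uni,
    dice = if (a + b == 0) 1 else 2 * inter / (a + b)
  )
}

#' Match predicted instances to ground-truth kernels
#'
#' Greedy one-to-one matching by descending IoU: candidate (prediction,
#' truth) pairs with IoU at or above `iou_floor` are accepted best-first,
#' each prediction and each truth kernel matched at most once. When
#' per-kernel class labels are supplied, matched pairs accumulate into a
#' [confusion_counts()]; unmatched ground-truth kernels are tallied
#' separately as missed detections (they never enter the confusion counts).
#'
#' @param pred_labels integer instance label map (`1..K`, 0 background).
#' @param truth a `scene_truth` (see [generate_scene()]).
#' @param iou_floor minimum IoU for a match (default 0.5).
#' @param pred_classes optional character vector of predicted labels, indexed
#'   by prediction instance id.
#' @return list with `matches` (data frame `pred_id`, `truth_id`, `iou`),
#'   `confusion` (a `confusion_counts`, or NULL when no classes supplied),
#'   `iou` (per matched truth kernel), `missed_truth` and `unmatched_pred`
#'   (ids).
#' @export
match_instances <- function(pred_labels, truth, iou_floor = 0.5,
                            pred_classes = NULL) {
  if (iou_floor <= 0 || iou_floor >= 1) stop("iou_floor must lie in (0, 1)")
  storage.mode(pred_labels) <- "integer"
  npred <- max(pred_labels, 0L)
  pred_sizes <- if (npred > 0L) tabulate(pred_labels[pred_labels > 0L], npred) else integer(0)
  cand <- list()
  for (k in seq_along(truth$masks)) {
    m <- truth$masks[[k]]
    bb <- m$bbox
    sub <- pred_labels[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    ids <- sub[m$mask]
    ids <- ids[ids > 0L]
    if (length(ids) == 0L) next
    tb <- table(ids)
    ta <- sum(m$mask)
    for (nm in names(tb)) {
      pid <- as.integer(nm)
      inter <- as.integer(tb[[nm]])
      iou <- inter / (pred_sizes[pid] + ta - inter)
      if (iou >= iou_floor) {
        cand[[length(cand) + 1L]] <- c(pid, k, iou)
      }
    }
  }
  matches <- data.frame(pred_id = integer(), truth_id = integer(), iou = numeric())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 2], cm[, 1]), , drop = FALSE]
    used_p <- logical(npred)
    used_t <- logical(length(truth$masks))
    for (i in seq_len(nrow(cm))) {
      p <- cm[i, 1]; t <- cm[i, 2]
      if (used_p[p] || used_t[t]) next
      used_p[p] <- TRUE
      used_t[t] <- TRUE
      matches <- rbind(matches, data.frame(pred_id = p, truth_id = t, iou = cm[i, 3]))
    }
  }
  confusion <- NULL
  if (!is.null(pred_classes) && nrow(matches) > 0L) {
    real <- truth$damage_labels[matches$truth_id]
    pred <- pred_classes[matches$pred_id]
    confusion <- confusion_counts(
      TN = sum(real == "intact" & pred == "intact"),
      TD = sum(real == "damaged" & pred == "damaged"),
      FN = sum(real == "damaged" & pred == "intact"),
      FD = sum(real == "intact" & pred == "damaged")
    )
  }
  list(
    matches = matches,
    confusion = confusion,
    iou = matches$iou,
    missed_truth = setdiff(seq_along(truth$masks), matches$truth_id),
    unmatched_pred = setdiff(seq_len(npred), matches$pred_id)
  )
}
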