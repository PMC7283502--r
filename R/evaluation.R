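#' Intersection-over-Union of two boxes
#'
#' Overlap area divided by union area under the half-open pixel convention;
#' disjoint boxes give 0 and identical boxes give 1, the ideal complete
#' overlap.
#'
#' @param a,b boxes ([bounding_box()] or length-4 `xmin, ymin, xmax, ymax`).
#' @return a ratio in `[0, 1]`.
#' @examples
#' iou(bounding_box(0, 0, 2, 2), bounding_box(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- as.numeric(a)[1:4]; b <- as.numeric(b)[1:4]
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4]) {
    stopf("degenerate box in iou()", class = "strawdetect_invalid_box")
  }
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Confusion counts for detection
#'
#' @param tp,tn,fp,fn non-negative tallies of true positives, true
#'   negatives, false positives and false negatives. A true positive is a
#'   region correctly classified as a strawberry, a true negative a region
#'   correctly classified as background.
#' @return an object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) stopf("confusion counts must be >= 0",
                        class = "strawdetect_invalid_argument")
  structure(as.list(v), class = "confusion_counts")
}

#' Matching protocol for detections against ground truth
#'
#' Detection has no natural true-negative region; the protocol
#' operationalises TN as background grid cells (default 64 px) intersecting
#' neither a prediction nor a truth box, and this protocol is reported with
#' every accuracy figure.
#'
#' @param iou_threshold minimum IOU for a prediction to claim a truth box
#'   (default 0.5, the detection-literature standard).
#' @param tn_cell_size grid cell edge in pixels for the TN protocol.
#' @return an object of class `"match_spec"`.
#' @export
match_spec <- function(iou_threshold = 0.5, tn_cell_size = 64L) {
  if (!(iou_threshold > 0 && iou_threshold < 1)) {
    stopf("iou_threshold must lie strictly in (0, 1)",
          class = "strawdetect_invalid_config")
  }
  structure(list(iou_threshold = iou_threshold,
                 tn_cell_size = as.integer(tn_cell_size),
                 matching = "greedy-by-score"),
            class = "match_spec")
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending score order: each prediction
#' claims the unclaimed truth box of highest IOU, provided IOU is at least
#' the threshold. TP = matches, FP = unmatched predictions, FN = unmatched
#' truths; TN = background grid cells free of both (0 when `image_size` is
#' not supplied).
#'
#' @param pred a [detection_result()] (or an n x 4 box matrix, taken in row
#'   order).
#' @param truth ground-truth boxes in any form accepted by [box_matrix()].
#' @param spec a [match_spec()].
#' @param image_size optional `c(width, height)` enabling the TN protocol.
#' @return a [confusion_counts()].
#' @export
match_detections <- function(pred, truth, spec = match_spec(),
                             image_size = NULL) {
  pm <- if (inherits(pred, "detection_result")) pred$boxes else box_matrix(pred)
  tm <- box_matrix(truth)
  np <- nrow(pm); nt <- nrow(tm)
  used <- rep(FALSE, nt)
  tp <- 0L
  for (i in seq_len(np)) {
    best <- 0; best_j <- 0L
    for (j in seq_len(nt)) {
      if (used[j]) next
      o <- iou(pm[i, ], tm[j, ])
      if (o > best) { best <- o; best_j <- j }
    }
    if (best_j > 0L && best >= spec$iou_threshold) {
      used[best_j] <- TRUE
      tp <- tp + 1L
    }
  }
  tn <- 0L
  if (!is.null(image_size)) {
    tn <- count_background_cells(rbind(pm, tm), image_size, spec$tn_cell_size)
  }
  confusion_counts(tp = tp, tn = tn, fp = np - tp, fn = nt - tp)
}

count_background_cells <- function(boxes, image_size, cell) {
  nx <- max(1L, floor(image_size[1] / cell))
  ny <- max(1L, floor(image_size[2] / cell))
  free <- 0L
  for (gy in seq_len(ny) - 1L) for (gx in seq_len(nx) - 1L) {
    cx1 <- gx * cell; cy1 <- gy * cell
    cx2 <- cx1 + cell; cy2 <- cy1 + cell
    hit <- FALSE
    for (i in seq_len(nrow(boxes))) {
      if (boxes[i, 1] < cx2 && boxes[i, 3] > cx1 &&
          boxes[i, 2] < cy2 && boxes[i, 4] > cy1) { hit <- TRUE; break }
    }
    if (!hit) free <- free + 1L
  }
  free
}

#' Detection evaluation indices
#'
#' `accuracy()` is `(TP + TN) / (TP + TN + FP + FN)`; `precision()` is
#' `TP / (TP + FP)`; `recall()` is `TP / (TP + FN)`; `f_measure()` is the
#' harmonic mean of precision and recall, 0 when TP = 0. Note the index
#' usually printed alongside detection results under the name "Precision"
#' is the accuracy formula above; this package names that index accuracy
#' and provides the standard precision separately.
#'
#' @param c a [confusion_counts()].
#' @return a ratio in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stopf("accuracy undefined on all-zero counts",
                        class = "strawdetect_undefined_metric")
  (c$tp + c$tn) / total
}

#' @rdname accuracy
#' @export
precision <- function(c) if (c$tp + c$fp == 0) 0 else c$tp / (c$tp + c$fp)

#' @rdname accuracy
#' @export
recall <- function(c) if (c$tp + c$fn == 0) 0 else c$tp / (c$tp + c$fn)

#' @rdname accuracy
#' @export
f_measure <- function(c) {
  if (c$tp == 0) return(0)
  p <- precision(c); r <- recall(c)
  2 * p * r / (p + r)
}

#' Average running time per image
#'
#' @param total_time total processing time in seconds over all images.
#' @param n_images number of images processed (>= 1).
#' @return seconds per image.
#' @export
art <- function(total_time, n_images) {
  if (n_images < 1) stopf("n_images must be >= 1",
                          class = "strawdetect_invalid_argument")
  if (total_time < 0) stopf("total_time must be >= 0",
                            class = "strawdetect_invalid_argument")
  total_time / n_images
}

#' Count-correlation statistics
#'
#' Pearson correlation R and normalized root-mean-square error between
#' per-image predicted counts and manual counts; NRMSE is the RMSE divided
#' by the mean manual count.
#'
#' @param pred_counts,manual_counts equal-length numeric vectors (n >= 2).
#' @return `list(r, nrmse)`.
#' @export
count_statistics <- function(pred_counts, manual_counts) {
  if (length(pred_counts) != length(manual_counts) ||
      length(pred_counts) < 2L) {
    stopf("count vectors must have equal length >= 2",
          class = "strawdetect_invalid_argument")
  }
  if (stats::sd(pred_counts) == 0 || stats::sd(manual_counts) == 0) {
    stopf("R undefined: a count vector has zero variance",
          class = "strawdetect_undefined_metric")
  }
  r <- stats::cor(pred_counts, manual_counts)
  rmse <- sqrt(mean((pred_counts - manual_counts)^2))
  list(r = r, nrmse = rmse / mean(manual_counts))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %g TN %g FP %g FN %g>\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
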