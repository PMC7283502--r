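# Operational constants of the occlusion/adhesion post-processing.
# None of these are dictated by the detection model; they were fixed once by
# tuning on the synthetic fixtures and are used everywhere:
#   red_dominance  — minimum R - max(G, B) for a pixel to count as fruit
#   red_floor      — minimum red level for a fruit pixel
#   solidity_min   — a component is shape-isolated iff area / hull area >= this
#   min_region_px  — smaller components are too small to split (reported isolated)
#   curvature_window — arc-length half-window (points) for finite differences
#   smooth_window  — circular moving-average width applied to the contour
#   mad_mult       — |curvature - median| > mad_mult * MAD flags an outlier
#   seed_merge_px  — watershed seed-merge radius (EBImage `ext`)
.pp_const <- list(red_dominance = 0.10, red_floor = 0.25,
                  solidity_min = 0.92, min_region_px = 20L,
                  curvature_window = 7L, smooth_window = 5L,
                  mad_mult = 3, seed_merge_px = 5L)

#' Binarize fruit regions
#'
#' Converts an RGB scene to a binary fruit mask via a red-dominance
#' threshold (fruit pixels are those whose red channel dominates green and
#' blue), cleaned by a morphological open and close with a 3 x 3 element,
#' then labels connected components and traces their contours. The
#' operation is deterministic.
#'
#' @param image H x W x 3 array in `[0, 1]`, or an `annotated_image`.
#' @return an object of class `"region_mask"`: `mask` (logical matrix),
#'   `labels` (integer matrix), `label_count`, `contours` (list of closed
#'   n x 2 `(row, col)` chains, 1-based).
#' @export
binarize <- function(image) {
  if (inherits(image, "annotated_image")) image <- image$pixels
  assert_image(image)
  k <- .pp_const
  fg <- (image[, , 1] - pmax(image[, , 2], image[, , 3])) > k$red_dominance &
    image[, , 1] > k$red_floor
  fg <- matrix(as.numeric(fg), nrow(fg), ncol(fg))
  brush <- EBImage::makeBrush(3, shape = "box")
  fg <- EBImage::closing(EBImage::opening(fg, brush), brush)
  region_mask_from_binary(fg > 0.5)
}

region_mask_from_binary <- function(mask) {
  labels <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  structure(list(mask = labels > 0L, labels = labels,
                 label_count = max(labels),
                 contours = trace_contours(labels)),
            class = "region_mask")
}

trace_contours <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(list())
  oc <- EBImage::ocontour(labels)
  lapply(oc, function(m) {
    # EBImage returns 0-based (dim1, dim2) coordinates; convert to 1-based
    cbind(row = m[, 1] + 1L, col = m[, 2] + 1L)
  })
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask: %d component(s), %d foreground px>\n",
              x$label_count, sum(x$mask)))
  invisible(x)
}

#' Contour curvature profile
#'
#' Signed curvature (1/pixels) along a closed contour, estimated by finite
#' differences over an arc-length window (default 7 points) on the
#' circularly smoothed chain. At a junction between two adhered fruit, or
#' where an occluder cuts a fruit's edge, the curvature changes abruptly;
#' points where `|curvature - median| > 3 * MAD` are flagged as outliers.
#' The sign convention is normalised so that convexity with respect to the
#' region interior is positive.
#'
#' @param contour n x 2 matrix of `(row, col)` contour points in traversal
#'   order (closed chain).
#' @param window finite-difference window in points (odd, default 7).
#' @return an object of class `"curvature_profile"`: `points`, `curvature`
#'   and `outlier_flags` (all of length n). A contour shorter than the
#'   window yields an empty profile.
#' @export
curvature_profile <- function(contour, window = .pp_const$curvature_window) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < window) {
    return(structure(list(points = contour,
                          curvature = numeric(0),
                          outlier_flags = logical(0)),
                     class = "curvature_profile"))
  }
  sm <- circular_smooth(contour, .pp_const$smooth_window)
  h <- max(1L, (as.integer(window) - 1L) %/% 2L)
  idx <- seq_len(n)
  ip <- ((idx - 1L + h) %% n) + 1L
  im <- ((idx - 1L - h) %% n) + 1L
  x <- sm[, 2]; y <- sm[, 1]
  dx <- (x[ip] - x[im]) / (2 * h)
  dy <- (y[ip] - y[im]) / (2 * h)
  ddx <- (x[ip] - 2 * x + x[im]) / h^2
  ddy <- (y[ip] - 2 * y + y[im]) / h^2
  denom <- (dx^2 + dy^2)^1.5
  curv <- ifelse(denom < 1e-9, 0, (dx * ddy - dy * ddx) / pmax(denom, 1e-9))
  if (stats::median(curv) < 0) curv <- -curv
  med <- stats::median(curv)
  # MAD with a small absolute floor so that flat-sided contours (MAD = 0)
  # still flag their corners; deviations below 0.003 1/px are never outliers
  dev <- max(stats::mad(curv), 1e-3)
  flags <- abs(curv - med) > .pp_const$mad_mult * dev
  structure(list(points = contour, curvature = curv, outlier_flags = flags),
            class = "curvature_profile")
}

circular_smooth <- function(pts, w) {
  n <- nrow(pts)
  if (w <= 1L || n < w) return(pts)
  h <- (w - 1L) %/% 2L
  out <- pts
  for (d in 1:2) {
    v <- pts[, d]
    acc <- v
    for (o in seq_len(h)) {
      acc <- acc + v[((seq_len(n) - 1L + o) %% n) + 1L] +
        v[((seq_len(n) - 1L - o) %% n) + 1L]
    }
    out[, d] <- acc / (2 * h + 1)
  }
  out
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile: %d point(s), %d outlier(s)>\n",
              nrow(x$points), sum(x$outlier_flags)))
  invisible(x)
}

#' Is a region isolated?
#'
#' Shape analysis deciding whether a connected component is a single,
#' unoccluded fruit. The operational definition of "isolated" is: solidity
#' (area over convex-hull area) at least 0.92 AND no curvature outliers on
#' the contour. Components smaller than 20 pixels are indeterminate and
#' reported as isolated (too small to split).
#'
#' @param region logical matrix holding one connected component.
#' @return `TRUE` or `FALSE`.
#' @export
is_isolated <- function(region) {
  region <- region > 0
  area <- sum(region)
  if (area < .pp_const$min_region_px) return(TRUE)
  pix <- which(region, arr.ind = TRUE)
  hull_idx <- grDevices::chull(pix[, 2], pix[, 1])
  hx <- pix[hull_idx, 2]; hy <- pix[hull_idx, 1]
  # shoelace on pixel centres, plus half-perimeter boundary correction
  nh <- length(hx)
  j <- c(nh, seq_len(nh - 1L))
  hull_area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  hull_area <- hull_area + per / 2 + 1
  solidity <- area / hull_area
  if (solidity < .pp_const$solidity_min) return(FALSE)
  lab <- region_mask_from_binary(region)
  if (length(lab$contours) == 0L) return(TRUE)
  prof <- curvature_profile(lab$contours[[1]])
  !any(prof$outlier_flags)
}

#' Separate adhered regions
#'
#' For every connected component that is not isolated (per [is_isolated()]):
#' delete the curvature-outlier contour pixels, compute the distance
#' transform, and run a seeded watershed (regional maxima merged within
#' 5 px) to split the component at its necks. Isolated components pass
#' through untouched, and a component that fails to split remains single,
#' so the label count never decreases.
#'
#' @param mask a [binarize()] result (`region_mask`), or a logical/numeric
#'   binary matrix.
#' @return a `region_mask` with `label_count >=` the input's.
#' @export
separate_adhered <- function(mask) {
  if (!inherits(mask, "region_mask")) mask <- region_mask_from_binary(mask > 0)
  h <- nrow(mask$mask); w <- ncol(mask$mask)
  out_labels <- matrix(0L, h, w)
  next_id <- 0L
  for (comp in seq_len(mask$label_count)) {
    cm <- mask$labels == comp
    if (is_isolated(cm)) {
      next_id <- next_id + 1L
      out_labels[cm] <- next_id
      next
    }
    # delete curvature-outlier pixels along the contour
    cm2 <- cm
    prof <- curvature_profile(mask$contours[[comp]])
    if (length(prof$outlier_flags) > 0 && any(prof$outlier_flags)) {
      bad <- prof$points[prof$outlier_flags, , drop = FALSE]
      cm2[cbind(bad[, 1], bad[, 2])] <- FALSE
    }
    if (!any(cm2)) cm2 <- cm
    d <- EBImage::distmap(matrix(as.numeric(cm2), h, w))
    ws <- EBImage::watershed(d, tolerance = 1,
                             ext = .pp_const$seed_merge_px)
    ws <- matrix(as.integer(ws), h, w)
    k <- max(ws)
    if (k <= 1L) {
      next_id <- next_id + 1L
      out_labels[cm2] <- next_id
    } else {
      for (sub in seq_len(k)) {
        next_id <- next_id + 1L
        out_labels[ws == sub] <- next_id
      }
    }
  }
  structure(list(mask = out_labels > 0L, labels = out_labels,
                 label_count = next_id,
                 contours = trace_contours(out_labels)),
            class = "region_mask")
}

label_boxes <- function(rm) {
  n <- rm$label_count
  if (n == 0L) return(matrix(numeric(0), ncol = 4))
  out <- matrix(NA_real_, n, 4)
  for (l in seq_len(n)) {
    pix <- which(rm$labels == l, arr.ind = TRUE)
    out[l, ] <- c(min(pix[, 2]) - 1, min(pix[, 1]) - 1,
                  max(pix[, 2]), max(pix[, 1]))
  }
  colnames(out) <- c("xmin", "ymin", "xmax", "ymax")
  out
}

#' Refine detections with curvature/watershed post-processing
#'
#' Binarizes the image, splits adhered regions, and reconciles the region
#' labels with the detection list: a detection box overlapped (IOU >= 0.3)
#' by two or more split labels is replaced by the per-label tight boxes
#' (inheriting its score); labels overlapping no box at all (IOU < 0.3
#' with every box) are added as new boxes with score 0.5 and flagged
#' `recovered`. On scenes where the detector missed occluded or adhered
#' fruit this step recovers them, so refinement never lowers recall.
#'
#' @param detections a [detection_result()].
#' @param image the scene (H x W x 3 array or `annotated_image`).
#' @param overlap_iou label-to-box association threshold (default 0.3).
#' @return a refined [detection_result()].
#' @export
refine_detections <- function(detections, image, overlap_iou = 0.3) {
  if (!inherits(detections, "detection_result")) {
    stopf("`detections` must be a detection_result",
          class = "strawdetect_invalid_argument")
  }
  rm_ <- separate_adhered(binarize(image))
  lb <- label_boxes(rm_)
  det <- detections$boxes
  scores <- detections$scores
  if (nrow(lb) == 0L) return(detections)

  out_boxes <- matrix(numeric(0), ncol = 4)
  out_scores <- numeric(0)
  out_rec <- logical(0)
  used_labels <- rep(FALSE, nrow(lb))
  for (i in seq_len(nrow(det))) {
    ov <- vapply(seq_len(nrow(lb)), function(l) iou(det[i, ], lb[l, ]),
                 numeric(1))
    hits <- which(ov >= overlap_iou & !used_labels)
    if (length(hits) >= 2L) {
      used_labels[hits] <- TRUE
      out_boxes <- rbind(out_boxes, lb[hits, , drop = FALSE])
      out_scores <- c(out_scores, rep(scores[i], length(hits)))
      out_rec <- c(out_rec, rep(FALSE, length(hits)))
    } else {
      out_boxes <- rbind(out_boxes, det[i, , drop = FALSE])
      out_scores <- c(out_scores, scores[i])
      out_rec <- c(out_rec, FALSE)
    }
  }
  # labels untouched by every current box become recovered detections
  for (l in seq_len(nrow(lb))) {
    if (nrow(out_boxes) > 0) {
      ov <- vapply(seq_len(nrow(out_boxes)),
                   function(i) iou(lb[l, ], out_boxes[i, ]), numeric(1))
      if (any(ov >= overlap_iou)) next
    }
    out_boxes <- rbind(out_boxes, lb[l, , drop = FALSE])
    out_scores <- c(out_scores, 0.5)
    out_rec <- c(out_rec, TRUE)
  }
  detection_result(out_boxes, out_scores, out_rec)
}
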