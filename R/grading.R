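#' Plumpness ratio of a bounding box
#'
#' Plumpness — the key structural trait of external fruit quality for
#' globose strawberry varieties — is estimated from the minimal external
#' rectangle as the length-to-width ratio
#' `(ymax - ymin) / (xmax - xmin)`; the ideal value is 1. Ratios above 1
#' (boxes taller than wide) are folded by reciprocal, i.e. the returned
#' value is `min(h, w) / max(h, w)`, so the codomain is `(0, 1]`, matching
#' the grade bands, and the ratio is invariant under 90-degree rotation,
#' translation and uniform scaling of the box.
#'
#' @param box a [bounding_box()] or length-4 `xmin, ymin, xmax, ymax`.
#' @return a ratio in `(0, 1]`.
#' @examples
#' plumpness_ratio(bounding_box(10, 10, 30, 30))  # 1
#' plumpness_ratio(bounding_box(0, 0, 40, 20))    # 0.5
#' @export
plumpness_ratio <- function(box) {
  b <- as.numeric(box)[1:4]
  w <- b[3] - b[1]; h <- b[4] - b[2]
  if (!all(is.finite(c(w, h))) || w <= 0 || h <= 0) {
    stopf("degenerate box in plumpness_ratio()",
          class = "strawdetect_invalid_box")
  }
  min(h, w) / max(h, w)
}

#' Plumpness grade bands
#'
#' The three bands partition `[0, 1]` exactly: Plump `[0, 0.5)`,
#' Approximately Plump `[0.5, 0.8)`, Fully Plump `[0.8, 1]`. Boundary
#' values go to the upper band. Note the conventional band names run
#' counter to intuition — "Plump" denotes the lowest ratio (least globose)
#' group; the names are kept as used in the field.
#'
#' @return character vector of the three band names in ascending ratio
#'   order.
#' @export
grade_bands <- function() c("Plump", "Approximately Plump", "Fully Plump")

#' Grade a plumpness ratio into a band
#'
#' @param ratio numeric ratio(s) in `[0, 1]`.
#' @return factor with levels [grade_bands()].
#' @examples
#' grade(c(0.3, 0.5, 0.95))
#' @export
grade <- function(ratio) {
  ratio <- as.numeric(ratio)
  if (any(!is.finite(ratio)) || any(ratio < 0 | ratio > 1)) {
    stopf("ratio must lie in [0, 1]", class = "strawdetect_invalid_argument")
  }
  bands <- grade_bands()
  out <- ifelse(ratio < 0.5, bands[1], ifelse(ratio < 0.8, bands[2], bands[3]))
  factor(out, levels = bands)
}

#' Grade a set of detections
#'
#' Computes the per-box plumpness ratio and band, plus the pooled
#' percentage of boxes per band (summing to 100 when boxes are present).
#' Per-image averaging of percentages is available through `by_image` when
#' `detections` is a list of per-image results.
#'
#' @param detections a [detection_result()], boxes acceptable to
#'   [box_matrix()], or (with `by_image = TRUE`) a list of either.
#' @param by_image average band percentages over images instead of pooling
#'   all boxes.
#' @return an object of class `"grade_report"`: `per_box` data frame
#'   (`xmin, ymin, xmax, ymax, ratio, band`) and `distribution` (named
#'   percentages). With no boxes, `distribution` is `NA` and flagged via
#'   `empty = TRUE`.
#' @export
grade_detections <- function(detections, by_image = FALSE) {
  if (by_image) {
    reports <- lapply(detections, grade_detections)
    non_empty <- Filter(function(r) !r$empty, reports)
    dist <- if (length(non_empty) == 0L) {
      stats::setNames(rep(NA_real_, 3), grade_bands())
    } else {
      rowMeans(vapply(non_empty, function(r) r$distribution, numeric(3)))
    }
    per_box <- do.call(rbind, lapply(reports, function(r) r$per_box))
    return(structure(list(per_box = per_box, distribution = dist,
                          empty = length(non_empty) == 0L,
                          pooled = FALSE),
                     class = "grade_report"))
  }
  m <- if (inherits(detections, "detection_result")) {
    detections$boxes
  } else {
    box_matrix(detections)
  }
  n <- nrow(m)
  ratios <- vapply(seq_len(n), function(i) plumpness_ratio(m[i, ]), numeric(1))
  bands <- if (n > 0) grade(ratios) else factor(character(0), levels = grade_bands())
  per_box <- data.frame(xmin = m[, 1], ymin = m[, 2], xmax = m[, 3],
                        ymax = m[, 4], ratio = ratios, band = bands,
                        row.names = NULL)
  dist <- if (n == 0L) {
    stats::setNames(rep(NA_real_, 3), grade_bands())
  } else {
    100 * table(bands) / n
  }
  structure(list(per_box = per_box,
                 distribution = stats::setNames(as.numeric(dist), grade_bands()),
                 empty = n == 0L, pooled = TRUE),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cat(sprintf("<grade_report: %d box(es)>\n", nrow(x$per_box)))
  if (!x$empty) {
    for (b in grade_bands()) {
      cat(sprintf("  %-20s %6.1f%%\n", b, x$distribution[[b]]))
    }
  } else {
    cat("  distribution undefined (no boxes)\n")
  }
  invisible(x)
}

#' Serialize a grade report
#'
#' Writes the per-box table as CSV (`xmin,ymin,xmax,ymax,ratio,band`) and,
#' optionally, the band distribution as JSON.
#'
#' @param report a [grade_detections()] result.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_grade_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_box, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(report$distribution), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
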