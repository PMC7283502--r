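#' Axis-aligned bounding boxes
#'
#' Boxes are the unit of detection, grading and overlap measurement
#' throughout the package. The coordinate convention, used everywhere, is:
#' 0-based pixel indices, origin at the top-left corner, half-open intervals
#' `[xmin, xmax) x [ymin, ymax)`, so that `width = xmax - xmin` and
#' `height = ymax - ymin`.
#'
#' `bounding_box()` constructs a single validated box; `box_matrix()`
#' normalises a box, a list of boxes, or an n x 4 matrix into an n x 4
#' numeric matrix with columns `xmin, ymin, xmax, ymax`.
#'
#' @param xmin,ymin,xmax,ymax box edges in pixels (0-based, half-open).
#' @return `bounding_box()`: a named numeric vector of class
#'   `"bounding_box"`.
#' @examples
#' b <- bounding_box(10, 20, 30, 40)
#' box_width(b)   # 20
#' box_height(b)  # 20
#' @export
bounding_box <- function(xmin, ymin, xmax, ymax) {
  b <- c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  validate_box(b)
  class(b) <- "bounding_box"
  b
}

validate_box <- function(b, index = NULL) {
  where <- if (is.null(index)) "" else sprintf(" (box %d)", index)
  if (any(!is.finite(b))) {
    stopf("box coordinates must be finite%s", where,
          class = "strawdetect_invalid_box")
  }
  if (any(b[c("xmin", "ymin")] < 0)) {
    stopf("box coordinates must be >= 0%s", where,
          class = "strawdetect_invalid_box")
  }
  if (b[["xmin"]] >= b[["xmax"]] || b[["ymin"]] >= b[["ymax"]]) {
    stopf("degenerate box: requires xmin < xmax and ymin < ymax%s", where,
          class = "strawdetect_invalid_box")
  }
  invisible(b)
}

#' @rdname bounding_box
#' @param boxes a `bounding_box`, a list of them, or an n x 4 matrix.
#' @export
box_matrix <- function(boxes) {
  if (is.null(boxes) || (is.list(boxes) && length(boxes) == 0L)) {
    m <- matrix(numeric(0), ncol = 4)
  } else if (inherits(boxes, "bounding_box")) {
    m <- matrix(unclass(boxes), ncol = 4, byrow = TRUE)
  } else if (is.matrix(boxes)) {
    if (ncol(boxes) != 4L) stopf("box matrix must have 4 columns",
                                 class = "strawdetect_invalid_box")
    m <- boxes
  } else if (is.list(boxes)) {
    m <- do.call(rbind, lapply(boxes, function(b) as.numeric(b)[1:4]))
  } else if (is.numeric(boxes) && length(boxes) == 4L) {
    m <- matrix(as.numeric(boxes), ncol = 4)
  } else {
    stopf("cannot interpret `boxes` as bounding boxes",
          class = "strawdetect_invalid_box")
  }
  colnames(m) <- c("xmin", "ymin", "xmax", "ymax")
  m
}

box_list <- function(m) {
  m <- box_matrix(m)
  lapply(seq_len(nrow(m)), function(i) {
    bounding_box(m[i, 1], m[i, 2], m[i, 3], m[i, 4])
  })
}

#' @rdname bounding_box
#' @param box a `bounding_box` or length-4 numeric vector.
#' @export
box_width <- function(box) unname(box[[3]] - box[[1]])

#' @rdname bounding_box
#' @export
box_height <- function(box) unname(box[[4]] - box[[2]])

#' @rdname bounding_box
#' @export
box_area <- function(box) box_width(box) * box_height(box)

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box [%g, %g) x [%g, %g)>\n", x[["xmin"]], x[["xmax"]],
              x[["ymin"]], x[["ymax"]]))
  invisible(x)
}
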