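#' Bounding-box annotation records
#'
#' An annotation record pairs an image path and size with a list of labelled
#' boxes, mirroring the four-number `(xmin, ymin, xmax, ymax)` arrays that
#' object-tagging tools export alongside each image.
#'
#' @param image_path path of the annotated image (stored verbatim).
#' @param image_size integer `c(width, height)` in pixels.
#' @param boxes boxes in any form accepted by [box_matrix()].
#' @param labels character vector of per-box labels, recycled; the toolkit
#'   uses the single category `"strawberry"`.
#' @return an object of class `"annotation_record"` with fields
#'   `image_path`, `image_size`, `objects` (list of `list(label, box)`).
#' @seealso [write_annotation()], [read_annotation()]
#' @export
annotation_record <- function(image_path, image_size, boxes,
                              labels = "strawberry") {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size <= 0L)) {
    stopf("image_size must be positive c(width, height)",
          class = "strawdetect_invalid_argument")
  }
  m <- box_matrix(boxes)
  labels <- rep_len(as.character(labels), nrow(m))
  objects <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    b <- bounding_box(m[i, 1], m[i, 2], m[i, 3], m[i, 4])
    if (b[["xmax"]] > image_size[1] || b[["ymax"]] > image_size[2]) {
      stopf("box %d exceeds image bounds (%d x %d)", i,
            image_size[1], image_size[2], class = "strawdetect_invalid_box")
    }
    objects[[i]] <- list(label = labels[i], box = b)
  }
  structure(list(image_path = image_path, image_size = image_size,
                 objects = objects),
            class = "annotation_record")
}

#' @export
print.annotation_record <- function(x, ...) {
  cat(sprintf("<annotation: %s (%d x %d), %d object(s)>\n",
              x$image_path, x$image_size[1], x$image_size[2],
              length(x$objects)))
  invisible(x)
}

#' Write a Pascal-VOC-dialect annotation XML
#'
#' Serialises an [annotation_record()] to the VOC element layout
#' (`annotation/size/object/bndbox/{xmin,ymin,xmax,ymax}`). Coordinates are
#' written as integers under the package's 0-based half-open convention.
#'
#' @param record an [annotation_record()].
#' @param destination file path to write.
#' @return `destination`, invisibly.
#' @export
write_annotation <- function(record, destination) {
  if (!inherits(record, "annotation_record")) {
    stopf("`record` must be an annotation_record",
          class = "strawdetect_invalid_argument")
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", basename(record$image_path))
  xml2::xml_add_child(doc, "path", record$image_path)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$image_size[1]))
  xml2::xml_add_child(size, "height", as.character(record$image_size[2]))
  xml2::xml_add_child(size, "depth", "3")
  for (obj in record$objects) {
    node <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(node, "name", obj$label)
    bnd <- xml2::xml_add_child(node, "bndbox")
    b <- obj$box
    xml2::xml_add_child(bnd, "xmin", as.character(as.integer(round(b[["xmin"]]))))
    xml2::xml_add_child(bnd, "ymin", as.character(as.integer(round(b[["ymin"]]))))
    xml2::xml_add_child(bnd, "xmax", as.character(as.integer(round(b[["xmax"]]))))
    xml2::xml_add_child(bnd, "ymax", as.character(as.integer(round(b[["ymax"]]))))
  }
  xml2::write_xml(doc, destination)
  invisible(destination)
}

#' Read a Pascal-VOC-dialect annotation XML
#'
#' Inverse of [write_annotation()]. Unknown extra elements are ignored;
#' object order is preserved. Malformed XML raises a parse error; a box
#' violating `xmin < xmax`, `ymin < ymax` raises a validation error naming
#' the box index.
#'
#' @param source path to an XML file.
#' @return an [annotation_record()].
#' @export
read_annotation <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e) {
    stopf("cannot parse annotation XML `%s`: %s", source, conditionMessage(e),
          class = "strawdetect_parse_error")
  })
  if (xml2::xml_name(doc) != "annotation") {
    stopf("root element is <%s>, expected <annotation>", xml2::xml_name(doc),
          class = "strawdetect_parse_error")
  }
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) {
    stopf("missing <size> element", class = "strawdetect_parse_error")
  }
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (is.na(width) || is.na(height)) {
    stopf("non-numeric <size> dimensions", class = "strawdetect_parse_error")
  }
  path_node <- xml2::xml_find_first(doc, "./path")
  image_path <- if (inherits(path_node, "xml_missing")) {
    xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  } else {
    xml2::xml_text(path_node)
  }
  objs <- xml2::xml_find_all(doc, "./object")
  n <- length(objs)
  boxes <- matrix(numeric(0), ncol = 4)
  labels <- character(0)
  if (n > 0L) {
    boxes <- matrix(NA_real_, nrow = n, ncol = 4)
    labels <- character(n)
    for (i in seq_len(n)) {
      bnd <- xml2::xml_find_first(objs[[i]], "./bndbox")
      if (inherits(bnd, "xml_missing")) {
        stopf("object %d has no <bndbox> element", i,
              class = "strawdetect_parse_error")
      }
      co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(nm) {
        v <- xml2::xml_text(xml2::xml_find_first(bnd, paste0("./", nm)))
        as.numeric(v)
      }, numeric(1))
      if (any(is.na(co))) {
        stopf("object %d has a missing or non-numeric bndbox coordinate", i,
              class = "strawdetect_parse_error")
      }
      if (co[["xmin"]] >= co[["xmax"]] || co[["ymin"]] >= co[["ymax"]]) {
        stopf("object %d violates xmin < xmax, ymin < ymax", i,
              class = "strawdetect_invalid_box")
      }
      boxes[i, ] <- co
      nm <- xml2::xml_find_first(objs[[i]], "./name")
      labels[i] <- if (inherits(nm, "xml_missing")) "strawberry" else xml2::xml_text(nm)
    }
  }
  annotation_record(image_path, c(width, height), boxes, labels)
}

#' Read and write dataset manifests
#'
#' A manifest is a newline-separated list of relative image paths used to
#' assemble datasets for preprocessing, training and evaluation.
#'
#' @param paths character vector of paths.
#' @param destination,source manifest file path.
#' @export
write_manifest <- function(paths, destination) {
  writeLines(as.character(paths), destination)
  invisible(destination)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines[nzchar(lines)]
}
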