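#' Median denoising
#'
#' Removes high-frequency sensor noise with a square median filter applied
#' independently to the red, green and blue channels; the denoised image is
#' the integration of the three filtered channels. Edges are handled by
#' reflection padding.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param window odd window size in pixels, default 3 (a 3 x 3 window).
#' @return filtered array, same shape.
#' @export
median_denoise <- function(image, window = 3L) {
  assert_image(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stopf("`window` must be an odd integer >= 3",
          class = "strawdetect_invalid_argument")
  }
  k <- (window - 1L) %/% 2L
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h <= k || w <= k) {
    stopf("image too small for a %d x %d median window", window, window,
          class = "strawdetect_invalid_argument")
  }
  ridx <- c(rev(seq_len(k) + 1L), seq_len(h), h - seq_len(k))
  cidx <- c(rev(seq_len(k) + 1L), seq_len(w), w - seq_len(k))
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- median_filter_plane(image[ridx, cidx, ch], window, h, w)
  }
  out
}

# exact windowed median: gather the window's shifted copies as columns and
# run a vectorised compare-exchange sort (pmin/pmax), then take the middle
# column — exact for any odd window, unlike quantizing histogram filters
median_filter_plane <- function(padded, window, h, w) {
  m <- window * window
  cols <- matrix(0, h * w, m)
  idx <- 0L
  for (dx in seq_len(window)) {
    for (dy in seq_len(window)) {
      idx <- idx + 1L
      cols[, idx] <- as.vector(padded[dy + seq_len(h) - 1L,
                                      dx + seq_len(w) - 1L])
    }
  }
  for (i in seq_len(m - 1L)) {
    for (j in seq_len(m - i)) {
      lo <- pmin(cols[, j], cols[, j + 1L])
      hi <- pmax(cols[, j], cols[, j + 1L])
      cols[, j] <- lo
      cols[, j + 1L] <- hi
    }
  }
  matrix(cols[, (m + 1L) %/% 2L], h, w)
}

#' Photometric augmentation recipe
#'
#' The nine photometric transforms used to expand a small fruit dataset:
#' brightness, chroma and contrast enhanced to 1.2x, sharpness enhanced to
#' 2x, brightness, chroma and contrast attenuated to 60% and sharpness to
#' 10%, plus additive Gaussian noise of variance 0.01 on `[0, 1]`
#' intensities. With the original included the expansion multiplier is 10.
#' Augmentation is purely photometric: image dimensions and box annotations
#' are unchanged.
#'
#' @param brightness_up,chroma_up,contrast_up enhancement factors (1.2).
#' @param sharpness_up sharpness enhancement factor (2.0).
#' @param brightness_down,chroma_down,contrast_down attenuation factors
#'   (0.6).
#' @param sharpness_down sharpness attenuation factor (0.1).
#' @param gaussian_noise_variance noise variance on `[0, 1]` intensities
#'   (0.01, i.e. sigma = 0.1).
#' @param include_original prepend the untouched image (default `TRUE`).
#' @return an object of class `"augmentation_recipe"`.
#' @export
augmentation_recipe <- function(brightness_up = 1.2, chroma_up = 1.2,
                                contrast_up = 1.2, sharpness_up = 2.0,
                                brightness_down = 0.6, chroma_down = 0.6,
                                contrast_down = 0.6, sharpness_down = 0.1,
                                gaussian_noise_variance = 0.01,
                                include_original = TRUE) {
  factors <- c(brightness_up = brightness_up, chroma_up = chroma_up,
               contrast_up = contrast_up, sharpness_up = sharpness_up,
               brightness_down = brightness_down, chroma_down = chroma_down,
               contrast_down = contrast_down, sharpness_down = sharpness_down)
  if (any(factors <= 0)) {
    stopf("all augmentation factors must be > 0",
          class = "strawdetect_invalid_config")
  }
  if (gaussian_noise_variance < 0) {
    stopf("gaussian_noise_variance must be >= 0",
          class = "strawdetect_invalid_config")
  }
  structure(list(factors = factors,
                 gaussian_noise_variance = gaussian_noise_variance,
                 include_original = isTRUE(include_original)),
            class = "augmentation_recipe")
}

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

enhance_brightness <- function(image, f) clip01(image * f)

enhance_chroma <- function(image, f) {
  grey <- luminance(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- grey + f * (image[, , ch] - grey)
  clip01(out)
}

enhance_contrast <- function(image, f) {
  mu <- mean(luminance(image))
  clip01(mu + f * (image - mu))
}

# 3 x 3 smoothing kernel (centre-weighted box) with reflection padding
smooth3 <- function(plane) {
  h <- nrow(plane); w <- ncol(plane)
  ridx <- c(2L, seq_len(h), h - 1L)
  cidx <- c(2L, seq_len(w), w - 1L)
  p <- plane[ridx, cidx]
  kern <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1) / 13, 3, 3)
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + kern[dy + 1, dx + 1] * p[dy + seq_len(h), dx + seq_len(w)]
  }
  acc
}

enhance_sharpness <- function(image, f) {
  out <- image
  for (ch in 1:3) {
    sm <- smooth3(image[, , ch])
    out[, , ch] <- sm + f * (image[, , ch] - sm)
  }
  clip01(out)
}

add_gaussian_noise <- function(image, variance, seed) {
  with_seed(seed, {
    clip01(image + array(stats::rnorm(length(image), 0, sqrt(variance)),
                         dim = dim(image)))
  })
}

#' Augment one image
#'
#' Applies the recipe's transforms and returns the expanded list: the
#' original (if included), then the eight factor transforms in recipe field
#' order, then the Gaussian-noise image. Only the noise transform consumes
#' the seed.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param recipe an [augmentation_recipe()].
#' @param seed integer seed for the noise transform.
#' @return list of arrays, each the same shape as `image`.
#' @export
augment_image <- function(image, recipe = augmentation_recipe(), seed = 1L) {
  assert_image(image)
  f <- recipe$factors
  out <- list()
  if (recipe$include_original) out <- c(out, list(image))
  out <- c(out, list(
    enhance_brightness(image, f[["brightness_up"]]),
    enhance_chroma(image, f[["chroma_up"]]),
    enhance_contrast(image, f[["contrast_up"]]),
    enhance_sharpness(image, f[["sharpness_up"]]),
    enhance_brightness(image, f[["brightness_down"]]),
    enhance_chroma(image, f[["chroma_down"]]),
    enhance_contrast(image, f[["contrast_down"]]),
    enhance_sharpness(image, f[["sharpness_down"]]),
    add_gaussian_noise(image, recipe$gaussian_noise_variance, seed)))
  out
}

#' Augment a dataset
#'
#' Concatenation of [augment_image()] over the inputs in order; under the
#' default recipe the output is 10x the input size. Inputs may be plain
#' arrays or `annotated_image` objects (whose pixels are augmented and whose
#' annotations are copied verbatim onto every variant).
#'
#' @param images list of H x W x 3 arrays or `annotated_image`s.
#' @param recipe an [augmentation_recipe()].
#' @param seed master seed; each image's noise seed is derived from it.
#' @return list of augmented items, same type as the inputs.
#' @export
augment_dataset <- function(images, recipe = augmentation_recipe(), seed = 1L) {
  out <- vector("list", 0L)
  for (i in seq_along(images)) {
    item <- images[[i]]
    s <- derive_seed(seed, i)
    if (inherits(item, "annotated_image")) {
      variants <- augment_image(item$pixels, recipe, s)
      out <- c(out, lapply(variants, function(px) {
        v <- item
        v$pixels <- px
        v
      }))
    } else {
      out <- c(out, augment_image(item, recipe, s))
    }
  }
  out
}

#' Split an image into square patches
#'
#' Tiles the image on a `ceil(H/ps) x ceil(W/ps)` grid. Edge tiles are taken
#' flush with the image border (the last tile starts at `dim - ps`), so
#' tiles may overlap at edges but always contain real pixels, and stitching
#' the tiles back at their offsets reproduces the image exactly. Images
#' smaller than the patch size in either dimension are reflection-padded to
#' the patch size and returned as a single tile.
#'
#' @param image H x W x 3 array.
#' @param patch_size square tile edge in pixels (default 256).
#' @return list of `list(pixels, offset)` where `offset = c(x, y)` is the
#'   tile's top-left corner (0-based) in image coordinates.
#' @export
split_patches <- function(image, patch_size = 256L) {
  assert_image(image)
  ps <- as.integer(patch_size)
  if (ps < 1L) stopf("patch_size must be >= 1",
                     class = "strawdetect_invalid_argument")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < ps || w < ps) {
    ridx <- reflect_index(h, ps)
    cidx <- reflect_index(w, ps)
    return(list(list(pixels = image[ridx, cidx, , drop = FALSE],
                     offset = c(x = 0, y = 0))))
  }
  starts <- function(d) {
    n <- ceiling(d / ps)
    vapply(seq_len(n) - 1L, function(i) min(i * ps, d - ps), numeric(1))
  }
  ys <- starts(h); xs <- starts(w)
  tiles <- list()
  for (y0 in ys) for (x0 in xs) {
    tiles[[length(tiles) + 1L]] <-
      list(pixels = image[y0 + seq_len(ps), x0 + seq_len(ps), , drop = FALSE],
           offset = c(x = x0, y = y0))
  }
  tiles
}

# index vector that reflection-pads a dimension of length d up to target
reflect_index <- function(d, target) {
  if (d >= target) return(seq_len(target))
  idx <- seq_len(d)
  while (length(idx) < target) {
    extra <- rev(seq_len(d - 1L))
    idx <- c(idx, extra[seq_len(min(length(extra), target - length(idx)))])
  }
  idx
}

#' Assign boxes to patches
#'
#' A box is assigned to a tile when the intersection of box and tile covers
#' at least `min_overlap_fraction` of the box's area (inclusive, so a box
#' straddling two tiles 50/50 at the default threshold appears in both).
#' Assigned boxes are clipped to the tile and re-expressed in tile
#' coordinates.
#'
#' @param boxes boxes in any form accepted by [box_matrix()] (image
#'   coordinates).
#' @param tiles list of tiles from [split_patches()], or a list of
#'   `c(x, y)` offsets.
#' @param patch_size tile edge in pixels.
#' @param min_overlap_fraction assignment threshold in `(0, 1]`.
#' @return list (one element per tile) of n x 4 box matrices in tile
#'   coordinates.
#' @export
split_boxes_to_patches <- function(boxes, tiles, patch_size = 256L,
                                   min_overlap_fraction = 0.5) {
  m <- box_matrix(boxes)
  ps <- as.numeric(patch_size)
  offsets <- lapply(tiles, function(t) if (is.list(t)) t$offset else t)
  lapply(offsets, function(off) {
    x0 <- off[[1]]; y0 <- off[[2]]
    keep <- matrix(numeric(0), ncol = 4,
                   dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
    for (i in seq_len(nrow(m))) {
      ix1 <- max(m[i, 1], x0); iy1 <- max(m[i, 2], y0)
      ix2 <- min(m[i, 3], x0 + ps); iy2 <- min(m[i, 4], y0 + ps)
      if (ix1 >= ix2 || iy1 >= iy2) next
      inter <- (ix2 - ix1) * (iy2 - iy1)
      area <- (m[i, 3] - m[i, 1]) * (m[i, 4] - m[i, 2])
      if (inter / area >= min_overlap_fraction) {
        keep <- rbind(keep, c(ix1 - x0, iy1 - y0, ix2 - x0, iy2 - y0))
      }
    }
    keep
  })
}

#' Train/test split specification
#'
#' @param train_fraction fraction of items assigned to training (0.8).
#' @param seed permutation seed.
#' @param shuffle permute before cutting (default `TRUE`).
#' @return an object of class `"split_spec"`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 1L, shuffle = TRUE) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie strictly in (0, 1)",
          class = "strawdetect_invalid_config")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle)),
            class = "split_spec")
}

#' Split items into train and test sets
#'
#' `floor(train_fraction * n)` items go to training, the remainder to
#' testing; with `shuffle`, a seeded permutation precedes the cut. The two
#' sets are disjoint and exhaustive.
#'
#' @param items a list (or vector) of at least 2 items.
#' @param spec a [split_spec()].
#' @return `list(train = ..., test = ...)`.
#' @export
split_dataset <- function(items, spec = split_spec()) {
  n <- length(items)
  if (n < 2L) stopf("need at least 2 items to split",
                    class = "strawdetect_invalid_argument")
  idx <- seq_len(n)
  if (spec$shuffle) idx <- with_seed(spec$seed, sample.int(n))
  n_train <- floor(spec$train_fraction * n)
  list(train = items[idx[seq_len(n_train)]],
       test = items[idx[n_train + seq_len(n - n_train)]])
}
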