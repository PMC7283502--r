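#' Configure a synthetic greenhouse scene
#'
#' Describes one synthetic scene: raster size, number of fruit, fruit
#' geometry, the fraction of fruit that adhere to (overlap) another fruit,
#' the fraction partially covered by a leaf occluder, the illumination
#' cluster, and sensor noise. Rendered scenes emulate near-ground greenhouse
#' imagery: red, roughly globose fruit on a textured green-brown bed, with
#' leaf occluders and five illumination clusters spanning 1000-6000 Lx.
#'
#' @param image_width,image_height raster size in pixels.
#' @param n_fruit number of fruit to place.
#' @param fruit_radius_range `c(min, max)` fruit half-width in pixels
#'   (minimum 2).
#' @param fruit_aspect_range `c(min, max)` height/width ratio of each
#'   fruit; this directly controls the bounding-box ratio the grading
#'   module measures.
#' @param adhesion_fraction proportion in `[0, 1]` of fruit placed
#'   overlapping a previously placed fruit.
#' @param occlusion_fraction proportion in `[0, 1]` of fruit partially
#'   covered by a leaf occluder.
#' @param illumination_lux one of 1000, 2000, 4000, 5000, 6000; maps
#'   linearly to global scene brightness (see Details).
#' @param noise_sigma additive Gaussian noise standard deviation in 8-bit
#'   grey levels.
#' @param seed integer RNG seed; the same config (including seed) always
#'   renders a bit-identical scene.
#'
#' @details Illumination is applied as a linear luminance gain
#'   `0.5 + lux / 8000`, clipped at channel saturation, so 4000 Lx is the
#'   nominal exposure and mean brightness is non-decreasing in lux.
#' @return an object of class `"scene_config"`.
#' @export
scene_config <- function(image_width = 640, image_height = 480,
                         n_fruit = 120,
                         fruit_radius_range = c(8, 16),
                         fruit_aspect_range = c(0.6, 1.0),
                         adhesion_fraction = 0.15,
                         occlusion_fraction = 0.15,
                         illumination_lux = 4000,
                         noise_sigma = 2,
                         seed = 1L) {
  cfg <- list(image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              n_fruit = as.integer(n_fruit),
              fruit_radius_range = as.numeric(fruit_radius_range),
              fruit_aspect_range = as.numeric(fruit_aspect_range),
              adhesion_fraction = as.numeric(adhesion_fraction),
              occlusion_fraction = as.numeric(occlusion_fraction),
              illumination_lux = as.numeric(illumination_lux),
              noise_sigma = as.numeric(noise_sigma),
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!ok) stopf("invalid scene config: %s", msg,
                   class = "strawdetect_invalid_config")
  }
  chk(cfg$image_width >= 16 && cfg$image_height >= 16,
      "image must be at least 16 x 16")
  chk(cfg$n_fruit >= 0, "n_fruit must be >= 0")
  chk(length(cfg$fruit_radius_range) == 2 &&
        cfg$fruit_radius_range[1] >= 2 &&
        diff(cfg$fruit_radius_range) >= 0,
      "fruit_radius_range must satisfy 2 <= min <= max")
  chk(length(cfg$fruit_aspect_range) == 2 &&
        cfg$fruit_aspect_range[1] > 0 &&
        diff(cfg$fruit_aspect_range) >= 0,
      "fruit_aspect_range must satisfy 0 < min <= max")
  chk(cfg$adhesion_fraction >= 0 && cfg$adhesion_fraction <= 1,
      "adhesion_fraction must lie in [0, 1]")
  chk(cfg$occlusion_fraction >= 0 && cfg$occlusion_fraction <= 1,
      "occlusion_fraction must lie in [0, 1]")
  chk(cfg$illumination_lux %in% c(1000, 2000, 4000, 5000, 6000),
      "illumination_lux must be one of 1000, 2000, 4000, 5000, 6000")
  chk(cfg$noise_sigma >= 0, "noise_sigma must be >= 0")
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config %dx%d, %d fruit, r [%g, %g], ",
                     "aspect [%g, %g], %g Lx, seed %d>\n"),
              x$image_width, x$image_height, x$n_fruit,
              x$fruit_radius_range[1], x$fruit_radius_range[2],
              x$fruit_aspect_range[1], x$fruit_aspect_range[2],
              x$illumination_lux, x$seed))
  invisible(x)
}

#' @rdname scene_config
#' @param ... overrides passed to [scene_config()].
#' @export
tiny_scene_config <- function(...) {
  defaults <- list(image_width = 64L, image_height = 64L, n_fruit = 5L,
                   fruit_radius_range = c(4, 7),
                   fruit_aspect_range = c(0.6, 1.0),
                   adhesion_fraction = 0, occlusion_fraction = 0,
                   illumination_lux = 4000, noise_sigma = 2, seed = 1L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(scene_config, defaults)
}

# fixed cosmetic constants of the renderer (colours in [0,1] RGB)
.scene_palette <- list(
  soil  = c(0.36, 0.27, 0.18),
  plant = c(0.28, 0.44, 0.20),
  leaf  = c(0.20, 0.42, 0.14),
  fruit_red_range   = c(0.72, 0.92),
  fruit_green_range = c(0.08, 0.20),
  fruit_blue_range  = c(0.06, 0.16)
)

illumination_gain <- function(lux) 0.5 + lux / 8000

# superellipse fruit mask on a local window; exponent 2.4 gives a rounded,
# slightly conical silhouette
fruit_mask <- function(rows, cols, cy, cx, half_w, half_h, expo = 2.4) {
  dy <- (rows - cy) / half_h
  dx <- (cols - cx) / half_w
  outer_dy <- matrix(abs(dy)^expo, nrow = length(rows), ncol = length(cols))
  outer_dx <- matrix(abs(dx)^expo, nrow = length(rows), ncol = length(cols),
                     byrow = TRUE)
  outer_dy + outer_dx <= 1
}

# smooth random field in [0,1] by bilinear interpolation of a coarse grid
smooth_field <- function(h, w, cell = 16) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(stats::runif(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1L); fx <- rx - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  c_ <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fy_m <- rep(fy, w); fx_m <- rep(fx, each = h)
  v <- a * (1 - fy_m) * (1 - fx_m) + b * fy_m * (1 - fx_m) +
    c_ * (1 - fy_m) * fx_m + d * fy_m * fx_m
  matrix(v, h, w)
}

#' Render one synthetic annotated scene
#'
#' Places `n_fruit` superellipse fruit (a configurable fraction adhering to
#' another fruit), draws leaf occluders over a configurable fraction, applies
#' the illumination gain and sensor noise, and records per-fruit ground
#' truth: the tight bounding box of each fruit's rendered, pre-occlusion
#' extent plus adhesion/occlusion flags.
#'
#' @param config a [scene_config()].
#' @return an object of class `"annotated_image"`: list with `pixels`
#'   (H x W x 3 array in `[0, 1]`, 8-bit quantized), `boxes` (n x 4 matrix,
#'   0-based half-open), `labels`, and `meta` (config plus per-box
#'   `adhered`/`occluded` flags).
#' @examples
#' sc <- generate_scene(tiny_scene_config(seed = 7))
#' nrow(sc$boxes)  # 5
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, render_scene(config))
}

render_scene <- function(config) {
  h <- config$image_height; w <- config$image_width
  n <- config$n_fruit
  pal <- .scene_palette

  # background: soil/plant mix weighted by a smooth field, mild texture
  field <- smooth_field(h, w)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- pal$soil[ch] * (1 - field) + pal$plant[ch] * field
  }
  img <- img + array(stats::rnorm(h * w * 3, 0, 0.012), dim = c(h, w, 3))
  img <- clip01(img)

  # --- fruit placement ---------------------------------------------------
  n_adhered <- round(config$adhesion_fraction * n)
  cy <- cx <- hw <- hh <- numeric(0)
  adhered <- logical(0)
  max_attempts <- 300L * max(n, 1L)
  attempts <- 0L
  for (i in seq_len(n)) {
    want_adhesion <- (i > 1L) && (sum(adhered) < n_adhered)
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stopf(paste0("could not place %d fruit of radius [%g, %g] in a ",
                     "%d x %d scene after %d attempts"),
              n, config$fruit_radius_range[1], config$fruit_radius_range[2],
              w, h, max_attempts, class = "strawdetect_placement_failure")
      }
      r <- stats::runif(1, config$fruit_radius_range[1],
                        config$fruit_radius_range[2])
      a <- stats::runif(1, config$fruit_aspect_range[1],
                        config$fruit_aspect_range[2])
      half_w_i <- r; half_h_i <- r * a
      if (want_adhesion) {
        anchor <- sample.int(length(cy), 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- 0.75 * (hw[anchor] + half_w_i)
        yy <- cy[anchor] + d * sin(ang)
        xx <- cx[anchor] + d * cos(ang)
      } else {
        yy <- stats::runif(1, half_h_i + 1, h - half_h_i)
        xx <- stats::runif(1, half_w_i + 1, w - half_w_i)
      }
      if (yy < half_h_i + 1 || yy > h - half_h_i ||
          xx < half_w_i + 1 || xx > w - half_w_i) next
      if (!want_adhesion && length(cy) > 0L) {
        dd <- sqrt((cy - yy)^2 + (cx - xx)^2)
        if (any(dd < pmax(hw, hh) + max(half_w_i, half_h_i) + 2)) next
      }
      cy <- c(cy, yy); cx <- c(cx, xx)
      hw <- c(hw, half_w_i); hh <- c(hh, half_h_i)
      adhered <- c(adhered, want_adhesion)
      placed <- TRUE
    }
  }

  # --- render fruit and record tight pre-occlusion boxes -----------------
  boxes <- matrix(NA_real_, nrow = n, ncol = 4,
                  dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  for (i in seq_len(n)) {
    rr <- max(1L, floor(cy[i] - hh[i])):min(h, ceiling(cy[i] + hh[i]))
    cc <- max(1L, floor(cx[i] - hw[i])):min(w, ceiling(cx[i] + hw[i]))
    m <- fruit_mask(rr, cc, cy[i], cx[i], hw[i], hh[i])
    if (!any(m)) m[which.min(abs(rr - cy[i])), which.min(abs(cc - cx[i]))] <- TRUE
    col_fruit <- c(stats::runif(1, pal$fruit_red_range[1], pal$fruit_red_range[2]),
                   stats::runif(1, pal$fruit_green_range[1], pal$fruit_green_range[2]),
                   stats::runif(1, pal$fruit_blue_range[1], pal$fruit_blue_range[2]))
    rho2 <- outer(((rr - cy[i]) / hh[i])^2, ((cc - cx[i]) / hw[i])^2, "+")
    shade <- 1 - 0.30 * pmin(rho2, 1)
    for (ch in 1:3) {
      plane <- img[rr, cc, ch]
      plane[m] <- (col_fruit[ch] * shade)[m]
      img[rr, cc, ch] <- plane
    }
    rows_in <- rr[rowSums(m) > 0]
    cols_in <- cc[colSums(m) > 0]
    # 0-based half-open: 1-based pixel range [p1, p2] -> [p1 - 1, p2)
    boxes[i, ] <- c(min(cols_in) - 1, min(rows_in) - 1,
                    max(cols_in), max(rows_in))
  }

  # --- leaf occluders ----------------------------------------------------
  n_occluded <- round(config$occlusion_fraction * n)
  occluded <- logical(n)
  if (n_occluded > 0L && n > 0L) {
    victims <- sample.int(n, n_occluded)
    for (i in victims) {
      occluded[i] <- TRUE
      ang <- stats::runif(1, 0, 2 * pi)
      ly <- cy[i] + 0.8 * hh[i] * sin(ang)
      lx <- cx[i] + 0.8 * hw[i] * cos(ang)
      lh <- 0.8 * hh[i]; lw <- 1.3 * hw[i]
      rr <- max(1L, floor(ly - lh)):min(h, ceiling(ly + lh))
      cc <- max(1L, floor(lx - lw)):min(w, ceiling(lx + lw))
      m <- fruit_mask(rr, cc, ly, lx, lw, lh, expo = 2)
      tint <- stats::runif(1, 0.85, 1.15)
      for (ch in 1:3) {
        plane <- img[rr, cc, ch]
        plane[m] <- clip01(pal$leaf[ch] * tint)
        img[rr, cc, ch] <- plane
      }
    }
  }

  # --- illumination gain and sensor noise --------------------------------
  img <- clip01(img * illumination_gain(config$illumination_lux))
  if (config$noise_sigma > 0) {
    img <- img + array(stats::rnorm(h * w * 3, 0, config$noise_sigma / 255),
                       dim = c(h, w, 3))
  }
  img <- quantize8(img)

  structure(list(pixels = img,
                 boxes = boxes,
                 labels = rep("strawberry", n),
                 meta = list(config = config, adhered = adhered,
                             occluded = occluded)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image %d x %d, %d box(es), %g Lx>\n",
              d[2], d[1], nrow(x$boxes), x$meta$config$illumination_lux))
  invisible(x)
}

#' Generate a seeded synthetic dataset
#'
#' Renders `n_images` scenes whose per-scene seeds are derived
#' deterministically from `seed`, so the whole dataset is reproducible from
#' `(config, n_images, seed)`. Optionally writes each scene as a PNG plus a
#' VOC-dialect annotation XML and a manifest of image paths.
#'
#' @param config a [scene_config()]; its `seed` field is replaced per scene.
#' @param n_images number of scenes (>= 1).
#' @param seed master seed.
#' @param dir optional output directory; created if missing.
#' @return a list of [generate_scene()] results, invisibly carrying
#'   attribute `"manifest"` with the written paths when `dir` is given.
#' @export
generate_dataset <- function(config, n_images, seed = config$seed, dir = NULL) {
  validate_scene_config(config)
  n_images <- as.integer(n_images)
  if (n_images < 1L) stopf("n_images must be >= 1",
                           class = "strawdetect_invalid_argument")
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(seed, i)
    scenes[[i]] <- tryCatch(generate_scene(cfg_i), error = function(e) {
      stopf("scene %d of %d failed: %s", i, n_images, conditionMessage(e),
            class = class(e)[1])
    })
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(n_images)
    for (i in seq_len(n_images)) {
      stem <- sprintf("scene_%04d", i)
      png_path <- file.path(dir, paste0(stem, ".png"))
      png::writePNG(scenes[[i]]$pixels, png_path)
      rec <- annotation_record(paste0(stem, ".png"),
                               c(config$image_width, config$image_height),
                               scenes[[i]]$boxes, scenes[[i]]$labels)
      write_annotation(rec, file.path(dir, paste0(stem, ".xml")))
      paths[i] <- paste0(stem, ".png")
    }
    write_manifest(paths, file.path(dir, "manifest.txt"))
    attr(scenes, "manifest") <- paths
  }
  scenes
}
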