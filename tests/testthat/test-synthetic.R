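test_that("scene generation is seeded-deterministic with exact box counts", {
  cfg <- tiny_scene_config(seed = 1)
  sc1 <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc1$pixels, sc2$pixels)
  expect_identical(sc1$boxes, sc2$boxes)
  expect_equal(nrow(sc1$boxes), 5L)
  expect_equal(sc1$labels, rep("strawberry", 5))

  # a different seed gives a different scene
  sc3 <- generate_scene(tiny_scene_config(seed = 2))
  expect_false(identical(sc1$pixels, sc3$pixels))
})

test_that("all boxes lie within image bounds", {
  for (seed in 1:5) {
    sc <- generate_scene(tiny_scene_config(seed = seed, n_fruit = 8L,
                                           adhesion_fraction = 0.25,
                                           occlusion_fraction = 0.25))
    expect_true(all(sc$boxes[, c("xmin", "ymin")] >= 0))
    expect_true(all(sc$boxes[, "xmax"] <= 64))
    expect_true(all(sc$boxes[, "ymax"] <= 64))
    expect_true(all(sc$boxes[, "xmax"] > sc$boxes[, "xmin"]))
    expect_true(all(sc$boxes[, "ymax"] > sc$boxes[, "ymin"]))
  }
})

test_that("illumination maps monotonically to mean brightness", {
  lux <- c(1000, 2000, 4000, 5000, 6000)
  means <- vapply(lux, function(l) {
    mean(generate_scene(tiny_scene_config(seed = 3,
                                          illumination_lux = l))$pixels)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_lt(means[1], means[5])
})

test_that("stored boxes are tight around each fruit's rendered extent", {
  # without occlusion or adhesion, re-thresholding the red fruit against the
  # green-brown background must reproduce the stored tight box
  sc <- generate_scene(tiny_scene_config(seed = 9, n_fruit = 3L,
                                         noise_sigma = 0))
  red <- sc$pixels[, , 1] - pmax(sc$pixels[, , 2], sc$pixels[, , 3])
  fruit <- red > 0.1
  for (i in seq_len(nrow(sc$boxes))) {
    b <- sc$boxes[i, ]
    sub <- fruit[(b["ymin"] + 1):b["ymax"], (b["xmin"] + 1):b["xmax"]]
    # the mask touches all four edges of the tight box
    expect_true(any(sub[1, ]))
    expect_true(any(sub[nrow(sub), ]))
    expect_true(any(sub[, 1]))
    expect_true(any(sub[, ncol(sub)]))
  }
})

test_that("impossible placements fail distinctly from invalid configs", {
  expect_error(scene_config(image_width = 8),
               class = "strawdetect_invalid_config")
  expect_error(scene_config(adhesion_fraction = 1.2),
               class = "strawdetect_invalid_config")
  expect_error(scene_config(fruit_radius_range = c(1, 5)),
               class = "strawdetect_invalid_config")
  expect_error(scene_config(illumination_lux = 3000),
               class = "strawdetect_invalid_config")
  # 40 large fruit cannot fit without overlap in a 64 x 64 scene
  cfg <- tiny_scene_config(n_fruit = 40L, fruit_radius_range = c(10, 12))
  expect_error(generate_scene(cfg), class = "strawdetect_placement_failure")
})

test_that("datasets derive per-scene seeds from the master seed", {
  cfg <- tiny_scene_config()
  d1 <- generate_dataset(cfg, 4, seed = 11)
  d2 <- generate_dataset(cfg, 4, seed = 11)
  expect_identical(d1, d2)
  expect_length(d1, 4L)
  # scenes differ from each other
  expect_false(identical(d1[[1]]$pixels, d1[[2]]$pixels))
})

test_that("dataset writing produces PNGs, XMLs and a manifest that round-trip", {
  dir <- withr::local_tempdir()
  cfg <- tiny_scene_config(n_fruit = 3L)
  scenes <- generate_dataset(cfg, 2, seed = 5, dir = dir)
  manifest <- read_manifest(file.path(dir, "manifest.txt"))
  expect_length(manifest, 2L)
  px <- png::readPNG(file.path(dir, manifest[1]))
  expect_equal(px[, , 1:3], scenes[[1]]$pixels, tolerance = 1e-9)
  rec <- read_annotation(file.path(dir, sub("\\.png$", ".xml", manifest[1])))
  expect_equal(length(rec$objects), 3L)
})
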