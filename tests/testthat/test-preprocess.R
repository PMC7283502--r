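test_that("median denoising matches the brute-force oracle", {
  # constant image is a fixed point
  cimg <- grey_image(8, 8, 0.5)
  expect_identical(median_denoise(cimg), cimg)

  # isolated hot pixel is removed entirely
  hot <- array(0, dim = c(5, 5, 3))
  hot[3, 3, ] <- 1
  expect_equal(max(median_denoise(hot)), 0)

  # random image agrees with the per-pixel oracle, including edges
  img <- noisy_image(12, 11, seed = 4)
  expect_equal(median_denoise(img), median_oracle(img))

  # idempotence trend: the second application changes no more pixels
  n1 <- sum(median_denoise(img) != img)
  once <- median_denoise(img)
  n2 <- sum(median_denoise(once) != once)
  expect_lte(n2, n1)

  expect_error(median_denoise(img, 4), class = "strawdetect_invalid_argument")
  expect_error(median_denoise(img, 1), class = "strawdetect_invalid_argument")
})

test_that("augmentation produces exactly the 10x expansion", {
  img <- noisy_image(16, 16, seed = 2)
  out <- augment_image(img)
  expect_length(out, 10L)
  expect_true(all(vapply(out, function(x) identical(dim(x), dim(img)),
                         logical(1))))
  expect_identical(out[[1]], img)

  out9 <- augment_image(img, augmentation_recipe(include_original = FALSE))
  expect_length(out9, 9L)
})

test_that("photometric transforms move intensities in the stated direction", {
  img <- grey_image(16, 16, 0.5)
  img[5:10, 5:10, 1] <- 0.8  # some structure so chroma/sharpness act
  out <- augment_image(img, seed = 7)
  base <- mean(img)
  expect_gte(mean(out[[2]]), base)            # brightness x1.2
  expect_lte(mean(out[[6]]), base)            # brightness x0.6
  # contrast: deviations from the mean grow
  dev0 <- mean(abs(img - mean(img)))
  expect_gte(mean(abs(out[[4]] - mean(out[[4]]))), 0.99 * dev0)
  # noise image differs but is seeded-deterministic
  out_b <- augment_image(img, seed = 7)
  expect_identical(out[[10]], out_b[[10]])
  expect_false(identical(out[[10]], img))
})

test_that("augment_dataset concatenates in order and copies annotations", {
  sc <- generate_scene(tiny_scene_config(seed = 2, n_fruit = 3L))
  out <- augment_dataset(list(sc), seed = 1)
  expect_length(out, 10L)
  for (v in out) expect_identical(v$boxes, sc$boxes)

  imgs <- replicate(7, grey_image(8, 8), simplify = FALSE)
  expect_length(augment_dataset(imgs), 70L)
  expect_length(augment_dataset(list()), 0L)
})

test_that("patch tiling covers the image with flush edge tiles", {
  img <- noisy_image(512, 512, seed = 1)
  tiles <- split_patches(img, 256)
  offs <- t(vapply(tiles, function(t) t$offset, numeric(2)))
  expect_equal(nrow(offs), 4L)
  expect_setequal(paste(offs[, 1], offs[, 2]),
                  c("0 0", "256 0", "0 256", "256 256"))

  img300 <- noisy_image(300, 300, seed = 2)
  tiles300 <- split_patches(img300, 256)
  offs300 <- t(vapply(tiles300, function(t) t$offset, numeric(2)))
  expect_equal(nrow(offs300), 4L)
  expect_setequal(unique(as.vector(offs300)), c(0, 44))

  one <- split_patches(noisy_image(256, 256, seed = 3), 256)
  expect_length(one, 1L)
  expect_equal(unname(one[[1]]$offset), c(0, 0))
})

test_that("stitching tiles at their offsets reproduces the image exactly", {
  img <- noisy_image(300, 260, seed = 9)
  tiles <- split_patches(img, 128)
  rebuilt <- array(NA_real_, dim = dim(img))
  for (t in tiles) {
    rebuilt[t$offset[["y"]] + 1:128, t$offset[["x"]] + 1:128, ] <- t$pixels
  }
  expect_identical(rebuilt, img)
})

test_that("small images are reflection-padded to a single patch", {
  img <- noisy_image(100, 120, seed = 5)
  tiles <- split_patches(img, 256)
  expect_length(tiles, 1L)
  expect_equal(dim(tiles[[1]]$pixels), c(256L, 256L, 3L))
  expect_identical(tiles[[1]]$pixels[1:100, 1:120, ], img)
})

test_that("boxes are assigned to patches by inclusive area fraction", {
  tiles <- split_patches(noisy_image(512, 512, seed = 1), 256)
  # fully inside one tile: appears once, translated
  per_tile <- split_boxes_to_patches(matrix(c(300, 300, 340, 340), ncol = 4),
                                     tiles, 256)
  counts <- vapply(per_tile, nrow, integer(1))
  expect_equal(sum(counts), 1L)
  hit <- which(counts == 1)
  expect_equal(unname(per_tile[[hit]][1, ]), c(44, 44, 84, 84))

  # 50/50 straddle with threshold 0.5 appears in both tiles (inclusive)
  straddle <- matrix(c(246, 10, 266, 20), ncol = 4)
  per_tile2 <- split_boxes_to_patches(straddle, tiles, 256)
  expect_equal(sum(vapply(per_tile2, nrow, integer(1))), 2L)

  # 10% overlap is excluded
  weak <- matrix(c(254, 10, 274, 20), ncol = 4)  # 2/20 = 10% in tile 1
  per_tile3 <- split_boxes_to_patches(weak, list(c(x = 0, y = 0)), 256)
  expect_equal(nrow(per_tile3[[1]]), 0L)
})

test_that("dataset splitting uses the floor rule and is exhaustive", {
  s <- split_dataset(as.list(1:4000), split_spec(0.8, seed = 1))
  expect_length(s$train, 3200L)
  expect_length(s$test, 800L)
  expect_setequal(c(unlist(s$train), unlist(s$test)), 1:4000)

  expect_length(split_dataset(as.list(1:10), split_spec())$train, 8L)
  s5 <- split_dataset(as.list(1:5), split_spec(0.8))
  expect_length(s5$train, 4L)
  expect_length(s5$test, 1L)

  # seeded determinism and real shuffling
  a <- split_dataset(as.list(1:100), split_spec(seed = 7))
  b <- split_dataset(as.list(1:100), split_spec(seed = 7))
  expect_identical(a, b)
  expect_false(identical(unlist(a$train), 1:80))

  expect_error(split_dataset(list(1), split_spec()),
               class = "strawdetect_invalid_argument")
  expect_error(split_spec(1.0), class = "strawdetect_invalid_config")
})
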