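test_that("binarization recovers the rendered fruit components", {
  sc1 <- generate_scene(tiny_scene_config(seed = 2))  # 5 isolated fruit
  bm <- binarize(sc1)
  expect_equal(bm$label_count, 5L)
  expect_length(bm$contours, 5L)

  sc3 <- generate_scene(tiny_scene_config(seed = 12, n_fruit = 3L))
  expect_equal(binarize(sc3)$label_count, 3L)

  # all-background image has zero components
  bg <- array(0, dim = c(32, 32, 3))
  bg[, , 2] <- 0.5
  expect_equal(binarize(bg)$label_count, 0L)
})

test_that("rasterized circle curvature approximates 1/r without outliers", {
  disc <- mk_disc(80, 80, 40, 40, 30)
  rm_ <- separate_adhered(disc)   # single disc passes straight through
  expect_equal(rm_$label_count, 1L)
  prof <- curvature_profile(rm_$contours[[1]])
  expect_lt(abs(mean(prof$curvature) - 1 / 30) * 30, 0.15)
  expect_equal(sum(prof$outlier_flags), 0L)
})

test_that("square contours flag outliers exactly at the four corners", {
  sq <- matrix(FALSE, 60, 60)
  sq[15:45, 15:45] <- TRUE
  rm_ <- binarize_matrix_for_test(sq)
  prof <- curvature_profile(rm_$contours[[1]])
  flags <- prof$outlier_flags
  n <- length(flags)
  runs <- sum(flags & !flags[c(n, seq_len(n - 1))])
  expect_equal(runs, 4L)
  # flagged points lie within a window width of a corner
  corners <- rbind(c(15, 15), c(15, 45), c(45, 15), c(45, 45))
  for (p in which(flags)) {
    d <- min(sqrt(rowSums((corners - matrix(prof$points[p, ], 4, 2,
                                            byrow = TRUE))^2)))
    expect_lt(d, 8)
  }
})

test_that("short contours yield an empty curvature profile", {
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  rm_ <- binarize_matrix_for_test(tiny)
  prof <- curvature_profile(rm_$contours[[1]])
  expect_length(prof$curvature, 0L)
})

test_that("isolation decisions follow solidity and curvature", {
  expect_true(is_isolated(mk_disc(80, 80, 40, 40, 25, 20)))  # single ellipse
  fused <- mk_disc(80, 120, 40, 40, 20, 12) | mk_disc(80, 120, 40, 70, 20, 12)
  expect_false(is_isolated(fused))
  crescent <- mk_disc(80, 80, 40, 40, 25) & !mk_disc(80, 80, 20, 40, 22)
  expect_false(is_isolated(crescent))
  # sub-threshold regions are indeterminate, reported isolated
  dot <- matrix(FALSE, 10, 10); dot[4:5, 4:5] <- TRUE
  expect_true(is_isolated(dot))
})

test_that("watershed separates a fused disc pair and passes singles through", {
  fused <- mk_disc(100, 120, 50, 45, 20) | mk_disc(100, 120, 50, 75, 20)
  out <- separate_adhered(fused)
  expect_equal(out$label_count, 2L)

  single <- mk_disc(60, 60, 30, 30, 15)
  expect_equal(separate_adhered(single)$label_count, 1L)

  three <- mk_disc(100, 100, 25, 25, 10) | mk_disc(100, 100, 25, 75, 10) |
    mk_disc(100, 100, 75, 50, 10)
  out3 <- separate_adhered(three)
  expect_equal(out3$label_count, 3L)
  expect_identical(out3$mask, three)   # isolated short-circuit: untouched
})

test_that("separation never decreases the label count (100 random masks)", {
  set.seed(14)
  for (i in 1:100) {
    m <- matrix(FALSE, 48, 48)
    n_blob <- sample(1:3, 1)
    cy <- runif(n_blob, 12, 36); cx <- runif(n_blob, 12, 36)
    r <- runif(n_blob, 4, 9)
    for (b in seq_len(n_blob)) m <- m | mk_disc(48, 48, cy[b], cx[b], r[b])
    before <- max(EBImage::bwlabel(matrix(as.numeric(m), 48, 48)))
    out <- separate_adhered(m)
    expect_gte(out$label_count, before)
  }
})

test_that("separation conserves foreground up to deleted contour pixels", {
  fused <- mk_disc(100, 120, 50, 45, 20) | mk_disc(100, 120, 50, 75, 20)
  out <- separate_adhered(fused)
  expect_true(all(out$mask <= fused))            # no new pixels
  expect_lt(sum(fused) - sum(out$mask), 60)      # only contour points removed
})

test_that("refinement replaces split boxes and recovers missed regions", {
  # scene with adhesion: one fused pair + isolated fruit
  cfg <- tiny_scene_config(seed = 41, n_fruit = 6L, image_width = 96L,
                           image_height = 96L, adhesion_fraction = 0.34)
  sc <- generate_scene(cfg)

  # detections already matching all fruit are (close to) unchanged
  full <- oracle_detector(sc, jitter = 0, drop_rate = 0)
  ref_full <- refine_detections(full, sc)
  expect_gte(nrow(ref_full$boxes), nrow(full$boxes))

  # dropping one fruit: refinement adds recovered boxes
  dropped <- oracle_detector(sc, jitter = 0, drop_rate = 0.35, seed = 4)
  n_missing <- nrow(sc$boxes) - nrow(dropped$boxes)
  expect_gt(n_missing, 0)
  ref <- refine_detections(dropped, sc)
  expect_gt(nrow(ref$boxes), nrow(dropped$boxes))
  expect_true(any(ref$recovered))

  # recall never drops
  ms <- match_spec()
  before <- match_detections(dropped, sc$boxes, ms)
  after <- match_detections(ref, sc$boxes, ms)
  expect_gte(recall(after), recall(before))
})

test_that("a fused pair covered by one detection splits into two boxes", {
  img <- array(0, dim = c(100, 120, 3))
  img[, , 2] <- 0.35; img[, , 3] <- 0.1   # greenish background
  fused <- mk_disc(100, 120, 50, 45, 20) | mk_disc(100, 120, 50, 75, 20)
  img[, , 1][fused] <- 0.85
  img[, , 2][fused] <- 0.12
  img[, , 3][fused] <- 0.10
  one_box <- detection_result(matrix(c(24, 29, 96, 71), ncol = 4), 0.9)
  ref <- refine_detections(one_box, img)
  expect_equal(nrow(ref$boxes), 2L)
  expect_false(any(ref$recovered))
})
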