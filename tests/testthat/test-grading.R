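test_that("plumpness ratio follows the length-to-width formula with folding", {
  expect_equal(plumpness_ratio(bounding_box(10, 10, 30, 30)), 1)
  expect_equal(plumpness_ratio(bounding_box(0, 0, 40, 20)), 0.5)
  # taller-than-wide boxes fold by reciprocal
  expect_equal(plumpness_ratio(bounding_box(0, 0, 20, 40)), 0.5)
  expect_error(plumpness_ratio(c(0, 0, 0, 10)),
               class = "strawdetect_invalid_box")
})

test_that("plumpness ratio is invariant under rotation, translation, scale", {
  set.seed(3)
  for (i in 1:50) {
    w <- runif(1, 1, 40); h <- runif(1, 1, 40)
    x <- runif(1, 0, 50); y <- runif(1, 0, 50)
    r0 <- plumpness_ratio(c(x, y, x + w, y + h))
    expect_equal(plumpness_ratio(c(x, y, x + h, y + w)), r0)  # 90 deg
    expect_equal(plumpness_ratio(c(x + 7, y + 3, x + 7 + w, y + 3 + h)), r0)
    expect_equal(plumpness_ratio(2.5 * c(x, y, x + w, y + h)), r0)
  }
})

test_that("grade bands partition [0, 1] with upper-band boundaries", {
  expect_equal(as.character(grade(0.3)), "Plump")
  expect_equal(as.character(grade(0.5)), "Approximately Plump")
  expect_equal(as.character(grade(0.8)), "Fully Plump")
  expect_equal(as.character(grade(0.95)), "Fully Plump")
  expect_equal(as.character(grade(0)), "Plump")
  expect_equal(as.character(grade(1)), "Fully Plump")
  expect_error(grade(1.2), class = "strawdetect_invalid_argument")
  expect_error(grade(-0.1), class = "strawdetect_invalid_argument")

  # every ratio maps to exactly one band
  set.seed(1)
  ratios <- runif(1e5)
  bands <- grade(ratios)
  expect_false(any(is.na(bands)))
  expect_true(all(ratios[bands == "Plump"] < 0.5))
  expect_true(all(ratios[bands == "Approximately Plump"] >= 0.5 &
                    ratios[bands == "Approximately Plump"] < 0.8))
  expect_true(all(ratios[bands == "Fully Plump"] >= 0.8))
})

test_that("grade reports pool percentages that sum to 100", {
  sq <- t(vapply(1:10, function(i) c(i * 5, 0, i * 5 + 4, 4), numeric(4)))
  rep1 <- grade_detections(sq)
  expect_equal(unname(rep1$distribution[["Fully Plump"]]), 100)

  two <- matrix(c(0, 0, 10, 4,    # ratio 0.4
                  0, 0, 10, 9),   # ratio 0.9
                ncol = 4, byrow = TRUE)
  rep2 <- grade_detections(two)
  expect_equal(unname(rep2$distribution),
               c(50, 0, 50))
  expect_equal(sum(rep2$distribution), 100)

  empty <- grade_detections(matrix(numeric(0), ncol = 4))
  expect_true(empty$empty)
  expect_true(all(is.na(empty$distribution)))
})

test_that("per-image averaging differs from pooling when images differ", {
  img1 <- matrix(c(0, 0, 10, 10), ncol = 4)                 # 1 fully plump
  img2 <- matrix(rep(c(0, 0, 10, 4), 3), ncol = 4, byrow = TRUE)  # 3 plump
  pooled <- grade_detections(rbind(img1, img2))
  by_img <- grade_detections(list(img1, img2), by_image = TRUE)
  expect_equal(unname(pooled$distribution[["Plump"]]), 75)
  expect_equal(unname(by_img$distribution[["Plump"]]), 50)
})

test_that("oracle detections of band-confined scenes grade 100% into that band", {
  cfg <- tiny_scene_config(seed = 31, n_fruit = 4L,
                           fruit_radius_range = c(8, 11),
                           fruit_aspect_range = c(0.85, 0.95),
                           image_width = 96L, image_height = 96L)
  sc <- generate_scene(cfg)
  det <- oracle_detector(sc, jitter = 0, drop_rate = 0)
  rep_ <- grade_detections(det)
  expect_equal(unname(rep_$distribution[["Fully Plump"]]), 100)
})

test_that("grade report serializes to CSV and JSON", {
  rep_ <- grade_detections(matrix(c(0, 0, 10, 9, 0, 0, 10, 4),
                                  ncol = 4, byrow = TRUE))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_grade_report(rep_, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 2L)
  expect_equal(back$ratio, c(0.9, 0.4))
  dist <- jsonlite::read_json(js)
  expect_equal(dist[["Fully Plump"]], 50)
})
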