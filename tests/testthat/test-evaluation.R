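test_that("IOU matches closed-form values and its invariants", {
  a <- bounding_box(0, 0, 2, 2)
  b <- bounding_box(1, 1, 3, 3)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(iou(b, a), 1 / 7)                      # symmetry
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)  # disjoint
  expect_error(iou(c(0, 0, 0, 2), a), class = "strawdetect_invalid_box")

  set.seed(2)
  for (i in 1:50) {
    x <- sort(runif(4, 0, 50)); y <- sort(runif(4, 0, 50))
    b1 <- c(x[1], y[1], x[3], y[3]); b2 <- c(x[2], y[2], x[4], y[4])
    o <- iou(b1, b2)
    expect_gte(o, 0); expect_lte(o, 1)
    expect_equal(o, iou(b2, b1))
  }
})

test_that("accuracy and F-measure match hand arithmetic", {
  expect_equal(accuracy(confusion_counts(40, 50, 5, 5)), 0.9)
  expect_equal(accuracy(confusion_counts(0, 10, 0, 0)), 1)
  expect_equal(accuracy(confusion_counts(0, 0, 3, 7)), 0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)),
               class = "strawdetect_undefined_metric")

  expect_equal(f_measure(confusion_counts(10, 0, 0, 0)), 1)
  expect_equal(f_measure(confusion_counts(8, 0, 2, 0)), 2 * 0.8 / 1.8)
  expect_equal(f_measure(confusion_counts(0, 5, 3, 2)), 0)

  # invariance under scaling all counts
  c1 <- confusion_counts(4, 5, 2, 1)
  c3 <- confusion_counts(12, 15, 6, 3)
  expect_equal(accuracy(c1), accuracy(c3))
  expect_equal(f_measure(c1), f_measure(c3))
})

test_that("greedy matching yields the stated counts", {
  truth <- matrix(c(0, 0, 10, 10,
                    20, 20, 30, 30), ncol = 4, byrow = TRUE)
  # perfect predictions
  cc <- match_detections(truth, truth)
  expect_equal(cc$tp, 2L); expect_equal(cc$fp, 0L); expect_equal(cc$fn, 0L)
  # no predictions
  cc2 <- match_detections(matrix(numeric(0), ncol = 4), truth)
  expect_equal(cc2$fn, 2L); expect_equal(cc2$tp, 0L)
  # two predictions on one truth: greedy takes one, other is FP
  pred <- detection_result(matrix(c(0, 0, 10, 10,
                                    1, 1, 11, 11), ncol = 4, byrow = TRUE),
                           c(0.9, 0.8))
  cc3 <- match_detections(pred, matrix(c(0, 0, 10, 10), ncol = 4))
  expect_equal(cc3$tp, 1L); expect_equal(cc3$fp, 1L); expect_equal(cc3$fn, 0L)
})

test_that("matching count identities hold on random configurations", {
  set.seed(5)
  for (i in 1:30) {
    np <- sample(0:5, 1); nt <- sample(0:5, 1)
    mk <- function(n) {
      if (n == 0) return(matrix(numeric(0), ncol = 4))
      x1 <- runif(n, 0, 50); y1 <- runif(n, 0, 50)
      cbind(x1, y1, x1 + runif(n, 3, 15), y1 + runif(n, 3, 15))
    }
    pm <- mk(np); tm <- mk(nt)
    cc <- match_detections(pm, tm)
    expect_equal(cc$tp + cc$fn, nt)
    expect_equal(cc$tp + cc$fp, np)
  }
})

test_that("greedy matching is within one of the optimal assignment", {
  set.seed(8)
  for (i in 1:60) {
    np <- sample(1:4, 1); nt <- sample(1:4, 1)
    x1 <- runif(np, 0, 30); y1 <- runif(np, 0, 30)
    pm <- cbind(x1, y1, x1 + runif(np, 4, 12), y1 + runif(np, 4, 12))
    x1 <- runif(nt, 0, 30); y1 <- runif(nt, 0, 30)
    tm <- cbind(x1, y1, x1 + runif(nt, 4, 12), y1 + runif(nt, 4, 12))
    greedy <- match_detections(pm, tm, match_spec(iou_threshold = 0.3))$tp
    opt <- optimal_tp(pm, tm, 0.3)
    expect_lte(greedy, opt)
    expect_gte(greedy + 1L, opt)
  }
})

test_that("the TN grid protocol counts cells free of all boxes", {
  # 128 x 128 image, 64 px cells -> 4 cells; one box in the top-left cell
  cc <- match_detections(matrix(c(5, 5, 20, 20), ncol = 4),
                         matrix(c(5, 5, 20, 20), ncol = 4),
                         image_size = c(128, 128))
  expect_equal(cc$tn, 3L)
  expect_equal(accuracy(cc), 1)
})

test_that("ART divides total time by image count", {
  expect_equal(art(10, 50), 0.2)
  expect_equal(art(0, 5), 0)
  expect_equal(art(7.9, 50), 0.158)
  expect_error(art(5, 0), class = "strawdetect_invalid_argument")
})

test_that("count statistics reproduce closed forms", {
  m <- c(80, 95, 110, 125, 140)  # arithmetic, so reversal is exactly linear
  ident <- count_statistics(m, m)
  expect_equal(ident$r, 1)
  expect_equal(ident$nrmse, 0)

  shifted <- count_statistics(m + 2, m)
  expect_equal(shifted$r, 1)
  expect_equal(shifted$nrmse, 2 / mean(m))

  expect_equal(count_statistics(rev(m), m)$r, -1)
  expect_error(count_statistics(rep(3, 4), 1:4),
               class = "strawdetect_undefined_metric")
  expect_error(count_statistics(1:3, 1:4),
               class = "strawdetect_invalid_argument")
})
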