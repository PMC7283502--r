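test_that("residual block with zeroed inner path is the (projected) identity", {
  spec <- residual_block_spec("two_3x3", 4, 4)
  wz <- residual_block_weights(spec, "zero")
  set.seed(1)
  x <- array(rnorm(5 * 5 * 4), dim = c(5, 5, 4))
  expect_identical(residual_block(x, spec, wz), x)

  # projection shortcut: output equals Ws applied to the input
  sp2 <- residual_block_spec("two_3x3", 2, 3)
  expect_true(sp2$projection)
  w2 <- residual_block_weights(sp2, "he", seed = 5)
  w2$w1[] <- 0; w2$w2[] <- 0; w2$b1[] <- 0; w2$b2[] <- 0
  x2 <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  y2 <- residual_block(x2, sp2, w2)
  proj <- array(0, dim = c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) for (co in 1:3) {
    proj[i, j, co] <- sum(x2[i, j, ] * w2$ws[1, 1, , co]) + w2$bs[co]
  }
  expect_equal(y2, proj, tolerance = 1e-12)
})

test_that("residual block matches a loop-based convolution oracle", {
  sp <- residual_block_spec("two_3x3", 2, 2)
  w <- residual_block_weights(sp, "he", seed = 9)
  set.seed(7)
  x <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  f1 <- conv_loop_oracle(x, w$w1, w$b1)
  f2 <- conv_loop_oracle(pmax(f1, 0), w$w2, w$b2)
  expect_equal(residual_block(x, sp, w), f2 + x, tolerance = 1e-5)
})

test_that("bottleneck variant produces the declared output shape", {
  sp <- residual_block_spec("bottleneck_1x1_3x3_1x1", 4, 8)
  w <- residual_block_weights(sp, "he", seed = 2)
  y <- residual_block(array(rnorm(6 * 6 * 4), dim = c(6, 6, 4)), sp, w)
  expect_equal(dim(y), c(6L, 6L, 8L))
  expect_error(residual_block(array(0, dim = c(4, 4, 3)), sp, w),
               class = "strawdetect_shape_error")
})

test_that("network introspection reports the declared architecture", {
  net <- build_network(network_spec(), seed = 1)
  info <- introspect_network(net)
  expect_equal(info$n_backbone_stages, 4L)
  expect_equal(info$adaptive_head_sizes, c(1000L, 256L, 7L))
  expect_equal(info$n_roi_fc_layers, 1L)
  expect_equal(info$roi_fc_width, 2048L)
  expect_equal(info$dropout_rate, 0.5)
  expect_true(info$dropout_after_first_fc)
  expect_equal(info$head_activation, "lrelu_softplus")

  expect_error(network_spec(backbone_channels = c(8, 16)),
               class = "strawdetect_invalid_config")
  expect_error(network_spec(adaptive_head_sizes = c(10, 5)),
               class = "strawdetect_invalid_config")
})

test_that("tiny forward pass runs and inference is deterministic", {
  net <- build_network(tiny_network_spec(), seed = 3)
  sc <- generate_scene(tiny_scene_config(seed = 4))
  d1 <- detect(net, sc, score_threshold = 0)
  d2 <- detect(net, sc, score_threshold = 0)
  expect_s3_class(d1, "detection_result")
  # dropout is removed in evaluation mode: bitwise identical passes
  expect_identical(d1, d2)
  # a threshold above every score empties the result
  d3 <- detect(net, sc, score_threshold = 1)
  expect_equal(nrow(d3$boxes), 0L)
  expect_error(detect(list(), sc), class = "strawdetect_invalid_argument")
})

test_that("detection results keep scores sorted and validated", {
  m <- matrix(c(0, 0, 5, 5, 10, 10, 15, 15), ncol = 4, byrow = TRUE)
  dr <- detection_result(m, c(0.3, 0.9))
  expect_equal(dr$scores, c(0.9, 0.3))
  expect_equal(unname(dr$boxes[1, ]), c(10, 10, 15, 15))
  expect_error(detection_result(m, 0.5),
               class = "strawdetect_invalid_argument")
  expect_error(detection_result(m, c(0.5, 1.2)),
               class = "strawdetect_invalid_argument")
})

test_that("the oracle detector reproduces, jitters and drops ground truth", {
  sc <- generate_scene(tiny_scene_config(seed = 6))
  exact <- oracle_detector(sc, jitter = 0, drop_rate = 0)
  expect_equal(sort(exact$boxes[, 1]), sort(sc$boxes[, 1]))
  expect_true(all(exact$scores == 1))

  none <- oracle_detector(sc, drop_rate = 1)
  expect_equal(nrow(none$boxes), 0L)

  # jitter = 2 keeps IOU > 0.5 for boxes >= 20 px
  big <- generate_scene(tiny_scene_config(seed = 8, image_width = 128L,
                                          image_height = 128L, n_fruit = 5L,
                                          fruit_radius_range = c(11, 14),
                                          fruit_aspect_range = c(0.9, 1)))
  jit <- oracle_detector(big, jitter = 2, drop_rate = 0, seed = 3)
  expect_equal(nrow(jit$boxes), nrow(big$boxes))
  for (i in seq_len(nrow(jit$boxes))) {
    best <- max(vapply(seq_len(nrow(big$boxes)),
                       function(j) iou(jit$boxes[i, ], big$boxes[j, ]),
                       numeric(1)))
    expect_gt(best, 0.5)
  }

  # seeded determinism
  expect_identical(oracle_detector(sc, 1, 0.4, seed = 2),
                   oracle_detector(sc, 1, 0.4, seed = 2))
})

test_that("training is seeded-deterministic and validates inputs", {
  scenes <- generate_dataset(tiny_scene_config(), 4, seed = 21)
  net <- build_network(tiny_network_spec(), seed = 2)
  cfg <- tiny_training_config(epochs = 2L, seed = 5)
  f1 <- train(net, scenes, cfg)
  f2 <- train(net, scenes, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_equal(nrow(f1$loss_trace), 2L)
  expect_error(train(net, list(), cfg),
               class = "strawdetect_invalid_argument")
})

test_that("the learning-rate schedule halves at the scaled boundary", {
  scenes <- generate_dataset(tiny_scene_config(), 4, seed = 22)
  net <- build_network(tiny_network_spec(), seed = 2)
  # 10 epochs x 1 batch = 10 iterations; tiny boundary = 0.6 * 10 = 6
  fit <- train(net, scenes, tiny_training_config(epochs = 10L, seed = 1))
  expect_equal(fit$loss_trace$lr[1:6], rep(0.001, 6))
  expect_equal(fit$loss_trace$lr[7:10], rep(0.0005, 4))
  expect_equal(unique(fit$loss_trace$lr), c(0.001, 0.0005))
})

test_that("training configs validate the published hyperparameters", {
  cfg <- training_config()
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$lr_after, 0.0005)
  expect_equal(cfg$lr_boundary, 3000L)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$loss, "dice")
  expect_error(training_config(lr = 0), class = "strawdetect_invalid_config")
  expect_error(training_config(epochs = 0),
               class = "strawdetect_invalid_config")
})
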