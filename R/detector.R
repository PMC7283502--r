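#' Detection results
#'
#' A set of scored boxes: the output unit of the detector and the input
#' unit of grading, post-processing and evaluation. Boxes are stored sorted
#' by descending score.
#'
#' @param boxes boxes in any form accepted by [box_matrix()].
#' @param scores per-box confidence in `[0, 1]`.
#' @param recovered optional logical per box, marking boxes added by
#'   post-processing rather than by the detector.
#' @return an object of class `"detection_result"`.
#' @export
detection_result <- function(boxes, scores = numeric(0), recovered = NULL) {
  m <- box_matrix(boxes)
  scores <- as.numeric(scores)
  if (length(scores) != nrow(m)) {
    stopf("need one score per box (%d boxes, %d scores)", nrow(m),
          length(scores), class = "strawdetect_invalid_argument")
  }
  if (length(scores) && (any(scores < 0) || any(scores > 1))) {
    stopf("scores must lie in [0, 1]", class = "strawdetect_invalid_argument")
  }
  if (is.null(recovered)) recovered <- rep(FALSE, nrow(m))
  ord <- order(scores, decreasing = TRUE)
  structure(list(boxes = m[ord, , drop = FALSE], scores = scores[ord],
                 recovered = recovered[ord]),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result: %d box(es)%s>\n", nrow(x$boxes),
              if (any(x$recovered)) sprintf(", %d recovered", sum(x$recovered))
              else ""))
  invisible(x)
}

# standard greedy non-maximum suppression at the given IOU threshold;
# assumes boxes already sorted by descending score
nms_keep <- function(boxes, iou_threshold = 0.5) {
  n <- nrow(boxes)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in which(keep)) {
      if (iou(boxes[i, ], boxes[j, ]) > iou_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  keep
}

#' Activation configuration
#'
#' @param kind `"relu"` or `"lrelu_softplus"`.
#' @param a negative-side slope for `lrelu_softplus` (default 0.01).
#' @export
activation_config <- function(kind = c("lrelu_softplus", "relu"), a = 0.01) {
  kind <- match.arg(kind)
  if (a <= 0) stopf("slope `a` must be > 0",
                    class = "strawdetect_invalid_config")
  structure(list(kind = kind, a = a), class = "activation_config")
}

apply_activation <- function(x, act) {
  if (act$kind == "relu") relu(x) else lrelu_softplus(x, act$a)
}

activation_grad <- function(x, act) {
  if (act$kind == "relu") as.numeric(x > 0) else lrelu_softplus_grad(x, act$a)
}

#' Residual block
#'
#' The residual unit `y = F(x, W1, W2) + Ws x`: an inner convolutional path
#' `F` added to a shortcut that is the identity, or a learned 1 x 1
#' projection `Ws` when the channel count or spatial stride changes. Two
#' variants exist: two 3 x 3 convolutions in series, or the bottleneck
#' 1 x 1, 3 x 3, 1 x 1 stack. No activation is applied to `y` itself (the
#' surrounding network applies its activation after the addition).
#'
#' @param variant `"two_3x3"` or `"bottleneck_1x1_3x3_1x1"`.
#' @param channels_in,channels_out input/output channel counts.
#' @param stride spatial stride of the first convolution.
#' @param bottleneck_channels inner width of the bottleneck variant
#'   (default `channels_out / 4`, at least 1).
#' @return an object of class `"residual_block_spec"`; `projection` is
#'   `TRUE` iff `channels_in != channels_out` or `stride != 1`.
#' @export
residual_block_spec <- function(variant = c("two_3x3", "bottleneck_1x1_3x3_1x1"),
                                channels_in, channels_out, stride = 1L,
                                bottleneck_channels = NULL) {
  variant <- match.arg(variant)
  channels_in <- as.integer(channels_in)
  channels_out <- as.integer(channels_out)
  stride <- as.integer(stride)
  if (channels_in < 1L || channels_out < 1L || stride < 1L) {
    stopf("channel counts and stride must be >= 1",
          class = "strawdetect_invalid_config")
  }
  if (is.null(bottleneck_channels)) {
    bottleneck_channels <- max(1L, channels_out %/% 4L)
  }
  structure(list(variant = variant, channels_in = channels_in,
                 channels_out = channels_out, stride = stride,
                 bottleneck_channels = as.integer(bottleneck_channels),
                 projection = channels_in != channels_out || stride != 1L),
            class = "residual_block_spec")
}

#' @rdname residual_block_spec
#' @param spec a `residual_block_spec`.
#' @param init `"he"` for seeded He-normal weights or `"zero"`.
#' @param seed RNG seed for `"he"` init.
#' @return `residual_block_weights()`: named list of weight/bias arrays
#'   (`w1, b1, w2, b2`, plus `w3, b3` for the bottleneck and `ws, bs` when
#'   the shortcut is a projection).
#' @export
residual_block_weights <- function(spec, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  gen_conv <- function(k, cin, cout) {
    if (init == "zero") array(0, dim = c(k, k, cin, cout))
    else he_init_conv(k, cin, cout)
  }
  with_seed(seed, {
    w <- if (spec$variant == "two_3x3") {
      list(w1 = gen_conv(3L, spec$channels_in, spec$channels_out),
           b1 = numeric(spec$channels_out),
           w2 = gen_conv(3L, spec$channels_out, spec$channels_out),
           b2 = numeric(spec$channels_out))
    } else {
      bc <- spec$bottleneck_channels
      list(w1 = gen_conv(1L, spec$channels_in, bc), b1 = numeric(bc),
           w2 = gen_conv(3L, bc, bc), b2 = numeric(bc),
           w3 = gen_conv(1L, bc, spec$channels_out),
           b3 = numeric(spec$channels_out))
    }
    if (spec$projection) {
      w$ws <- gen_conv(1L, spec$channels_in, spec$channels_out)
      w$bs <- numeric(spec$channels_out)
    }
    w
  })
}

#' @rdname residual_block_spec
#' @param x feature tensor, array (H, W, channels_in).
#' @param weights weights from [residual_block_weights()].
#' @return `residual_block()`: the output feature tensor
#'   (H/stride, W/stride, channels_out).
#' @export
residual_block <- function(x, spec, weights) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stopf("`x` must be an (H, W, C) array", class = "strawdetect_shape_error")
  }
  if (dim(x)[3] != spec$channels_in) {
    stopf("input has %d channels but the block expects %d",
          dim(x)[3], spec$channels_in, class = "strawdetect_shape_error")
  }
  inner <- if (spec$variant == "two_3x3") {
    c1 <- conv_forward(x, weights$w1, weights$b1, stride = spec$stride)
    a1 <- relu(c1$out)
    conv_forward(a1, weights$w2, weights$b2, stride = 1L)$out
  } else {
    c1 <- conv_forward(x, weights$w1, weights$b1, stride = spec$stride,
                       pad = 0L)
    a1 <- relu(c1$out)
    c2 <- conv_forward(a1, weights$w2, weights$b2, stride = 1L)
    a2 <- relu(c2$out)
    conv_forward(a2, weights$w3, weights$b3, stride = 1L, pad = 0L)$out
  }
  shortcut <- if (spec$projection) {
    conv_forward(x, weights$ws, weights$bs, stride = spec$stride, pad = 0L)$out
  } else {
    x
  }
  inner + shortcut
}

#' Detector architecture specification
#'
#' Declarative description of the detector: a backbone of four residual
#' stages (M1-M4) feeding a region-proposal branch (dense per-cell
#' objectness + box regression over anchors) and a region head with a
#' single wide fully connected layer, dropout after it, and a three-layer
#' adaptive classification head (N1-N3). The default head widths are
#' 1000, 256 and 7 neurons with the `lrelu_softplus` activation; the
#' region head has exactly one fully connected layer of `roi_fc_width`
#' neurons (2048 by default).
#'
#' @param backbone_channels integer vector of 4 stage widths.
#' @param backbone_strides integer vector of 4 stage strides.
#' @param rpn_channels width of the proposal branch's hidden convolution.
#' @param anchor_scales,anchor_ratios anchor box sizes (pixels) and
#'   height/width ratios; one anchor per scale x ratio combination. Chosen
#'   to bracket the synthetic fruit size range.
#' @param adaptive_head_sizes integer vector of 3 head widths (N1-N3).
#' @param head_activation an [activation_config()].
#' @param roi_fc_width width of the single region FC layer.
#' @param roi_pool_size pooled feature grid edge.
#' @param dropout_rate dropout probability after the first FC layer.
#' @param class_unit which N3 unit carries the strawberry logit.
#' @return an object of class `"network_spec"`.
#' @export
network_spec <- function(backbone_channels = c(8L, 16L, 32L, 64L),
                         backbone_strides = c(2L, 2L, 1L, 1L),
                         rpn_channels = 16L,
                         anchor_scales = c(24, 40),
                         anchor_ratios = c(1),
                         adaptive_head_sizes = c(1000L, 256L, 7L),
                         head_activation = activation_config("lrelu_softplus"),
                         roi_fc_width = 2048L,
                         roi_pool_size = 7L,
                         dropout_rate = 0.5,
                         class_unit = 1L) {
  if (length(backbone_channels) != 4L || length(backbone_strides) != 4L) {
    stopf("backbone must have exactly 4 stages",
          class = "strawdetect_invalid_config")
  }
  if (length(adaptive_head_sizes) != 3L) {
    stopf("adaptive head must have exactly 3 layers",
          class = "strawdetect_invalid_config")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stopf("dropout_rate must lie in [0, 1)",
          class = "strawdetect_invalid_config")
  }
  anchors <- expand.grid(scale = anchor_scales, ratio = anchor_ratios)
  structure(list(backbone_channels = as.integer(backbone_channels),
                 backbone_strides = as.integer(backbone_strides),
                 rpn_channels = as.integer(rpn_channels),
                 anchor_scales = anchor_scales,
                 anchor_ratios = anchor_ratios,
                 anchor_w = anchors$scale / sqrt(anchors$ratio),
                 anchor_h = anchors$scale * sqrt(anchors$ratio),
                 adaptive_head_sizes = as.integer(adaptive_head_sizes),
                 head_activation = head_activation,
                 roi_fc_width = as.integer(roi_fc_width),
                 roi_pool_size = as.integer(roi_pool_size),
                 dropout_rate = dropout_rate,
                 dropout_after_first_fc = TRUE,
                 class_unit = as.integer(class_unit)),
            class = "network_spec")
}

#' @rdname network_spec
#' @param ... overrides passed to [network_spec()].
#' @details `tiny_network_spec()` is the desk-scale preset used for CPU
#'   training on small synthetic scenes: narrow stages, a single anchor
#'   sized to the synthetic fruit, a 2-class head and small FC widths.
#' @export
tiny_network_spec <- function(...) {
  defaults <- list(backbone_channels = c(4L, 8L, 16L, 16L),
                   backbone_strides = c(2L, 2L, 1L, 1L),
                   rpn_channels = 8L,
                   anchor_scales = c(11),
                   anchor_ratios = c(1),
                   adaptive_head_sizes = c(32L, 16L, 2L),
                   roi_fc_width = 64L,
                   roi_pool_size = 2L,
                   dropout_rate = 0.5)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(network_spec, defaults)
}

#' Build a detector network
#'
#' Allocates seeded He-initialised weights for the architecture described
#' by the spec and returns a model handle exposing a forward pass
#' (image -> [detection_result()], via [detect()]) and structural
#' introspection ([introspect_network()]).
#'
#' @param spec a [network_spec()].
#' @param seed weight initialisation seed.
#' @return an object of class `"strawberry_network"`.
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "network_spec")) {
    stopf("`spec` must be a network_spec",
          class = "strawdetect_invalid_argument")
  }
  params <- with_seed(seed, {
    cin <- 3L
    stages <- vector("list", 4L)
    for (s in 1:4) {
      cout <- spec$backbone_channels[s]
      stages[[s]] <- list(
        down = list(w = he_init_conv(3L, cin, cout), b = numeric(cout)),
        res = list(w1 = he_init_conv(3L, cout, cout), b1 = numeric(cout),
                   w2 = he_init_conv(3L, cout, cout), b2 = numeric(cout)))
      cin <- cout
    }
    n_anchor <- length(spec$anchor_w)
    rpn <- list(hidden = list(w = he_init_conv(3L, cin, spec$rpn_channels),
                              b = numeric(spec$rpn_channels)),
                # objectness bias starts at a low foreground prior so the
                # dice denominator is small from the first iteration and
                # its gradients do not vanish at the p = 0.5 saddle
                obj = list(w = he_init_conv(1L, spec$rpn_channels, n_anchor),
                           b = rep(-2, n_anchor)),
                box = list(w = he_init_conv(1L, spec$rpn_channels, 4L * n_anchor),
                           b = numeric(4L * n_anchor)))
    pooled <- spec$roi_pool_size^2 * cin
    hs <- spec$adaptive_head_sizes
    head <- list(fc = list(w = he_init_fc(pooled, spec$roi_fc_width),
                           b = numeric(spec$roi_fc_width)),
                 n1 = list(w = he_init_fc(spec$roi_fc_width, hs[1]),
                           b = numeric(hs[1])),
                 n2 = list(w = he_init_fc(hs[1], hs[2]), b = numeric(hs[2])),
                 n3 = list(w = he_init_fc(hs[2], hs[3]), b = rep(-2, hs[3])))
    list(stages = stages, rpn = rpn, head = head)
  })
  structure(list(spec = spec, params = params, trained = FALSE),
            class = "strawberry_network")
}

#' @rdname build_network
#' @param model a `strawberry_network` or trained `strawberry_detector`.
#' @return `introspect_network()`: named list reporting backbone stage
#'   count and widths, head layer widths, region FC width and count,
#'   dropout placement and rate, and the head activation kind.
#' @export
introspect_network <- function(model) {
  net <- as_network(model)
  spec <- net$spec
  list(n_backbone_stages = length(net$params$stages),
       backbone_channels = spec$backbone_channels,
       adaptive_head_sizes = spec$adaptive_head_sizes,
       n_roi_fc_layers = 1L,
       roi_fc_width = spec$roi_fc_width,
       dropout_rate = spec$dropout_rate,
       dropout_after_first_fc = spec$dropout_after_first_fc,
       head_activation = spec$head_activation$kind,
       n_anchors = length(spec$anchor_w))
}

as_network <- function(model) {
  if (inherits(model, "strawberry_network")) return(model)
  if (inherits(model, "strawberry_detector")) return(model$network)
  stopf("not a detector model handle (build_network() or train() result)",
        class = "strawdetect_invalid_argument")
}

#' @export
print.strawberry_network <- function(x, ...) {
  info <- introspect_network(x)
  cat(sprintf(paste0("<strawberry_network: 4 residual stages (%s), head ",
                     "%s, roi fc %d, %s>\n"),
              paste(info$backbone_channels, collapse = "/"),
              paste(info$adaptive_head_sizes, collapse = "/"),
              info$roi_fc_width, info$head_activation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# forward / backward passes

backbone_forward <- function(params, x) {
  caches <- vector("list", 4L)
  strides <- attr(params, "strides")
  for (s in 1:4) {
    st <- params$stages[[s]]
    c1 <- conv_forward(x, st$down$w, st$down$b, stride = strides[s])
    a1 <- relu(c1$out)
    r1 <- conv_forward(a1, st$res$w1, st$res$b1, stride = 1L)
    ra <- relu(r1$out)
    r2 <- conv_forward(ra, st$res$w2, st$res$b2, stride = 1L)
    y <- a1 + r2$out
    out <- relu(y)
    caches[[s]] <- list(c1 = c1, pre1 = c1$out, r1 = r1, pre_ra = r1$out,
                        r2 = r2, y = y)
    x <- out
  }
  list(out = x, caches = caches)
}

backbone_backward <- function(d_out, params, caches) {
  grads <- list(stages = vector("list", 4L))
  for (s in 4:1) {
    cc <- caches[[s]]
    dy <- d_out * (cc$y > 0)
    b2 <- conv_backward(dy, cc$r2$cache)
    dra <- b2$dx * (cc$pre_ra > 0)
    b1 <- conv_backward(dra, cc$r1$cache)
    da1 <- dy + b1$dx                      # shortcut + inner path
    dc1 <- da1 * (cc$pre1 > 0)
    bd <- conv_backward(dc1, cc$c1$cache)
    grads$stages[[s]] <- list(down = list(w = bd$dw, b = bd$db),
                              res = list(w1 = b1$dw, b1 = b1$db,
                                         w2 = b2$dw, b2 = b2$db))
    d_out <- bd$dx
  }
  grads
}

rpn_forward <- function(params, feat) {
  h <- conv_forward(feat, params$rpn$hidden$w, params$rpn$hidden$b)
  ha <- relu(h$out)
  obj <- conv_forward(ha, params$rpn$obj$w, params$rpn$obj$b, pad = 0L)
  box <- conv_forward(ha, params$rpn$box$w, params$rpn$box$b, pad = 0L)
  list(obj = obj$out, box = box$out,
       caches = list(h = h, pre_h = h$out, obj = obj, box = box))
}

rpn_backward <- function(d_obj, d_box, caches) {
  bo <- conv_backward(d_obj, caches$obj$cache)
  bb <- conv_backward(d_box, caches$box$cache)
  dha <- bo$dx + bb$dx
  dh <- dha * (caches$pre_h > 0)
  bh <- conv_backward(dh, caches$h$cache)
  list(grads = list(hidden = list(w = bh$dw, b = bh$db),
                    obj = list(w = bo$dw, b = bo$db),
                    box = list(w = bb$dw, b = bb$db)),
       d_feat = bh$dx)
}

head_forward <- function(params, x, spec, train = FALSE) {
  act <- spec$head_activation
  f <- fc_forward(x, params$head$fc$w, params$head$fc$b)
  a0 <- apply_activation(f$out, act)
  mask <- NULL
  keep <- 1 - spec$dropout_rate
  if (train && spec$dropout_rate > 0) {
    mask <- as.numeric(stats::runif(length(a0)) < keep)
    a0d <- a0 * mask
  } else {
    # dropout removed at test time; outputs scaled by the retention
    # probability to preserve the expected magnitude
    a0d <- a0 * keep
  }
  h1 <- fc_forward(a0d, params$head$n1$w, params$head$n1$b)
  a1 <- apply_activation(h1$out, act)
  h2 <- fc_forward(a1, params$head$n2$w, params$head$n2$b)
  a2 <- apply_activation(h2$out, act)
  h3 <- fc_forward(a2, params$head$n3$w, params$head$n3$b)
  # N3's class unit is read as a raw logit: squashing it through the hybrid
  # activation would floor the score near 0.5 and kill negative-side
  # gradients, leaving the head unable to reject background proposals
  logit <- h3$out[spec$class_unit]
  list(logit = logit, score = sigmoid(logit),
       cache = list(f = f, pre0 = f$out, mask = mask, keep = keep,
                    h1 = h1, pre1 = h1$out, h2 = h2, pre2 = h2$out,
                    h3 = h3, pre3 = h3$out, act = act))
}

head_backward <- function(d_logit, cache, spec) {
  act <- cache$act
  d3 <- numeric(length(cache$pre3))
  d3[spec$class_unit] <- d_logit
  b3 <- fc_backward(d3, cache$h3$cache)
  d2 <- b3$dx * activation_grad(cache$pre2, act)
  b2 <- fc_backward(d2, cache$h2$cache)
  d1 <- b2$dx * activation_grad(cache$pre1, act)
  b1 <- fc_backward(d1, cache$h1$cache)
  d0 <- b1$dx
  d0 <- if (is.null(cache$mask)) d0 * cache$keep else d0 * cache$mask
  d0 <- d0 * activation_grad(cache$pre0, act)
  bf <- fc_backward(d0, cache$f$cache)
  list(fc = list(w = bf$dw, b = bf$db),
       n1 = list(w = b1$dw, b = b1$db),
       n2 = list(w = b2$dw, b = b2$db),
       n3 = list(w = b3$dw, b = b3$db))
}

# anchor geometry: cell centres in 0-based image coordinates for a feature
# map of h_f x w_f at total stride s
anchor_centers <- function(h_f, w_f, s) {
  list(xc = (seq_len(w_f) - 0.5) * s, yc = (seq_len(h_f) - 0.5) * s)
}

decode_boxes <- function(cells, deltas, spec, s, image_w, image_h) {
  out <- matrix(NA_real_, nrow = nrow(cells), ncol = 4)
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]; a <- cells[r, 3]
    xc <- (j - 0.5) * s + deltas[r, 1] * spec$anchor_w[a]
    yc <- (i - 0.5) * s + deltas[r, 2] * spec$anchor_h[a]
    bw <- spec$anchor_w[a] * exp(pmin(pmax(deltas[r, 3], -3), 3))
    bh <- spec$anchor_h[a] * exp(pmin(pmax(deltas[r, 4], -3), 3))
    x1 <- max(0, xc - bw / 2); x2 <- min(image_w, xc + bw / 2)
    y1 <- max(0, yc - bh / 2); y2 <- min(image_h, yc + bh / 2)
    out[r, ] <- c(x1, y1, x2, y2)
  }
  out
}

pool_roi <- function(feat, box, s, p) {
  h_f <- dim(feat)[1]; w_f <- dim(feat)[2]; cc <- dim(feat)[3]
  fx1 <- box[1] / s; fx2 <- box[3] / s
  fy1 <- box[2] / s; fy2 <- box[4] / s
  i1 <- max(1L, min(h_f, floor(fy1) + 1L)); i2 <- max(i1, min(h_f, ceiling(fy2)))
  j1 <- max(1L, min(w_f, floor(fx1) + 1L)); j2 <- max(j1, min(w_f, ceiling(fx2)))
  ri <- i1:i2; cj <- j1:j2
  bins_i <- split(ri, cut(seq_along(ri), p, labels = FALSE))
  bins_j <- split(cj, cut(seq_along(cj), p, labels = FALSE))
  out <- numeric(p * p * cc)
  idx <- 1L
  for (ch in seq_len(cc)) {
    for (bj in seq_len(p)) {
      for (bi in seq_len(p)) {
        rows <- bins_i[[min(bi, length(bins_i))]]
        cols <- bins_j[[min(bj, length(bins_j))]]
        out[idx] <- mean(feat[rows, cols, ch])
        idx <- idx + 1L
      }
    }
  }
  out
}

# objectness / regression targets for one image
rpn_targets <- function(gt, spec, h_f, w_f, s) {
  n_anchor <- length(spec$anchor_w)
  t_obj <- array(0, dim = c(h_f, w_f, n_anchor))
  assign_gt <- array(0L, dim = c(h_f, w_f, n_anchor))
  ac <- anchor_centers(h_f, w_f, s)
  if (nrow(gt) > 0) {
    gxc <- (gt[, 1] + gt[, 3]) / 2
    gyc <- (gt[, 2] + gt[, 4]) / 2
    for (i in seq_len(h_f)) {
      for (j in seq_len(w_f)) {
        inside <- which(gt[, 1] <= ac$xc[j] & ac$xc[j] < gt[, 3] &
                          gt[, 2] <= ac$yc[i] & ac$yc[i] < gt[, 4])
        if (length(inside) > 0) {
          d <- (gxc[inside] - ac$xc[j])^2 + (gyc[inside] - ac$yc[i])^2
          g <- inside[which.min(d)]
          t_obj[i, j, ] <- 1
          assign_gt[i, j, ] <- g
        }
      }
    }
  }
  list(t_obj = t_obj, assign_gt = assign_gt)
}

# single-image loss + gradients; returns NULL grads for an empty image
detector_train_step <- function(params, spec, image, gt, strides_total,
                                n_rois = 16L,
                                loss_weights = c(obj = 1, box = 1, head = 1)) {
  bf <- backbone_forward(params, image)
  rf <- rpn_forward(params, bf$out)
  h_f <- dim(rf$obj)[1]; w_f <- dim(rf$obj)[2]
  s <- strides_total
  p_obj <- sigmoid(rf$obj)
  tg <- rpn_targets(gt, spec, h_f, w_f, s)
  dl <- dice_loss(as.vector(p_obj), as.vector(tg$t_obj))
  w_obj <- loss_weights[["obj"]]
  d_obj <- array(w_obj * dl$grad * as.vector(p_obj * (1 - p_obj)),
                 dim = dim(rf$obj))

  # box regression at positive anchors
  d_box <- array(0, dim = dim(rf$box))
  loss_box <- 0
  pos <- which(tg$t_obj == 1, arr.ind = TRUE)
  if (nrow(pos) > 0) {
    ac <- anchor_centers(h_f, w_f, s)
    n_pos <- nrow(pos)
    for (r in seq_len(n_pos)) {
      i <- pos[r, 1]; j <- pos[r, 2]; a <- pos[r, 3]
      g <- tg$assign_gt[i, j, a]
      gw <- gt[g, 3] - gt[g, 1]; gh <- gt[g, 4] - gt[g, 2]
      tx <- ((gt[g, 1] + gt[g, 3]) / 2 - ac$xc[j]) / spec$anchor_w[a]
      ty <- ((gt[g, 2] + gt[g, 4]) / 2 - ac$yc[i]) / spec$anchor_h[a]
      tw <- log(gw / spec$anchor_w[a]); th <- log(gh / spec$anchor_h[a])
      pred <- rf$box[i, j, (a - 1L) * 4L + 1:4]
      d <- pred - c(tx, ty, tw, th)
      loss_box <- loss_box + sum(smooth_l1(d))
      d_box[i, j, (a - 1L) * 4L + 1:4] <-
        loss_weights[["box"]] * smooth_l1_grad(d) / n_pos
    }
    loss_box <- loss_box / n_pos
  }

  # region head on current proposals (pooled features detached)
  ord <- order(p_obj, decreasing = TRUE)[seq_len(min(n_rois, length(p_obj)))]
  cells <- arrayInd(ord, dim(p_obj))
  deltas <- matrix(0, nrow(cells), 4)
  for (r in seq_len(nrow(cells))) {
    deltas[r, ] <- rf$box[cells[r, 1], cells[r, 2], (cells[r, 3] - 1L) * 4L + 1:4]
  }
  rois <- decode_boxes(cells, deltas, spec, s, dim(image)[2], dim(image)[1])
  valid <- rois[, 1] < rois[, 3] & rois[, 2] < rois[, 4]
  head_grads <- NULL
  loss_head <- 0
  if (any(valid)) {
    rois_v <- rois[valid, , drop = FALSE]
    labels <- vapply(seq_len(nrow(rois_v)), function(r) {
      if (nrow(gt) == 0) return(0)
      best <- max(vapply(seq_len(nrow(gt)),
                         function(g) iou(rois_v[r, ], gt[g, ]), numeric(1)))
      as.numeric(best >= 0.5)
    }, numeric(1))
    scores <- numeric(nrow(rois_v))
    hcaches <- vector("list", nrow(rois_v))
    pooled_list <- vector("list", nrow(rois_v))
    for (r in seq_len(nrow(rois_v))) {
      pooled_list[[r]] <- pool_roi(bf$out, rois_v[r, ], s, spec$roi_pool_size)
      hf <- head_forward(params, pooled_list[[r]], spec, train = TRUE)
      scores[r] <- hf$score
      hcaches[[r]] <- hf$cache
    }
    hd <- dice_loss(scores, labels)
    loss_head <- hd$loss
    for (r in seq_len(nrow(rois_v))) {
      d_logit <- loss_weights[["head"]] * hd$grad[r] * scores[r] * (1 - scores[r])
      g <- head_backward(d_logit, hcaches[[r]], spec)
      head_grads <- if (is.null(head_grads)) g else tree_map2(head_grads, g, `+`)
    }
  }

  rb <- rpn_backward(d_obj, d_box, rf$caches)
  bg <- backbone_backward(rb$d_feat, params, bf$caches)

  grads <- list(stages = bg$stages, rpn = rb$grads,
                head = if (is.null(head_grads)) zero_like(params$head) else head_grads)
  list(loss = w_obj * dl$loss + loss_weights[["box"]] * loss_box +
         loss_weights[["head"]] * loss_head,
       grads = grads)
}

# --- parameter-tree helpers -------------------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

zero_like <- function(a) tree_map(a, function(x) x * 0)

#' Training configuration
#'
#' The detector's hyperparameter schedule: dice loss, SGD with momentum
#' 0.9, base learning rate 0.001 for the first 3000 iterations then 0.0005,
#' dropout 0.5, 200 epochs, batch size 64. In tiny mode (small network,
#' small synthetic scenes, CPU-scale epochs) the learning-rate boundary is
#' scaled proportionally so the two-phase schedule is preserved: the first
#' 60% of iterations run at `lr`, the remainder at `lr_after` (3000 of the
#' 5000 planned iterations).
#'
#' @param loss loss name; `"dice"` (soft-Dice on the binary
#'   object-vs-background targets, with smooth-L1 box regression retained).
#' @param lr,lr_after learning rates of the two schedule phases.
#' @param lr_boundary iteration index at which the rate drops.
#' @param momentum SGD momentum.
#' @param dropout dropout rate applied after the first FC layer.
#' @param epochs,batch_size training duration and batch size.
#' @param seed RNG seed covering shuffling, dropout and any other
#'   stochastic choice; training is a pure function of (data, config,
#'   seed).
#' @param tiny_mode scale the schedule boundary to the actual number of
#'   iterations.
#' @param grad_clip clip the global gradient norm of each batch update to
#'   this value before the momentum step (`Inf` disables). Stabilises the
#'   weighted-Dice phase of short from-scratch schedules.
#' @param loss_weights named weights `c(obj, box, head)` balancing the
#'   three loss terms. Multi-task weighting is a free calibration of
#'   two-stage detectors; the soft-Dice objectness term has gradients
#'   inversely proportional to the foreground size, so the tiny preset
#'   up-weights it to keep the three terms' gradient magnitudes comparable
#'   within a short from-scratch schedule.
#' @return an object of class `"training_config"`.
#' @export
training_config <- function(loss = "dice", lr = 0.001, lr_after = 0.0005,
                            lr_boundary = 3000L, momentum = 0.9,
                            dropout = 0.5, epochs = 200L, batch_size = 64L,
                            seed = 1L, tiny_mode = FALSE,
                            loss_weights = c(obj = 1, box = 1, head = 1),
                            grad_clip = Inf) {
  if (lr <= 0 || lr_after <= 0) {
    stopf("learning rates must be > 0", class = "strawdetect_invalid_config")
  }
  if (epochs < 1L) stopf("epochs must be >= 1",
                         class = "strawdetect_invalid_config")
  if (!all(c("obj", "box", "head") %in% names(loss_weights)) ||
      any(loss_weights <= 0)) {
    stopf("loss_weights must be positive and named obj, box, head",
          class = "strawdetect_invalid_config")
  }
  structure(list(loss = loss, lr = lr, lr_after = lr_after,
                 lr_boundary = as.integer(lr_boundary), momentum = momentum,
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 tiny_mode = isTRUE(tiny_mode), loss_weights = loss_weights,
                 grad_clip = grad_clip),
            class = "training_config")
}

#' @rdname training_config
#' @param ... overrides passed to [training_config()].
#' @export
tiny_training_config <- function(...) {
  defaults <- list(epochs = 20L, batch_size = 4L, tiny_mode = TRUE,
                   loss_weights = c(obj = 50, box = 5, head = 5),
                   grad_clip = 10)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(training_config, defaults)
}

#' Train the detector
#'
#' Seeded SGD-with-momentum training of the detector on annotated scenes:
#' soft-Dice loss on the dense objectness map, smooth-L1 box regression at
#' positive anchors, and soft-Dice classification loss on region proposals
#' through the adaptive head. Dropout is active during training only.
#'
#' @param model a [build_network()] handle (an untrained
#'   `strawberry_network`).
#' @param train_set non-empty list of `annotated_image` scenes (or
#'   `list(pixels, boxes)` pairs).
#' @param config a [training_config()].
#' @return an object of class `"strawberry_detector"`: the trained network
#'   plus `loss_trace`, a data frame with one row per epoch
#'   (`epoch, loss, lr`).
#' @export
train <- function(model, train_set, config = tiny_training_config()) {
  net <- as_network(model)
  if (length(train_set) == 0L) {
    stopf("training set is empty", class = "strawdetect_invalid_argument")
  }
  spec <- net$spec
  spec$dropout_rate <- config$dropout
  params <- net$params
  attr(params, "strides") <- spec$backbone_strides
  s_total <- prod(spec$backbone_strides)
  n <- length(train_set)
  n_batches <- ceiling(n / config$batch_size)
  total_iters <- config$epochs * n_batches
  boundary <- if (config$tiny_mode) {
    planned <- config$lr_boundary / (config$lr_boundary + 2000)
    max(1L, round(planned * total_iters))
  } else {
    config$lr_boundary
  }
  images <- lapply(train_set, function(x) if (is.list(x)) x$pixels else x)
  gts <- lapply(train_set, function(x) box_matrix(x$boxes))

  trace <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  params <- with_seed(config$seed, {
    vel <- zero_like(params)
    iter <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_losses <- numeric(0)
      lr_now <- config$lr
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
        acc <- NULL
        for (i in idx) {
          step <- detector_train_step(params, spec, images[[i]], gts[[i]],
                                      s_total,
                                      loss_weights = config$loss_weights)
          if (!is.finite(step$loss)) {
            stopf("non-finite loss at epoch %d", ep,
                  class = "strawdetect_training_failure")
          }
          ep_losses <- c(ep_losses, step$loss)
          acc <- if (is.null(acc)) step$grads else tree_map2(acc, step$grads, `+`)
        }
        acc <- tree_map(acc, function(g) g / length(idx))
        if (is.finite(config$grad_clip)) {
          sq <- 0
          acc_flat <- rapply(acc, function(g) { sq <<- sq + sum(g^2); NULL },
                             how = "unlist")
          gnorm <- sqrt(sq)
          if (gnorm > config$grad_clip) {
            acc <- tree_map(acc, function(g) g * (config$grad_clip / gnorm))
          }
        }
        iter <- iter + 1L
        lr_now <- if (iter <= boundary) config$lr else config$lr_after
        vel <- tree_map2(vel, acc, function(v, g) config$momentum * v - lr_now * g)
        params <- tree_map2(params, vel, `+`)
        attr(params, "strides") <- spec$backbone_strides
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(ep_losses),
                                       lr = lr_now))
    }
    params
  })
  attr(params, "strides") <- NULL
  net$params <- params
  net$spec <- spec
  net$trained <- TRUE
  structure(list(network = net, config = config, loss_trace = trace),
            class = "strawberry_detector")
}

#' @export
print.strawberry_detector <- function(x, ...) {
  n_ep <- nrow(x$loss_trace)
  cat(sprintf("<strawberry_detector: %d epoch(s), final loss %.4f>\n",
              n_ep, x$loss_trace$loss[n_ep]))
  print(x$network)
  invisible(x)
}

#' @export
plot.strawberry_detector <- function(x, ...) {
  graphics::plot(x$loss_trace$epoch, x$loss_trace$loss, type = "l",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}

#' @export
predict.strawberry_detector <- function(object, image, score_threshold = 0.5,
                                        ...) {
  detect(object, image, score_threshold = score_threshold)
}

#' Run detection on an image
#'
#' Forward pass in evaluation mode (dropout removed, outputs rescaled by
#' the retention probability): dense objectness, box decoding at proposal
#' cells, region-head scoring, score thresholding and non-maximum
#' suppression at IOU 0.5. Inference is deterministic.
#'
#' @param model a trained `strawberry_detector` (or a `strawberry_network`
#'   handle).
#' @param image H x W x 3 array, or an `annotated_image` (its pixels are
#'   used).
#' @param score_threshold minimum final score (default 0.5).
#' @param proposal_threshold minimum objectness for a cell to be decoded.
#' @param max_proposals cap on decoded proposals.
#' @return a [detection_result()].
#' @export
detect <- function(model, image, score_threshold = 0.5,
                   proposal_threshold = 0.3, max_proposals = 100L) {
  net <- as_network(model)
  if (inherits(image, "annotated_image")) image <- image$pixels
  assert_image(image)
  spec <- net$spec
  params <- net$params
  attr(params, "strides") <- spec$backbone_strides
  s <- prod(spec$backbone_strides)
  bf <- backbone_forward(params, image)
  rf <- rpn_forward(params, bf$out)
  p_obj <- sigmoid(rf$obj)
  cand <- which(p_obj >= proposal_threshold)
  if (length(cand) == 0L) {
    return(detection_result(matrix(numeric(0), ncol = 4), numeric(0)))
  }
  cand <- cand[order(p_obj[cand], decreasing = TRUE)]
  cand <- cand[seq_len(min(max_proposals, length(cand)))]
  cells <- arrayInd(cand, dim(p_obj))
  deltas <- matrix(0, nrow(cells), 4)
  for (r in seq_len(nrow(cells))) {
    deltas[r, ] <- rf$box[cells[r, 1], cells[r, 2], (cells[r, 3] - 1L) * 4L + 1:4]
  }
  rois <- decode_boxes(cells, deltas, spec, s, dim(image)[2], dim(image)[1])
  valid <- rois[, 1] < rois[, 3] & rois[, 2] < rois[, 4]
  rois <- rois[valid, , drop = FALSE]
  obj_s <- p_obj[cand][valid]
  if (nrow(rois) == 0L) {
    return(detection_result(matrix(numeric(0), ncol = 4), numeric(0)))
  }
  head_s <- vapply(seq_len(nrow(rois)), function(r) {
    pooled <- pool_roi(bf$out, rois[r, ], s, spec$roi_pool_size)
    head_forward(params, pooled, spec, train = FALSE)$score
  }, numeric(1))
  # confidence is the dice-calibrated objectness; the region head acts as a
  # classification veto on proposals it confidently rejects (its absolute
  # calibration is unreliable after short from-scratch schedules)
  score <- obj_s
  keep <- score >= score_threshold & head_s >= 0.05
  rois <- rois[keep, , drop = FALSE]
  score <- score[keep]
  if (nrow(rois) == 0L) {
    return(detection_result(matrix(numeric(0), ncol = 4), numeric(0)))
  }
  ord <- order(score, decreasing = TRUE)
  rois <- rois[ord, , drop = FALSE]
  score <- score[ord]
  keep_nms <- nms_keep(rois, 0.5)
  detection_result(rois[keep_nms, , drop = FALSE], score[keep_nms])
}

#' Oracle detector
#'
#' Returns the scene's ground-truth boxes perturbed by seeded uniform
#' jitter, with a fraction dropped — a deterministic stand-in for a trained
#' detector that lets post-processing, grading and evaluation be exercised
#' independently of training.
#'
#' @param scene an `annotated_image`.
#' @param jitter maximum absolute uniform perturbation (pixels) applied to
#'   each box coordinate.
#' @param drop_rate fraction of boxes dropped at random.
#' @param seed RNG seed.
#' @return a [detection_result()]; with `jitter = 0, drop_rate = 0` it is
#'   exactly the ground truth with scores 1.
#' @export
oracle_detector <- function(scene, jitter = 0, drop_rate = 0, seed = 1L) {
  gt <- box_matrix(scene$boxes)
  w <- dim(scene$pixels)[2]; h <- dim(scene$pixels)[1]
  with_seed(seed, {
    n <- nrow(gt)
    keep <- if (drop_rate <= 0) rep(TRUE, n) else stats::runif(n) >= drop_rate
    m <- gt[keep, , drop = FALSE]
    if (jitter > 0 && nrow(m) > 0) {
      m <- m + matrix(stats::runif(4 * nrow(m), -jitter, jitter), ncol = 4)
      m[, 1] <- pmin(pmax(m[, 1], 0), w - 1)
      m[, 2] <- pmin(pmax(m[, 2], 0), h - 1)
      m[, 3] <- pmin(pmax(m[, 3], m[, 1] + 1), w)
      m[, 4] <- pmin(pmax(m[, 4], m[, 2] + 1), h)
      scores <- stats::runif(nrow(m), 0.8, 1)
    } else {
      scores <- rep(1, nrow(m))
    }
    detection_result(m, scores)
  })
}
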