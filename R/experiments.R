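#' Evaluate detections against ground truth
#'
#' Aggregates greedy matching over paired prediction/truth lists into
#' pooled confusion counts, accuracy, F-measure, and the mean IOU of
#' matched pairs.
#'
#' @param preds list of [detection_result()]s (or box matrices).
#' @param truths list of ground-truth box matrices, same length.
#' @param spec a [match_spec()].
#' @param image_size optional `c(width, height)` enabling the TN grid
#'   protocol.
#' @return list with `counts` ([confusion_counts()]), `accuracy`,
#'   `f_measure`, `precision`, `recall`, `mean_iou`.
#' @export
evaluate_detections <- function(preds, truths, spec = match_spec(),
                                image_size = NULL) {
  if (length(preds) != length(truths)) {
    stopf("preds and truths must have equal length",
          class = "strawdetect_invalid_argument")
  }
  tot <- confusion_counts()
  ious <- numeric(0)
  for (i in seq_along(preds)) {
    pm <- if (inherits(preds[[i]], "detection_result")) preds[[i]]$boxes
          else box_matrix(preds[[i]])
    tm <- box_matrix(truths[[i]])
    gm <- greedy_match(pm, tm, spec$iou_threshold)
    ious <- c(ious, gm$matched_iou)
    tn <- if (is.null(image_size)) 0L else {
      count_background_cells(rbind(pm, tm), image_size, spec$tn_cell_size)
    }
    tot <- confusion_counts(tp = tot$tp + gm$tp, tn = tot$tn + tn,
                            fp = tot$fp + (nrow(pm) - gm$tp),
                            fn = tot$fn + (nrow(tm) - gm$tp))
  }
  list(counts = tot,
       accuracy = if (tot$tp + tot$tn + tot$fp + tot$fn > 0) accuracy(tot) else NA_real_,
       f_measure = f_measure(tot),
       precision = precision(tot),
       recall = recall(tot),
       mean_iou = if (length(ious)) mean(ious) else 0)
}

greedy_match <- function(pm, tm, thr) {
  used <- rep(FALSE, nrow(tm))
  tp <- 0L
  matched_iou <- numeric(0)
  for (i in seq_len(nrow(pm))) {
    best <- 0; best_j <- 0L
    for (j in seq_len(nrow(tm))) {
      if (used[j]) next
      o <- iou(pm[i, ], tm[j, ])
      if (o > best) { best <- o; best_j <- j }
    }
    if (best_j > 0L && best >= thr) {
      used[best_j] <- TRUE
      tp <- tp + 1L
      matched_iou <- c(matched_iou, best)
    }
  }
  list(tp = tp, matched_iou = matched_iou)
}

#' Robustness experiment harness
#'
#' Reruns the tiny detection pipeline across either training-set sizes
#' (`"dataset_size"`: retrain at each level) or illumination clusters
#' (`"light_intensity"`: train once per repeat at the nominal 4000 Lx,
#' then test the same model on matched scenes re-rendered at each lux
#' level). Each level is repeated `n_repeats` times with derived seeds and
#' the per-repeat accuracy, mean IOU and F-measure are tabulated.
#'
#' @param kind `"dataset_size"` or `"light_intensity"`.
#' @param levels numeric vector: training-set sizes, or lux levels from
#'   `c(1000, 2000, 4000, 5000, 6000)`.
#' @param base list of overrides: `scene` ([tiny_scene_config()]),
#'   `network` ([tiny_network_spec()]), `training`
#'   ([tiny_training_config()]), `match` ([match_spec()]), `n_train`,
#'   `n_test`.
#' @param seed master seed.
#' @param n_repeats seeded repeats per level (default 5).
#' @return data frame of per-level aggregates (`level, mean_accuracy,
#'   mean_iou, mean_f, sd_accuracy`), with the per-repeat table in
#'   attribute `"detail"`.
#' @export
run_robustness_experiment <- function(kind = c("dataset_size", "light_intensity"),
                                      levels, base = list(), seed = 1L,
                                      n_repeats = 5L) {
  kind <- match.arg(kind)
  scene <- base$scene %||% tiny_scene_config()
  netspec <- base$network %||% tiny_network_spec()
  training <- base$training %||% tiny_training_config(epochs = 6L)
  mspec <- base$match %||% match_spec()
  n_train <- base$n_train %||% 16L
  n_test <- base$n_test %||% 8L
  img_size <- c(scene$image_width, scene$image_height)

  detail <- data.frame(level = numeric(0), repeat_id = integer(0),
                       accuracy = numeric(0), iou = numeric(0),
                       f_measure = numeric(0))
  eval_model <- function(fit, test_scenes) {
    preds <- lapply(test_scenes, function(sc) predict(fit, sc))
    truths <- lapply(test_scenes, function(sc) sc$boxes)
    evaluate_detections(preds, truths, mspec, image_size = img_size)
  }
  if (kind == "dataset_size") {
    for (lv in levels) {
      for (rep_i in seq_len(n_repeats)) {
        s <- derive_seed(seed, lv * 100 + rep_i)
        train_scenes <- generate_dataset(scene, lv, seed = s)
        test_scenes <- generate_dataset(scene, n_test, seed = derive_seed(s, 999))
        cfg <- training; cfg$seed <- s
        fit <- train(build_network(netspec, seed = s), train_scenes, cfg)
        ev <- eval_model(fit, test_scenes)
        detail <- rbind(detail, data.frame(level = lv, repeat_id = rep_i,
                                           accuracy = ev$accuracy,
                                           iou = ev$mean_iou,
                                           f_measure = ev$f_measure))
      }
    }
  } else {
    lux_clusters <- c(1000, 2000, 4000, 5000, 6000)
    for (rep_i in seq_len(n_repeats)) {
      s <- derive_seed(seed, rep_i)
      # the training pool spans all five illumination clusters, as a field
      # training set captured under changing light would
      train_scenes <- vector("list", n_train)
      for (i in seq_len(n_train)) {
        sc_i <- scene
        sc_i$illumination_lux <- lux_clusters[((i - 1L) %% 5L) + 1L]
        sc_i$seed <- derive_seed(s, i)
        train_scenes[[i]] <- generate_scene(sc_i)
      }
      cfg <- training; cfg$seed <- s
      fit <- train(build_network(netspec, seed = s), train_scenes, cfg)
      for (lv in levels) {
        sc_lv <- scene
        sc_lv$illumination_lux <- lv
        # matched seed: identical geometry at every lux level
        test_scenes <- generate_dataset(sc_lv, n_test,
                                        seed = derive_seed(s, 999))
        ev <- eval_model(fit, test_scenes)
        detail <- rbind(detail, data.frame(level = lv, repeat_id = rep_i,
                                           accuracy = ev$accuracy,
                                           iou = ev$mean_iou,
                                           f_measure = ev$f_measure))
      }
    }
  }
  agg <- do.call(rbind, lapply(split(detail, detail$level), function(d) {
    data.frame(level = d$level[1],
               mean_accuracy = mean(d$accuracy),
               mean_iou = mean(d$iou),
               mean_f = mean(d$f_measure),
               sd_accuracy = stats::sd(d$accuracy))
  }))
  agg <- agg[match(levels, agg$level), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "detail") <- detail
  agg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
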