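# End-to-end pipeline commands. Each cmd_* function is the programmatic
# form of one CLI subcommand (see inst/cli/strawdetect); all of them log a
# one-line summary to stderr and are reproducible from (config, seed).

log_line <- function(fmt, ..., quiet = FALSE) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` scenes as PNG + annotation XML plus a manifest.
#'
#' @param config a [scene_config()].
#' @param n number of scenes.
#' @param out output directory.
#' @param seed master seed.
#' @param quiet suppress the log line.
#' @return manifest paths, invisibly.
#' @export
cmd_generate <- function(config, n, out, seed = config$seed, quiet = FALSE) {
  scenes <- generate_dataset(config, n, seed = seed, dir = out)
  log_line("generated %d scene(s) in %s (seed %d)", n, out, seed,
           quiet = quiet)
  invisible(attr(scenes, "manifest"))
}

read_dataset_dir <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.txt"))
  lapply(manifest, function(p) {
    px <- png::readPNG(file.path(dir, p))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
    px <- px[, , 1:3, drop = FALSE]
    rec <- read_annotation(file.path(dir, sub("\\.png$", ".xml", p)))
    boxes <- box_matrix(lapply(rec$objects, function(o) o$box))
    structure(list(pixels = px, boxes = boxes,
                   labels = vapply(rec$objects, function(o) o$label, character(1)),
                   meta = list(path = p)),
              class = "annotated_image")
  })
}

#' Preprocess a dataset: denoise, augment, split
#'
#' Median-denoises every image, expands it with the photometric recipe,
#' and writes train/test manifests. By default the train/test split is
#' made at the original-image level before augmentation, so augmented
#' copies of one scene never straddle the split; `split_after_augment =
#' TRUE` instead splits the expanded pool, which reproduces the published
#' 10x-then-80/20 counts at the cost of leakage.
#'
#' @param in_dir dataset directory (from [cmd_generate()]).
#' @param out output directory.
#' @param recipe an [augmentation_recipe()].
#' @param split a [split_spec()].
#' @param split_after_augment split the augmented pool instead of the
#'   originals.
#' @param denoise_window median window (default 3).
#' @param quiet suppress the log line.
#' @return list with `train` and `test` manifests, invisibly.
#' @export
cmd_preprocess <- function(in_dir, out, recipe = augmentation_recipe(),
                           split = split_spec(), split_after_augment = FALSE,
                           denoise_window = 3L, quiet = FALSE) {
  scenes <- read_dataset_dir(in_dir)
  if (length(scenes) == 0L) {
    stopf("empty manifest in %s", in_dir, class = "strawdetect_invalid_argument")
  }
  for (i in seq_along(scenes)) {
    scenes[[i]]$pixels <- median_denoise(scenes[[i]]$pixels, denoise_window)
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_item <- function(item, stem) {
    png::writePNG(quantize8(item$pixels), file.path(out, paste0(stem, ".png")))
    d <- dim(item$pixels)
    rec <- annotation_record(paste0(stem, ".png"), c(d[2], d[1]),
                             item$boxes, item$labels)
    write_annotation(rec, file.path(out, paste0(stem, ".xml")))
    paste0(stem, ".png")
  }
  expand_and_write <- function(items, prefix) {
    aug <- augment_dataset(items, recipe, seed = split$seed)
    vapply(seq_along(aug), function(i) {
      write_item(aug[[i]], sprintf("%s_%05d", prefix, i))
    }, character(1))
  }
  if (split_after_augment) {
    aug <- augment_dataset(scenes, recipe, seed = split$seed)
    paths <- vapply(seq_along(aug), function(i) {
      write_item(aug[[i]], sprintf("aug_%05d", i))
    }, character(1))
    parts <- split_dataset(paths, split)
    train_paths <- unlist(parts$train); test_paths <- unlist(parts$test)
  } else {
    parts <- split_dataset(scenes, split)
    train_paths <- expand_and_write(parts$train, "train")
    test_paths <- expand_and_write(parts$test, "test")
  }
  write_manifest(train_paths, file.path(out, "train_manifest.txt"))
  write_manifest(test_paths, file.path(out, "test_manifest.txt"))
  log_line("preprocessed %d -> %d images (%d train / %d test)",
           length(scenes), length(train_paths) + length(test_paths),
           length(train_paths), length(test_paths), quiet = quiet)
  invisible(list(train = train_paths, test = test_paths))
}

#' Train a detector from a dataset directory
#'
#' @param in_dir dataset directory with a manifest (train_manifest.txt is
#'   preferred when present).
#' @param out_model path for the serialized model (RDS) — a sidecar JSON
#'   describing the architecture is written next to it.
#' @param network a [network_spec()].
#' @param config a [training_config()].
#' @param quiet suppress the log line.
#' @return the fitted `strawberry_detector`, invisibly.
#' @export
cmd_train <- function(in_dir, out_model, network = tiny_network_spec(),
                      config = tiny_training_config(), quiet = FALSE) {
  manifest_file <- if (file.exists(file.path(in_dir, "train_manifest.txt"))) {
    file.path(in_dir, "train_manifest.txt")
  } else {
    file.path(in_dir, "manifest.txt")
  }
  paths <- read_manifest(manifest_file)
  scenes <- lapply(paths, function(p) {
    px <- png::readPNG(file.path(in_dir, p))[, , 1:3, drop = FALSE]
    rec <- read_annotation(file.path(in_dir, sub("\\.png$", ".xml", p)))
    list(pixels = px, boxes = box_matrix(lapply(rec$objects, function(o) o$box)))
  })
  fit <- train(build_network(network, seed = config$seed), scenes, config)
  saveRDS(fit, out_model)
  sidecar <- sub("\\.rds$", ".json", out_model)
  if (identical(sidecar, out_model)) sidecar <- paste0(out_model, ".json")
  jsonlite::write_json(introspect_network(fit), sidecar, auto_unbox = TRUE)
  utils::write.csv(fit$loss_trace, sub("\\.rds$", "_loss.csv", out_model),
                   row.names = FALSE)
  log_line("trained on %d image(s), final loss %.4f", length(scenes),
           fit$loss_trace$loss[nrow(fit$loss_trace)], quiet = quiet)
  invisible(fit)
}

#' Detect fruit across a dataset directory
#'
#' Runs the trained detector (or, for pipeline testing, the ground-truth
#' oracle detector) over every manifest image and writes one CSV of scored
#' boxes. `postprocess = TRUE` applies [refine_detections()] to every
#' scene.
#'
#' @param in_dir dataset directory.
#' @param out_csv output CSV (`image, xmin, ymin, xmax, ymax, score,
#'   recovered`).
#' @param model a `strawberry_detector`, a path to one saved by
#'   [cmd_train()], or `"oracle"`.
#' @param postprocess apply curvature/watershed refinement.
#' @param score_threshold forwarded to [detect()].
#' @param oracle_jitter,oracle_drop,seed oracle-detector parameters.
#' @param quiet suppress the log line.
#' @return the per-image list of [detection_result()]s, invisibly.
#' @export
cmd_detect <- function(in_dir, out_csv, model = "oracle", postprocess = FALSE,
                       score_threshold = 0.5, oracle_jitter = 0,
                       oracle_drop = 0, seed = 1L, quiet = FALSE) {
  scenes <- read_dataset_dir(in_dir)
  paths <- vapply(scenes, function(s) s$meta$path, character(1))
  if (is.character(model) && !identical(model, "oracle")) {
    model <- readRDS(model)
  }
  results <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    det <- if (identical(model, "oracle")) {
      oracle_detector(scenes[[i]], jitter = oracle_jitter,
                      drop_rate = oracle_drop, seed = derive_seed(seed, i))
    } else {
      detect(model, scenes[[i]], score_threshold = score_threshold)
    }
    if (postprocess) det <- refine_detections(det, scenes[[i]])
    results[[i]] <- det
  }
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (nrow(r$boxes) == 0L) return(NULL)
    data.frame(image = paths[i], xmin = r$boxes[, 1], ymin = r$boxes[, 2],
               xmax = r$boxes[, 3], ymax = r$boxes[, 4], score = r$scores,
               recovered = r$recovered)
  }))
  if (is.null(rows)) {
    rows <- data.frame(image = character(0), xmin = numeric(0),
                       ymin = numeric(0), xmax = numeric(0),
                       ymax = numeric(0), score = numeric(0),
                       recovered = logical(0))
  }
  utils::write.csv(rows, out_csv, row.names = FALSE)
  log_line("detected %d box(es) over %d image(s)%s", nrow(rows),
           length(scenes), if (postprocess) " (postprocessed)" else "",
           quiet = quiet)
  invisible(stats::setNames(results, paths))
}

#' Grade a detection CSV
#'
#' @param detections_csv CSV from [cmd_detect()].
#' @param out_csv per-box grading CSV.
#' @param out_json band-distribution JSON.
#' @param quiet suppress the log line.
#' @return the [grade_detections()] report, invisibly.
#' @export
cmd_grade <- function(detections_csv, out_csv = NULL, out_json = NULL,
                      quiet = FALSE) {
  rows <- utils::read.csv(detections_csv)
  report <- grade_detections(as.matrix(rows[, c("xmin", "ymin", "xmax", "ymax")]))
  write_grade_report(report, csv_path = out_csv, json_path = out_json)
  log_line("graded %d box(es)", nrow(report$per_box), quiet = quiet)
  invisible(report)
}

#' Evaluate a detection CSV against annotation XML
#'
#' @param detections_csv CSV from [cmd_detect()].
#' @param truth_dir dataset directory holding the annotation XML files.
#' @param out_json metrics JSON path (optional).
#' @param spec a [match_spec()].
#' @param quiet suppress the log line.
#' @return the [evaluate_detections()] metrics, invisibly.
#' @export
cmd_evaluate <- function(detections_csv, truth_dir, out_json = NULL,
                         spec = match_spec(), quiet = FALSE) {
  rows <- utils::read.csv(detections_csv)
  manifest <- read_manifest(file.path(truth_dir, "manifest.txt"))
  preds <- list(); truths <- list()
  img_size <- NULL
  for (p in manifest) {
    rec <- read_annotation(file.path(truth_dir, sub("\\.png$", ".xml", p)))
    img_size <- rec$image_size
    truths[[p]] <- box_matrix(lapply(rec$objects, function(o) o$box))
    sub_rows <- rows[rows$image == p, , drop = FALSE]
    preds[[p]] <- as.matrix(sub_rows[, c("xmin", "ymin", "xmax", "ymax")])
  }
  ev <- evaluate_detections(preds, truths, spec, image_size = img_size)
  if (!is.null(out_json)) {
    jsonlite::write_json(list(accuracy = ev$accuracy,
                              f_measure = ev$f_measure,
                              precision = ev$precision, recall = ev$recall,
                              mean_iou = ev$mean_iou,
                              tp = ev$counts$tp, tn = ev$counts$tn,
                              fp = ev$counts$fp, fn = ev$counts$fn,
                              iou_threshold = spec$iou_threshold,
                              tn_cell_size = spec$tn_cell_size),
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  log_line("accuracy %.3f, F %.3f, mean IOU %.3f", ev$accuracy, ev$f_measure,
           ev$mean_iou, quiet = quiet)
  invisible(ev)
}

#' Run a robustness experiment and write its table
#'
#' @param kind,levels,base,seed,n_repeats see [run_robustness_experiment()].
#' @param out_csv aggregate CSV path; the per-repeat table goes to
#'   `*_detail.csv`.
#' @param quiet suppress the log line.
#' @return the aggregate table, invisibly.
#' @export
cmd_experiment <- function(kind, levels, out_csv, base = list(), seed = 1L,
                           n_repeats = 5L, quiet = FALSE) {
  tab <- run_robustness_experiment(kind, levels, base = base, seed = seed,
                                   n_repeats = n_repeats)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  utils::write.csv(attr(tab, "detail"),
                   sub("\\.csv$", "_detail.csv", out_csv), row.names = FALSE)
  log_line("experiment %s over %d level(s) written to %s", kind,
           length(levels), out_csv, quiet = quiet)
  invisible(tab)
}
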