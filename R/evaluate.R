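# Evaluation harness: ROC/AUC, accuracy, F1, and end-to-end orchestration
# at phantom scale. Decision rule everywhere: score >= threshold implies
# abnormal; the positive class is "abnormal".

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed from average
#' ranks, which is exact including ties.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = abnormal/positive); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' ROC curve points
#'
#' One `(fpr, tpr)` point per distinct threshold (descending), anchored at
#' `(0, 0)` and `(1, 1)`; both coordinates are monotone non-decreasing.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC undefined: only one class present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied score
  data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
}

#' Accuracy and F1 at a threshold
#'
#' Predictions are `score >= threshold` (abnormal). F1 is defined as 0
#' when no sample is predicted positive while positives exist.
#'
#' @inheritParams roc_auc
#' @param threshold decision cut.
#' @return named numeric vector `c(accuracy, f1)`.
#' @export
accuracy_f1 <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = acc, f1 = f1)
}

#' Assemble an evaluation report from scores and labels
#'
#' @inheritParams accuracy_f1
#' @return an `eval_report`: list with `auc`, `accuracy`, `f1`,
#'   `threshold_used`, `n_normal`, `n_abnormal`, `roc_points`.
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  af <- accuracy_f1(scores, labels, threshold)
  structure(list(auc = roc_auc(scores, labels),
                 accuracy = unname(af["accuracy"]),
                 f1 = unname(af["f1"]),
                 threshold_used = threshold,
                 n_normal = sum(labels == 0),
                 n_abnormal = sum(labels == 1),
                 roc_points = roc_points(scores, labels)),
            class = "eval_report")
}

#' Configuration for the end-to-end phantom pipeline
#'
#' The `"tiny"` preset is the desk-scale recipe used throughout the tests:
#' 64x64 phantoms, 200 normal training images, a 20+20 validation split for
#' checkpointing/thresholding, a 50+50 test split, 20 epochs on one CPU.
#'
#' @param preset backbone preset, `"tiny"` or `"resnet18"`.
#' @param n_train normal training phantoms.
#' @param n_val_normal,n_val_abnormal validation split.
#' @param n_test_normal,n_test_abnormal test split.
#' @param image_size working resolution.
#' @param epochs training epochs.
#' @param mode augmentation mode (`"full"`, `"no_segmentation"`,
#'   `"no_blur"`).
#' @param seed master seed; every stage derives a named substream from it.
#' @param n_example_augmentations first-epoch augmented images written out
#'   as artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "tiny", n_train = 200L,
                            n_val_normal = 20L, n_val_abnormal = 20L,
                            n_test_normal = 50L, n_test_abnormal = 50L,
                            image_size = NULL, epochs = NULL,
                            mode = "full", seed = 1L,
                            n_example_augmentations = 8L) {
  mc <- model_config(preset, image_size = image_size, epochs = epochs,
                     seed = mix_seed(seed, "model"))
  structure(list(preset = preset, n_train = as.integer(n_train),
                 n_val_normal = as.integer(n_val_normal),
                 n_val_abnormal = as.integer(n_val_abnormal),
                 n_test_normal = as.integer(n_test_normal),
                 n_test_abnormal = as.integer(n_test_abnormal),
                 image_size = mc$image_size, epochs = mc$epochs,
                 mode = mode, seed = as.integer(seed),
                 n_example_augmentations = as.integer(n_example_augmentations),
                 model = mc),
            class = "pipeline_config")
}

#' Run the full pipeline: synthesize, segment, train, score, evaluate
#'
#' Stages: (1) generate phantom train/val/test splits; (2) segment the
#' training lungs; (3) train the pretext classifier with checkpointing by
#' validation AUC; (4) embed, KDE-score; (5) pick the best-F1 threshold on
#' the validation scores; (6) report AUC/accuracy/F1 on the test scores at
#' that threshold. All randomness derives from `config$seed` via named
#' substreams, and every stage is logged (stage, seconds, counts). When
#' `out_dir` is given, artifacts are written: `manifest.csv`, per-image
#' `scores.csv`, `report.json`, a `log.csv`, and the first-epoch augmented
#' examples as 8-bit grayscale images.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @param verbose print stage progress.
#' @return list with `report` (an `eval_report`), `scores` (data.frame),
#'   `threshold` (validation decision), `model`, `stage_log`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_log <- data.frame(stage = character(0), seconds = numeric(0),
                          n_in = integer(0), n_out = integer(0))
  tick <- function(stage, n_in, n_out, t0) {
    stage_log <<- rbind(stage_log, data.frame(
      stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 3),
      n_in = n_in, n_out = n_out))
    if (verbose) message(sprintf("[%s] done (%d -> %d, %.1fs)", stage,
                                 n_in, n_out, as.numeric(Sys.time()) - t0))
  }
  S <- config$image_size
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  t0 <- as.numeric(Sys.time())
  train <- wrap_stage("synth",
    phantom_dataset(config$n_train, 0, S, mix_seed(config$seed, "data", 1)))
  val <- wrap_stage("synth",
    phantom_dataset(config$n_val_normal, config$n_val_abnormal, S,
                    mix_seed(config$seed, "data", 2)))
  test <- wrap_stage("synth",
    phantom_dataset(config$n_test_normal, config$n_test_abnormal, S,
                    mix_seed(config$seed, "data", 3)))
  tick("synth", 0, config$n_train + nrow(val$manifest) + nrow(test$manifest), t0)

  imgs <- lapply(train$samples, `[[`, "image")
  t0 <- as.numeric(Sys.time())
  sp <- seg_params(S)
  masks <- wrap_stage("segment",
    suppressWarnings(lapply(imgs, segment_lungs, params = sp)))
  tick("segment", length(imgs), sum(vapply(masks, sum, 0) > 0), t0)

  aug_par <- augment_params(S, mode = config$mode)
  t0 <- as.numeric(Sys.time())
  model <- wrap_stage("train", train_model(
    imgs, masks,
    lapply(val$samples, `[[`, "image"),
    as.integer(val$manifest$label == "abnormal"),
    config$model, aug_par, verbose = verbose))
  tick("train", length(imgs), nrow(model$log), t0)

  t0 <- as.numeric(Sys.time())
  bank <- extract_features(model, imgs)
  val_raw <- kde_score(extract_features(
    model, lapply(val$samples, `[[`, "image")), bank)
  val_norm <- normalize_scores(val_raw)
  thr <- select_threshold(val_norm,
                          as.integer(val$manifest$label == "abnormal"))
  test_raw <- kde_score(extract_features(
    model, lapply(test$samples, `[[`, "image")), bank)
  test_norm <- normalize_scores(test_raw)
  test_labels <- as.integer(test$manifest$label == "abnormal")
  report <- evaluate_scores(test_norm, test_labels, thr$threshold)
  tick("score", nrow(test$manifest), nrow(test$manifest), t0)

  scores <- data.frame(image_id = test$manifest$id,
                       label = test_labels,
                       raw_score = test_raw,
                       normalized_score = test_norm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- default_image_ext()
    write.csv(rbind(train$manifest, val$manifest, test$manifest),
              file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    write.csv(stage_log, file.path(out_dir, "log.csv"), row.names = FALSE)
    rep_json <- list(auc = report$auc, accuracy = report$accuracy,
                     f1 = report$f1, threshold_used = report$threshold_used,
                     n_normal = report$n_normal,
                     n_abnormal = report$n_abnormal,
                     best_epoch = model$best_epoch,
                     best_val_auc = model$best_val_auc,
                     seed = config$seed, mode = config$mode)
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    # first-epoch augmented examples, regenerated with the training seeds
    k <- 0
    for (i in seq_along(imgs)) {
      if (k >= config$n_example_augmentations) break
      if (sum(masks[[i]]) == 0) next
      a <- paste_augment(imgs[[i]], masks[[i]], aug_par,
                         rng_seed = mix_seed(config$model$seed, "aug", 1, i))
      k <- k + 1
      write_gray(a$image,
                 file.path(out_dir, sprintf("augmented_%03d.%s", i, ext)))
    }
  }

  list(report = report, scores = scores, threshold = thr, model = model,
       stage_log = stage_log, out_dir = out_dir)
}
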