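# One-class pretext classifier.
#
# A residual CNN backbone with a fully connected projection head is trained
# to distinguish original images (label 0) from paste-augmented ones
# (label 1):
#   L = (1/N) sum_i { CE(f(X_i), 0) + CE(f(Aug(X_i)), 1) }.
# SGD with momentum, weight decay, and a cycle cosine-annealing learning
# rate; per epoch the validation AUC (computed through the same KDE scoring
# path as final evaluation) decides which weights to keep.

#' Training configuration for the pretext classifier
#'
#' Two backbone presets ship: `"resnet18"`, the full-scale network
#' (17 convolutions in four residual stages of widths 64/128/256/512 plus a
#' 3-layer head; 512-d embedding), and `"tiny"`, a 4-stage-equivalent
#' desk-scale network (stem 8, residual stages 8/16/32 at 64x64 input;
#' 32-d embedding) used by the test suite. Optimizer defaults are per
#' preset: SGD with momentum 0.9, weight decay 3e-5, lr 0.03 and one cosine
#' annealing cycle in both; `resnet18` uses the reference batch 64 over 256
#' epochs, while `tiny` uses batch 32 so that 20 epochs over a few hundred
#' images still provide ~13 SGD steps per epoch (see the methods vignette
#' for the calibration).
#'
#' @param backbone `"tiny"` or `"resnet18"`.
#' @param image_size input side length; preset default if `NULL`.
#' @param epochs training epochs (256 for `resnet18`, 20 for `tiny`).
#' @param batch_size images per minibatch (each minibatch holds
#'   `batch_size / 2` original/augmented pairs).
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param head_layers fully connected layers in the projection head.
#' @param schedule only `"cycle_cosine"` is implemented.
#' @param cycles cosine restart cycles over the epoch budget (default 1:
#'   a single annealing cycle).
#' @param seed master seed for init, shuffling and augmentation.
#' @return an object of class `model_config`.
#' @export
model_config <- function(backbone = c("tiny", "resnet18"),
                         image_size = NULL, epochs = NULL, batch_size = NULL,
                         lr = NULL, momentum = 0.9, weight_decay = 3e-5,
                         head_layers = 3L, schedule = "cycle_cosine",
                         cycles = 1L, seed = 1L) {
  if (length(backbone) == 1 && !backbone %in% c("tiny", "resnet18"))
    stop("unknown backbone identifier: ", backbone)
  backbone <- match.arg(backbone)
  preset <- switch(backbone,
    tiny = list(image_size = 64L, stem = 8L, widths = c(8L, 16L, 32L),
                blocks = c(1L, 1L, 1L), epochs = 20L, lr = 0.03,
                batch_size = 32L),
    resnet18 = list(image_size = 256L, stem = 64L,
                    widths = c(64L, 128L, 256L, 512L),
                    blocks = c(2L, 2L, 2L, 2L), epochs = 256L, lr = 0.03,
                    batch_size = 64L))
  if (is.null(image_size)) image_size <- preset$image_size
  if (is.null(epochs)) epochs <- preset$epochs
  # Presets carry their own optimizer defaults; the desk-scale preset uses a
  # smaller batch so 200 training images still give ~13 SGD steps per epoch.
  if (is.null(lr)) lr <- preset$lr
  if (is.null(batch_size)) batch_size <- preset$batch_size
  D <- preset$widths[length(preset$widths)]
  head_dims <- integer(head_layers)
  d <- D
  for (l in seq_len(head_layers - 1)) {
    head_dims[l] <- max(4L, as.integer(d))
    d <- d / 2
  }
  head_dims[head_layers] <- 2L
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0, epochs >= 1,
            schedule == "cycle_cosine")
  if (image_size %% 2^length(preset$widths) != 0)
    stop("image_size must be divisible by 2^", length(preset$widths))
  structure(list(backbone = backbone,
                 image_size = as.integer(image_size),
                 stem_channels = preset$stem, widths = preset$widths,
                 blocks = preset$blocks, head_dims = head_dims,
                 embedding_dim = D,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 schedule = schedule, cycles = as.integer(cycles),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Shapes of every parameter in canonical order: per conv unit W (He fan-in),
# BatchNorm gamma (init 1) and beta (init 0); per head layer W and b.
layer_shapes <- function(config) {
  shapes <- list()
  add_conv <- function(nm, out, fan) {
    shapes[[length(shapes) + 1]] <<- list(name = paste0(nm, ".W"),
                                          dim = c(out, fan), fan = fan,
                                          kind = "weight")
    shapes[[length(shapes) + 1]] <<- list(name = paste0(nm, ".g"),
                                          dim = out, kind = "gamma")
    shapes[[length(shapes) + 1]] <<- list(name = paste0(nm, ".beta"),
                                          dim = out, kind = "beta")
  }
  add_fc <- function(nm, out, fan) {
    shapes[[length(shapes) + 1]] <<- list(name = paste0(nm, ".W"),
                                          dim = c(out, fan), fan = fan,
                                          kind = "weight")
    shapes[[length(shapes) + 1]] <<- list(name = paste0(nm, ".b"),
                                          dim = out, kind = "beta")
  }
  add_conv("stem", config$stem_channels, 9)
  cin <- config$stem_channels
  for (s in seq_along(config$widths)) {
    wth <- config$widths[s]
    if (cin != wth) { add_conv(sprintf("s%d.proj", s), wth, cin * 9); cin <- wth }
    for (b in seq_len(config$blocks[s])) {
      add_conv(sprintf("s%d.b%d.c1", s, b), wth, wth * 9)
      add_conv(sprintf("s%d.b%d.c2", s, b), wth, wth * 9)
    }
  }
  din <- config$embedding_dim
  for (l in seq_along(config$head_dims)) {
    add_fc(sprintf("head%d", l), config$head_dims[l], din)
    din <- config$head_dims[l]
  }
  shapes
}

#' Build a pretext model with seeded He-normal initialization
#'
#' @param config a [model_config()].
#' @return an object of class `pretext_model` holding the parameter list
#'   (canonical W/b order), the config, and (after training) input
#'   normalization statistics.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  shapes <- layer_shapes(config)
  params <- with_seed(mix_seed(config$seed, "init"), {
    lapply(shapes, function(s) {
      switch(s$kind,
             weight = matrix(rnorm(prod(s$dim), sd = sqrt(2 / s$fan)),
                             s$dim[1], s$dim[2]),
             gamma = rep(1, s$dim),
             beta = numeric(s$dim))
    })
  })
  names(params) <- vapply(shapes, `[[`, "", "name")
  structure(list(config = config, params = params, bn = bn_init(config),
                 norm = NULL, log = NULL),
            class = "pretext_model")
}

# Fresh BatchNorm running statistics: mean 0, variance 1 per conv channel.
bn_init <- function(config) {
  shapes <- layer_shapes(config)
  out <- list()
  for (s in shapes) {
    if (s$kind != "gamma") next
    out[[length(out) + 1]] <- numeric(s$dim)   # running mean
    out[[length(out) + 1]] <- rep(1, s$dim)    # running variance
  }
  out
}

images_to_cube <- function(images, S) {
  if (is.array(images) && length(dim(images)) == 3) return(images)
  if (is.matrix(images)) images <- list(images)
  arr <- array(0, c(S, S, length(images)))
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == c(S, S)))
      stop("image ", i, " size ", paste(dim(images[[i]]), collapse = "x"),
           " does not match the model's input size ", S, "x", S)
    arr[, , i] <- images[[i]]
  }
  arr
}

normalize_images <- function(arr, norm) {
  if (is.null(norm)) arr else (arr - norm$mean) / norm$sd
}

model_forward <- function(model, images) {
  S <- model$config$image_size
  arr <- normalize_images(images_to_cube(images, S), model$norm)
  .cnn_forward_cpp(unname(model$params), unclass(model$config), arr,
                   unname(model$bn))
}

#' Pretext-task loss (pairwise cross entropy)
#'
#' Batch mean over paired predictions of
#' `CE(pred_normal, 0) + CE(pred_aug, 1)`. Inputs may be logits or
#' probability pairs (rows summing to one); probabilities are clipped at
#' `1e-12` before the log.
#'
#' @param pred_normal,pred_aug numeric `n x 2` matrices (or length-2
#'   vectors) of logits or class probabilities for the original and
#'   augmented member of each pair.
#' @return non-negative scalar loss.
#' @export
pretext_loss <- function(pred_normal, pred_aug) {
  as_probs <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (any(!is.finite(x))) stop("non-finite predictions")
    if (all(x >= 0) && all(abs(rowSums(x) - 1) < 1e-8)) return(x)
    e <- exp(x - apply(x, 1, max))
    e / rowSums(e)
  }
  p0 <- as_probs(pred_normal)
  p1 <- as_probs(pred_aug)
  if (nrow(p0) != nrow(p1)) stop("pair counts differ")
  mean(-log(pmax(p0[, 1], 1e-12)) - log(pmax(p1[, 2], 1e-12)))
}

cosine_lr <- function(config, epoch) {
  cycle_len <- ceiling(config$epochs / config$cycles)
  pos <- ((epoch - 1) %% cycle_len) / cycle_len
  config$lr * 0.5 * (1 + cos(pi * pos))
}

#' Train the pretext classifier on normal images
#'
#' Each epoch rebuilds the augmented counterpart of every training image
#' with a fresh seed derived from `(seed, epoch, index)`, minimizes the
#' pairwise cross-entropy loss by SGD, scores the validation set through
#' KDE against the current training-embedding bank, and keeps the weights
#' with the best validation AUC. Images whose lung mask is empty are
#' logged and skipped (no augmented pair can be formed for them).
#'
#' @param images list of normal training images (matrices in `[0, 1]`).
#' @param masks list of binary lung masks aligned with `images`.
#' @param val_images list of validation images.
#' @param val_labels 0/1 vector (1 = abnormal); both classes required.
#' @param config a [model_config()].
#' @param aug_params an [augment_params()]; defaults to the config's
#'   working resolution.
#' @param verbose print per-epoch loss/AUC.
#' @return a trained `pretext_model` with elements `log` (per-epoch
#'   data.frame: epoch, lr, loss, val_auc), `best_epoch`, `best_val_auc`,
#'   `norm`, `final_params`.
#' @export
train_model <- function(images, masks, val_images, val_labels, config,
                        aug_params = augment_params(config$image_size),
                        verbose = FALSE) {
  if (length(images) == 0) stop("empty training set")
  if (length(unique(val_labels)) < 2)
    stop("validation set must contain both classes (AUC undefined)")
  stopifnot(length(masks) == length(images),
            length(val_images) == length(val_labels))
  S <- config$image_size
  model <- build_model(config)
  model$norm <- local({
    v <- unlist(lapply(images, as.vector))
    list(mean = mean(v), sd = max(stats::sd(v), 1e-8))
  })
  usable <- which(vapply(masks, sum, 0) > 0)
  n_skipped <- length(images) - length(usable)
  if (length(usable) == 0) stop("all lung masks are empty")

  Xorig <- normalize_images(images_to_cube(images[usable], S), model$norm)
  velocity <- lapply(model$params, function(p) p * 0)
  pairs_per_batch <- max(1L, config$batch_size %/% 2L)
  val_arr <- images_to_cube(val_images, S)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    val_auc = numeric(0))
  best <- list(auc = -Inf, params = model$params, bn = model$bn, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config, epoch)
    aug_list <- vector("list", length(usable))
    for (k in seq_along(usable)) {
      i <- usable[k]
      aug_list[[k]] <- tryCatch(
        paste_augment(images[[i]], masks[[i]], aug_params,
                      rng_seed = mix_seed(config$seed, "aug", epoch, i))$image,
        error = function(e) NULL)   # unplaceable shape: skip pair this epoch
    }
    placed <- which(!vapply(aug_list, is.null, TRUE))
    n_skipped <- n_skipped + (length(usable) - length(placed))
    Xaug <- normalize_images(images_to_cube(aug_list[placed], S), model$norm)
    Xor <- Xorig[, , placed, drop = FALSE]
    ord <- with_seed(mix_seed(config$seed, "shuffle", epoch),
                     sample.int(length(placed)))
    ep_loss <- 0; n_batches <- 0
    for (start in seq(1, length(ord), by = pairs_per_batch)) {
      idx <- ord[start:min(start + pairs_per_batch - 1, length(ord))]
      g <- .cnn_grad_cpp(unname(model$params), unclass(config),
                         Xor[, , idx, drop = FALSE],
                         Xaug[, , idx, drop = FALSE],
                         unname(model$bn))
      model$bn <- g$stats
      for (j in seq_along(model$params)) {
        velocity[[j]] <- config$momentum * velocity[[j]] + g$grads[[j]] +
          config$weight_decay * model$params[[j]]
        model$params[[j]] <- model$params[[j]] - lr * velocity[[j]]
      }
      ep_loss <- ep_loss + g$loss
      n_batches <- n_batches + 1
    }
    ep_loss <- ep_loss / n_batches

    bank <- .cnn_forward_cpp(unname(model$params), unclass(config), Xorig,
                             unname(model$bn))$emb
    vemb <- .cnn_forward_cpp(unname(model$params), unclass(config),
                             normalize_images(val_arr, model$norm),
                             unname(model$bn))$emb
    vauc <- roc_auc(kde_score(vemb, bank), val_labels)
    # ties go to the later epoch: with a small validation set the AUC is
    # quantized, and later weights have seen more augmentation draws
    if (vauc >= best$auc) best <- list(auc = vauc, params = model$params,
                                       bn = model$bn, epoch = epoch)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                                 val_auc = vauc))
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  loss %.4f  val AUC %.3f",
                      epoch, lr, ep_loss, vauc))
  }
  model$final_params <- model$params
  model$final_bn <- model$bn
  model$params <- best$params
  model$bn <- best$bn
  model$best_epoch <- best$epoch
  model$best_val_auc <- best$auc
  model$log <- log
  model$n_skipped_empty_mask <- n_skipped
  model
}

#' Extract embedding vectors from a model
#'
#' Deterministic inference: fixed normalization, no augmentation, and
#' per-image evaluation, so results are identical regardless of batching.
#'
#' @param model a `pretext_model`.
#' @param images list of images (or an `S x S x n` array).
#' @return numeric `n x D` matrix of embeddings (the backbone's
#'   global-average-pooled features).
#' @export
extract_features <- function(model, images) {
  model_forward(model, images)$emb
}

#' Classification logits for a batch of images
#' @inheritParams extract_features
#' @return numeric `n x 2` matrix of head logits.
#' @export
predict_logits <- function(model, images) {
  model_forward(model, images)$logits
}
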