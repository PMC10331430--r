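# Pretext classifier: construction, loss closed forms, gradients, training
# mechanics, and deterministic feature extraction.

micro_cfg <- function(seed = 5) model_config("tiny", image_size = 16L,
                                             epochs = 2L, seed = seed)

test_that("build_model is seeded and rejects unknown backbones", {
  a <- build_model(model_config("tiny", seed = 3))
  b <- build_model(model_config("tiny", seed = 3))
  expect_identical(a$params, b$params)
  c <- build_model(model_config("tiny", seed = 4))
  expect_false(identical(a$params, c$params))
  expect_error(model_config("nonexistent-backbone"), "unknown backbone")
})

test_that("forward pass meets the shape and latency contract", {
  m <- build_model(model_config("tiny", seed = 1))
  x <- matrix(runif(64 * 64), 64, 64)
  f <- lungpaste:::model_forward(m, list(x))
  expect_equal(dim(f$logits), c(1, 2))
  expect_equal(dim(f$emb), c(1, m$config$embedding_dim))
  tm <- system.time(for (k in 1:5) lungpaste:::model_forward(m, list(x)))
  expect_lt(tm[["elapsed"]] / 5, 0.05)          # < 50 ms per 64x64 image
  expect_error(lungpaste:::model_forward(m, list(matrix(0.5, 32, 32))),
               "does not match")
})

test_that("pretext loss has its closed forms and symmetry", {
  uni <- matrix(0.5, 4, 2)
  expect_equal(pretext_loss(uni, uni), 2 * log(2), tolerance = 1e-9)
  perfect0 <- cbind(rep(1 - 1e-12, 4), rep(1e-12, 4))
  perfect1 <- cbind(rep(1e-12, 4), rep(1 - 1e-12, 4))
  expect_lt(pretext_loss(perfect0, perfect1), 1e-6)
  # swapping which member is "normal" while swapping labels is symmetric
  a <- matrix(runif(8), 4, 2); a <- a / rowSums(a)
  b <- matrix(runif(8), 4, 2); b <- b / rowSums(b)
  expect_equal(pretext_loss(a, b), pretext_loss(b[, 2:1], a[, 2:1]))
  # logits are accepted and converted
  expect_equal(pretext_loss(matrix(0, 2, 2), matrix(0, 2, 2)), 2 * log(2),
               tolerance = 1e-7)
  expect_error(pretext_loss(matrix(NaN, 1, 2), matrix(0.5, 1, 2)),
               "non-finite")
})

test_that("analytic gradients match a directional finite difference", {
  cfg <- micro_cfg()
  m <- build_model(cfg)
  set.seed(1)
  Xo <- array(runif(16 * 16 * 3), c(16, 16, 3))
  Xa <- array(runif(16 * 16 * 3), c(16, 16, 3))
  g <- lungpaste:::.cnn_grad_cpp(unname(m$params), unclass(cfg), Xo, Xa,
                                 unname(m$bn))
  set.seed(2)
  dir <- lapply(m$params, function(p) {
    d <- array(rnorm(length(p)), dim = dim(p) %||% length(p))
    d / sqrt(sum(d^2))
  })
  eps <- 5e-4
  shift <- function(s) mapply(function(p, d) p + s * d, m$params, dir,
                              SIMPLIFY = FALSE)
  l1 <- lungpaste:::.cnn_grad_cpp(unname(shift(eps)), unclass(cfg), Xo, Xa,
                                  unname(m$bn))$loss
  l0 <- lungpaste:::.cnn_grad_cpp(unname(shift(-eps)), unclass(cfg), Xo, Xa,
                                  unname(m$bn))$loss
  num <- (l1 - l0) / (2 * eps)
  ana <- sum(mapply(function(gr, d) sum(gr * d), g$grads, dir))
  expect_equal(num, ana, tolerance = 0.05)
})

test_that("batch loss is invariant to sample order within a batch", {
  cfg <- micro_cfg()
  m <- build_model(cfg)
  set.seed(4)
  Xo <- array(runif(16 * 16 * 6), c(16, 16, 6))
  Xa <- array(runif(16 * 16 * 6), c(16, 16, 6))
  l1 <- lungpaste:::.cnn_grad_cpp(unname(m$params), unclass(cfg), Xo, Xa,
                                  unname(m$bn))$loss
  perm <- c(4, 2, 6, 1, 5, 3)
  l2 <- lungpaste:::.cnn_grad_cpp(unname(m$params), unclass(cfg),
                                  Xo[, , perm], Xa[, , perm],
                                  unname(m$bn))$loss
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("with augmentation disabled the loss plateaus at 2 ln 2", {
  # identical original/augmented pairs make the labels unlearnable; the
  # per-pair loss CE(p,0) + CE(p,1) = -log p0 - log p1 >= 2 ln 2
  cfg <- micro_cfg()
  m <- build_model(cfg)
  set.seed(9)
  X <- array(runif(16 * 16 * 8), c(16, 16, 8))
  v <- lapply(m$params, function(p) p * 0)
  for (step in 1:40) {
    g <- lungpaste:::.cnn_grad_cpp(unname(m$params), unclass(cfg), X, X,
                                   unname(m$bn))
    m$bn <- g$stats
    for (j in seq_along(m$params)) {
      v[[j]] <- 0.9 * v[[j]] + g$grads[[j]]
      m$params[[j]] <- m$params[[j]] - 0.01 * v[[j]]
    }
  }
  final <- lungpaste:::.cnn_grad_cpp(unname(m$params), unclass(cfg), X, X,
                                     unname(m$bn))$loss
  expect_gte(final, 2 * log(2) - 1e-6)
  expect_lt(final, 2 * log(2) + 0.2)
})

test_that("training runs, logs, checkpoints, and validates inputs", {
  ph <- tiny_phantoms(30)
  v <- phantom_dataset(6, 6, 64, seed = 61)
  vl <- as.integer(v$manifest$label == "abnormal")
  vimgs <- lapply(v$samples, `[[`, "image")
  cfg <- model_config("tiny", epochs = 3L, seed = 8)
  m <- train_model(ph$images, ph$masks, vimgs, vl, cfg)
  expect_equal(nrow(m$log), 3)
  expect_true(all(c("epoch", "lr", "loss", "val_auc") %in% names(m$log)))
  expect_true(m$best_epoch %in% 1:3)
  # checkpoint invariance: stored best weights reproduce the logged AUC
  bank <- extract_features(m, ph$images)
  vauc <- roc_auc(kde_score(extract_features(m, vimgs), bank), vl)
  expect_equal(vauc, m$best_val_auc, tolerance = 1e-12)
  expect_error(train_model(list(), list(), vimgs, vl, cfg), "empty")
  expect_error(train_model(ph$images, ph$masks, vimgs, rep(0, 12), cfg),
               "both classes")
})

test_that("feature extraction is deterministic and batch-size invariant", {
  m <- build_model(model_config("tiny", seed = 2))
  set.seed(5)
  imgs <- lapply(1:7, function(i) matrix(runif(64 * 64), 64, 64))
  e_all <- extract_features(m, imgs)
  expect_equal(dim(e_all), c(7, 32))
  e_one <- do.call(rbind, lapply(imgs, function(x)
    extract_features(m, list(x))))
  expect_equal(e_all, e_one, tolerance = 1e-5)
  expect_identical(extract_features(m, imgs[1]),
                   extract_features(m, imgs[1]))
})
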