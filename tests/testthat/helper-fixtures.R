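# Shared fixtures. The expensive end-to-end training runs used by the
# scaled-down acceptance criteria are computed once per test session and
# memoised here, so the recovery and ablation criteria share them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small bank of 64 px phantoms with computed lung masks.
tiny_phantoms <- function(n = 20, seed = 5) {
  memo(sprintf("phantoms_%d_%d", n, seed), {
    d <- phantom_dataset(n, 0, 64L, seed)
    imgs <- lapply(d$samples, `[[`, "image")
    masks <- suppressWarnings(lapply(imgs, segment_lungs))
    list(images = imgs, masks = masks,
         truths = lapply(d$samples, `[[`, "lung_truth"))
  })
}

# One full tiny-preset pipeline run per (seed, mode); cached.
acceptance_run <- function(seed, mode) {
  memo(sprintf("run_%d_%s", seed, mode), {
    run_pipeline(pipeline_config(seed = seed, mode = mode))
  })
}

# The no-training random-init baseline on the same data splits as
# acceptance_run(seed, "full"): identical scoring path, untrained weights.
baseline_auc <- function(seed) {
  memo(sprintf("base_%d", seed), {
    cfg <- pipeline_config(seed = seed)
    S <- cfg$image_size
    tr <- phantom_dataset(cfg$n_train, 0, S, mix_seed(cfg$seed, "data", 1))
    te <- phantom_dataset(cfg$n_test_normal, cfg$n_test_abnormal, S,
                          mix_seed(cfg$seed, "data", 3))
    imgs <- lapply(tr$samples, `[[`, "image")
    m0 <- build_model(cfg$model)
    v <- unlist(lapply(imgs, as.vector))
    m0$norm <- list(mean = mean(v), sd = stats::sd(v))
    roc_auc(kde_score(extract_features(m0, lapply(te$samples, `[[`, "image")),
                      extract_features(m0, imgs)),
            as.integer(te$manifest$label == "abnormal"))
  })
}
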