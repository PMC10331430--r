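# Phantom generator: rendering contracts, determinism, opacity injection.

test_that("rendering is deterministic and respects intensity contracts", {
  sp <- phantom_spec(128, seed = 3, rng_seed = 11)
  a <- generate_normal_phantom(sp)
  b <- generate_normal_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$lung_truth, b$lung_truth)
  expect_true(all(a$image >= 0 & a$image <= 1))

  stats <- sapply(1:20, function(i) {
    s <- generate_normal_phantom(phantom_spec(128, seed = i, rng_seed = i))
    c(lung = mean(s$image[s$lung_truth == 1]),
      surround = mean(s$image[s$lung_truth == 0]),
      frac = mean(s$lung_truth))
  })
  expect_true(all(stats["lung", ] <= 0.45))
  expect_true(all(stats["surround", ] >= 0.55))
  # mean lung-area fraction of the frame over 20 seeds
  expect_gte(mean(stats["frac", ]), 0.15)
  expect_lte(mean(stats["frac", ]), 0.45)
})

test_that("noise-free, rib-free lungs are strictly darker than the mediastinum", {
  sp <- phantom_spec(128, noise_sigma = 0, rib_count = 0, rng_seed = 1)
  s <- generate_normal_phantom(sp)
  band_center <- s$image[, 64]          # mediastinal band center column
  expect_true(max(s$image[s$lung_truth == 1]) < min(band_center))
})

test_that("lung_truth is exactly the analytic ellipse-union raster", {
  sp <- phantom_spec(96, seed = 7, rng_seed = 7)
  s <- generate_normal_phantom(sp)
  ref <- matrix(0, 96, 96)
  for (e in sp$lung_ellipse_params)
    ref <- pmax(ref, ellipse_mask(96, e$center, e$semi, e$rot))
  expect_identical(s$lung_truth, ref)
  expect_equal(dice(s$lung_truth, s$lung_truth), 1)
})

test_that("invalid geometry is rejected with a descriptive error", {
  expect_error(
    phantom_spec(64, lung_ellipse_params = list(
      list(center = c(32, 5), semi = c(20, 10), rot = 0),
      list(center = c(32, 45), semi = c(17, 8), rot = 0))),
    "outside the image bounds")
  expect_error(
    phantom_spec(64, lung_ellipse_params = list(
      list(center = c(32, 28), semi = c(17, 9), rot = 0),
      list(center = c(32, 45), semi = c(17, 8), rot = 0))),
    "mediastinal band")
})

test_that("inject_opacity brightens a lung-confined bounded region", {
  s <- generate_normal_phantom(phantom_spec(128, seed = 3, rng_seed = 11))
  ab <- inject_opacity(s, 7)
  expect_identical(ab$label, "abnormal")
  expect_gte(sum(ab$anomaly_truth), 1)
  # at least half the marked pixels lie inside the true lung
  expect_gte(sum(ab$anomaly_truth & s$lung_truth),
             0.5 * sum(ab$anomaly_truth))
  # additive bright blob: mean intensity inside the truth region increases
  expect_gt(mean(ab$image[ab$anomaly_truth == 1]),
            mean(s$image[ab$anomaly_truth == 1]))
  # bounded support: pixels outside a 3x neighborhood of the blob untouched
  changed <- which(ab$image != s$image, arr.ind = TRUE)
  tr <- which(ab$anomaly_truth == 1, arr.ind = TRUE)
  ctr <- colMeans(tr)
  half <- apply(abs(sweep(tr, 2, ctr)), 2, max)    # truth half-extent
  d <- abs(sweep(changed, 2, ctr))
  expect_true(all(d[, 1] <= 3 * half[1] + 2 & d[, 2] <= 3 * half[2] + 2))
  # determinism
  expect_identical(inject_opacity(s, 7)$image, ab$image)
})

test_that("degenerate and invalid opacity calls are rejected", {
  s <- generate_normal_phantom(phantom_spec(64, seed = 1, rng_seed = 1))
  expect_error(inject_opacity(s, 1, amplitude_range = c(0, 0)),
               "zero-amplitude")
  ab <- inject_opacity(s, 1)
  expect_error(inject_opacity(ab, 2), "normal")
  s$lung_truth[] <- 0
  expect_error(inject_opacity(s, 1), "empty")
})

test_that("mean lung intensity alone separates injected phantoms (difficulty bound)", {
  d <- phantom_dataset(50, 50, 64, seed = 42)
  naive <- vapply(d$samples, function(s) mean(s$image[s$lung_truth == 1]), 0)
  labels <- as.integer(d$manifest$label == "abnormal")
  expect_gte(roc_auc(naive, labels), 0.9)
})

test_that("phantom_dataset manifest is consistent with its samples", {
  d <- phantom_dataset(4, 3, 64, seed = 9)
  expect_equal(nrow(d$manifest), 7)
  expect_equal(d$manifest$label,
               vapply(d$samples, `[[`, "", "label"))
  expect_equal(sum(d$manifest$label == "abnormal"), 3)
  # abnormal samples have non-empty anomaly truth, normals have none
  for (i in seq_along(d$samples)) {
    n_anom <- sum(d$samples[[i]]$anomaly_truth)
    if (d$manifest$label[i] == "abnormal") expect_gt(n_anom, 0)
    else expect_equal(n_anom, 0)
  }
})
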