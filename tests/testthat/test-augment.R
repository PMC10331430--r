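# Anatomy-aware paste augmentation: patch sampling, pasted-patch
# rendering, blurred shapes, anatomical masking, and the convex blend.

test_that("cut_patch is deterministic and samples the configured ranges", {
  img <- matrix(0.5, 256, 256)
  p1 <- cut_patch(img, 42)
  p2 <- cut_patch(img, 42)
  expect_identical(p1, p2)
  pars <- augment_params(256)
  fr <- vapply(1:2000, function(k) {
    b <- cut_patch(img, k, pars)$crop_box
    b[3] * b[4] / (256 * 256)
  }, 0)
  # realized fractions stay in the configured band (up to integer rounding)
  expect_gte(min(fr), 0.02 * 0.95)
  expect_lte(max(fr), 0.15 * 1.05)
  # both ends of the range are attained within 1% of its width
  expect_lte(min(fr), 0.02 + 0.0013)
  expect_gte(max(fr), 0.15 - 0.0013)
  expect_error(cut_patch(matrix(0.5, 3, 3), 1), "too small")
})

test_that("render_pasted_patch translates the crop without resampling", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  spec <- structure(list(crop_box = c(2, 1, 3, 4), paste_offset = c(0, 0),
                         source_seed = 1L), class = "patch_spec")
  out <- render_pasted_patch(img, spec)
  expect_equal(out[3:5, 2:5], img[3:5, 2:5])
  out[3:5, 2:5] <- 0
  expect_true(all(out == 0))
  # conservation of mass under translation
  spec$paste_offset <- c(3, 2)
  out2 <- render_pasted_patch(img, spec)
  expect_equal(sum(out2), sum(img[3:5, 2:5]))
  # 4x4 toy with values 1..16 (row-major), crop top-left 2x2 -> bottom-right
  toy <- matrix(1:16 / 16, 4, 4, byrow = TRUE)
  sp <- structure(list(crop_box = c(0, 0, 2, 2), paste_offset = c(2, 2),
                       source_seed = 1L), class = "patch_spec")
  o <- render_pasted_patch(toy, sp)
  expect_equal(o[3:4, 3:4], toy[1:2, 1:2])
  expect_equal(sum(o != 0), 4)
  expect_setequal(o[o != 0] * 16, c(1, 2, 5, 6))
  # bounds checking
  sp$paste_offset <- c(3, 3)
  expect_error(render_pasted_patch(toy, sp), "out of image bounds")
})

test_that("render_blur_shape honors its constraints and the zero-blur case", {
  lung <- matrix(0, 64, 64); lung[20:44, 12:52] <- 1
  hard <- render_blur_shape(lung, c(18, 10, 20, 24), 5,
                            augment_params(64, blur_max = 0))
  expect_true(all(abs(hard$grid) < 1e-12 | abs(hard$grid - hard$v) < 1e-12))
  expect_gte(hard$v, 0.59); expect_lte(hard$v, 1)
  for (k in 1:200) {
    sh <- render_blur_shape(lung, c(18, 10, 20, 24), k, augment_params(64))
    expect_lte(max(sh$grid), sh$v + 1e-9)
    expect_gte(sum(sh$support * lung), 1)                 # constraint (a)
    expect_lt(prod(sh$bbox), 20 * 24)                     # constraint (b)
  }
  expect_error(render_blur_shape(matrix(0, 64, 64), c(0, 0, 8, 8), 1),
               "empty")
  # lung far from the paste box: no admissible placement
  far <- matrix(0, 64, 64); far[1:4, 1:4] <- 1
  expect_error(render_blur_shape(far, c(50, 50, 10, 10), 1,
                                 augment_params(64)),
               "no admissible shape placement")
})

test_that("Gaussian-blurred hard rectangle has sharp center and decayed far field", {
  grid <- matrix(0, 30, 30); grid[11:20, 11:20] <- 1
  bl <- gaussian_blur(grid, 2 / 3)   # blur radius 2 -> sigma 2/3
  expect_gte(bl[15, 15], 0.99)
  expect_lte(bl[15, 26], 0.01)       # 5 px outside the right edge
  expect_lte(max(bl), 1 + 1e-9)
})

test_that("interior opacity v is uniform on [0.59, 1]", {
  lung <- matrix(1, 32, 32)
  vs <- vapply(1:2000, function(k)
    render_blur_shape(lung, c(8, 8, 12, 12), k, augment_params(32))$v, 0)
  ks <- suppressWarnings(stats::ks.test(vs, "punif", 0.59, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("make_anatomical_mask implements the three modes", {
  lung <- matrix(0, 16, 16); lung[5:12, 5:12] <- 1
  sh <- render_blur_shape(lung, c(4, 4, 8, 8), 3, augment_params(16))
  full <- make_anatomical_mask(lung, sh, "full")
  expect_true(all(full[lung == 0] == 0))
  expect_true(all(full <= sh$grid + 1e-12))
  noseg <- make_anatomical_mask(lung, sh, "no_segmentation")
  expect_identical(noseg, sh$grid)
  noblur <- make_anatomical_mask(lung, sh, "no_blur")
  expect_identical(noblur, lung * sh$support)
  # blur entirely outside the lung -> zero mask
  out_grid <- matrix(0, 16, 16); out_grid[1:2, 1:2] <- 0.8
  expect_true(all(make_anatomical_mask(lung, out_grid, "full") == 0))
  expect_error(make_anatomical_mask(lung, matrix(0, 8, 8)), "differ")
})

test_that("blend_images is exactly the convex combination", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    A <- matrix(runif(n * n), n); B <- matrix(runif(n * n), n)
    M <- matrix(runif(n * n), n)
    out <- blend_images(A, B, M)
    expect_identical(blend_images(A, B, matrix(0, n, n)), A)
    expect_identical(blend_images(A, B, matrix(1, n, n)), B)
    expect_equal(out, A * (1 - M) + B * M)
    expect_true(all(out >= pmin(A, B) - 1e-12 & out <= pmax(A, B) + 1e-12))
  }
  expect_equal(blend_images(matrix(0.2), matrix(0.8), matrix(0.5))[1], 0.5)
  expect_error(blend_images(matrix(0.2), matrix(0.8), matrix(1.5)), "mask")
})

test_that("paste_augment confines changes to the lung mask and is reproducible", {
  ph <- tiny_phantoms(6)
  ok <- which(vapply(ph$masks, sum, 0) > 0)[1:4]
  for (i in ok) {
    a <- paste_augment(ph$images[[i]], ph$masks[[i]], augment_params(64), i)
    expect_equal(a$pretext_label, 1L)
    d <- a$image != ph$images[[i]]
    expect_true(all(ph$masks[[i]][d] == 1))     # anatomy confinement
    b <- paste_augment(ph$images[[i]], ph$masks[[i]], augment_params(64), i)
    expect_identical(a$image, b$image)          # determinism
    expect_true(all(c("patch", "shape", "mode") %in% names(a$provenance)))
  }
  expect_error(paste_augment(ph$images[[1]], matrix(0, 64, 64)), "empty")
})
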