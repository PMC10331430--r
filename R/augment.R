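# Anatomy-aware cut-paste augmentation.
#
# A rectangular patch is cut from the normal image and pasted elsewhere on
# a zero canvas (X_patch). An oval or rectangle is drawn at the pasted
# position, its edge softened by a Gaussian blur (X_blur, opacity in
# [0, v]). The anatomical mask is the element-wise product of the lung
# segmentation and the blurred shape (X_mask = X_seg * X_blur), and the
# pseudo-anomalous image is the per-pixel convex blend
#   X_anomaly = X_normal * (1 - X_mask) + X_patch * X_mask,
# so synthetic anomalies arise only inside the lung fields. Two ablation
# modes drop the anatomy gate or the edge blur.

#' Augmentation parameters
#'
#' Crop area fraction is uniform on `area_range`, aspect ratio (height /
#' width) log-uniform on `aspect_range` — the conventional cut-paste
#' sampler. The shape's interior opacity `v ~ U[0.59, 1]` and blur radius
#' `r ~ U[0, blur_max]` with `blur_max = 15` px at the 256 px working
#' resolution, scaled proportionally for other sizes; the Gaussian kernel
#' has `sigma = r / 3`, truncated at `3 sigma`.
#'
#' @param image_size working resolution the blur range is resolved at.
#' @param area_range crop area as a fraction of the image, default
#'   `c(0.02, 0.15)`.
#' @param aspect_range crop aspect-ratio range, default `c(1/3, 3)`.
#' @param value_range interior opacity range, default `c(0.59, 1)`.
#' @param blur_max maximum blur radius in pixels.
#' @param shape_frac shape bounding-box side as a fraction of the patch
#'   side, sampled uniformly, default `c(0.3, 0.9)` (keeps the bounding-box
#'   area strictly below the patch area).
#' @param max_attempts rejection-sampling budget for the placement
#'   constraints.
#' @param mode `"full"`, `"no_segmentation"`, or `"no_blur"`.
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(image_size = 256L,
                           area_range = c(0.02, 0.15),
                           aspect_range = c(1 / 3, 3),
                           value_range = c(0.59, 1),
                           blur_max = 15 * image_size / 256,
                           shape_frac = c(0.3, 0.9),
                           max_attempts = 100L,
                           mode = c("full", "no_segmentation", "no_blur")) {
  mode <- match.arg(mode)
  structure(list(image_size = as.integer(image_size),
                 area_range = area_range, aspect_range = aspect_range,
                 value_range = value_range, blur_max = blur_max,
                 shape_frac = shape_frac,
                 max_attempts = as.integer(max_attempts), mode = mode),
            class = "augment_params")
}

#' Sample a patch cut/paste specification
#'
#' Draws a crop box (area fraction and aspect ratio from the configured
#' ranges) and an independent paste position, both uniform over admissible
#' placements. Boxes are 0-based, half-open, row-major. Deterministic given
#' `rng_seed`.
#'
#' @param image numeric matrix at working resolution.
#' @param rng_seed integer seed.
#' @param params an [augment_params()].
#' @return a `patch_spec`: list with `crop_box = c(row, col, height, width)`,
#'   `paste_offset = c(drow, dcol)`, `source_seed`.
#' @export
cut_patch <- function(image, rng_seed, params = augment_params(nrow(image))) {
  H <- nrow(image); W <- ncol(image)
  min_area <- params$area_range[1] * H * W
  if (min_area < 1 || H < 2 || W < 2)
    stop("image too small for the minimum patch size")
  draw <- function() {
    for (attempt in seq_len(params$max_attempts)) {
      a <- runif(1, params$area_range[1], params$area_range[2]) * H * W
      asp <- exp(runif(1, log(params$aspect_range[1]),
                       log(params$aspect_range[2])))
      h <- max(1L, as.integer(round(sqrt(a * asp))))
      w <- max(1L, as.integer(round(a / h)))
      if (h > H || w > W) next
      r0 <- sample.int(H - h + 1, 1) - 1L
      c0 <- sample.int(W - w + 1, 1) - 1L
      r1 <- sample.int(H - h + 1, 1) - 1L
      c1 <- sample.int(W - w + 1, 1) - 1L
      return(structure(list(crop_box = c(r0, c0, h, w),
                            paste_offset = c(r1 - r0, c1 - c0),
                            source_seed = as.integer(rng_seed)),
                       class = "patch_spec"))
    }
    stop("no admissible crop box found within ", params$max_attempts,
         " attempts")
  }
  with_seed(rng_seed, draw())
}

#' Render the full-size pasted-patch image
#'
#' Zero everywhere except the pasted box, which carries the crop-box
#' content translated without resampling.
#'
#' @param image source image.
#' @param spec a `patch_spec`.
#' @return numeric matrix, same shape as `image`.
#' @export
render_pasted_patch <- function(image, spec) {
  H <- nrow(image); W <- ncol(image)
  b <- spec$crop_box
  r0 <- b[1]; c0 <- b[2]; h <- b[3]; w <- b[4]
  r1 <- r0 + spec$paste_offset[1]; c1 <- c0 + spec$paste_offset[2]
  if (r0 < 0 || c0 < 0 || r0 + h > H || c0 + w > W)
    stop("crop box out of image bounds")
  if (r1 < 0 || c1 < 0 || r1 + h > H || c1 + w > W)
    stop("pasted box out of image bounds")
  out <- matrix(0, H, W)
  out[(r1 + 1):(r1 + h), (c1 + 1):(c1 + w)] <-
    image[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
  out
}

#' Draw the blurred-shape opacity field at the pasted position
#'
#' An oval or rectangle (50/50) is centered inside the pasted box with
#' bounding-box sides a `shape_frac` fraction of the patch sides, filled
#' with the constant opacity `v ~ U[0.59, 1]`, and blurred with a Gaussian
#' of radius `r ~ U[0, blur_max]` (`sigma = r/3`). Placements are rejected
#' until (a) the unblurred shape overlaps the lung mask in at least one
#' pixel and (b) the shape bounding-box area is strictly smaller than the
#' patch area; after `max_attempts` failures an error names the violated
#' constraint.
#'
#' @param lung binary lung mask.
#' @param paste_box `c(row, col, height, width)` of the pasted patch
#'   (0-based, half-open).
#' @param rng_seed integer seed.
#' @param params an [augment_params()].
#' @return a `blur_shape`: list with `kind`, `center`, `bbox`, `v`, `r`,
#'   `grid` (blurred opacity field, full size), `support` (binary unblurred
#'   shape).
#' @export
render_blur_shape <- function(lung, paste_box, rng_seed,
                              params = augment_params(nrow(lung))) {
  check_mask(lung)
  if (sum(lung) == 0) stop("lung mask is empty")
  S <- nrow(lung); W <- ncol(lung)
  pr <- paste_box[1]; pc <- paste_box[2]; ph <- paste_box[3]; pw <- paste_box[4]
  draw <- function() {
    v <- runif(1, params$value_range[1], params$value_range[2])
    r <- runif(1, 0, params$blur_max)
    last_violation <- "placement"
    for (attempt in seq_len(params$max_attempts)) {
      kind <- if (runif(1) < 0.5) "oval" else "rectangle"
      hb <- max(2L, as.integer(round(runif(1, params$shape_frac[1],
                                           params$shape_frac[2]) * ph)))
      wb <- max(2L, as.integer(round(runif(1, params$shape_frac[1],
                                           params$shape_frac[2]) * pw)))
      if (hb * wb >= ph * pw) { last_violation <- "(b) shape not smaller than patch"; next }
      ctr <- c(pr + runif(1, 0, ph - 1), pc + runif(1, 0, pw - 1))
      support <- if (kind == "oval") {
        ellipse_mask(S, ctr, c(hb / 2, wb / 2))
      } else {
        rws <- abs(matrix(0:(S - 1), S, W) - ctr[1]) <= hb / 2
        cls <- abs(matrix(0:(W - 1), S, W, byrow = TRUE) - ctr[2]) <= wb / 2
        (rws & cls) * 1
      }
      if (sum(support) == 0) { last_violation <- "empty shape raster"; next }
      if (sum(support * lung) < 1) { last_violation <- "(a) no overlap with the lung region"; next }
      grid <- gaussian_blur(support * v, r / 3)
      return(structure(list(kind = kind, center = ctr, bbox = c(hb, wb),
                            v = v, r = r, grid = grid, support = support),
                       class = "blur_shape"))
    }
    stop("no admissible shape placement after ", params$max_attempts,
         " attempts; last violated constraint: ", last_violation)
  }
  with_seed(rng_seed, draw())
}

#' Combine lung segmentation and blurred shape into the anatomical mask
#'
#' `full`: element-wise product of the lung mask and the blurred opacity.
#' `no_segmentation`: the lung mask is replaced by all-ones (anatomy gate
#' off). `no_blur`: the blurred opacity is replaced by a hard all-ones
#' shape on its unblurred support (edge softening off).
#'
#' @param lung binary lung mask.
#' @param blur a `blur_shape` (or a plain opacity matrix for modes that do
#'   not need the unblurred support).
#' @param mode `"full"`, `"no_segmentation"`, or `"no_blur"`.
#' @return numeric matrix in `[0, 1]`.
#' @export
make_anatomical_mask <- function(lung, blur,
                                 mode = c("full", "no_segmentation", "no_blur")) {
  mode <- match.arg(mode)
  grid <- if (inherits(blur, "blur_shape")) blur$grid else blur
  if (!all(dim(lung) == dim(grid))) stop("lung mask and shape shapes differ")
  if (mode == "no_blur") {
    if (!inherits(blur, "blur_shape"))
      stop("mode 'no_blur' needs the unblurred shape support")
    grid <- blur$support
  }
  if (mode == "no_segmentation") grid else lung * grid
}

#' Convex blend of normal image and pasted patch
#'
#' Per-pixel `X_normal * (1 - X_mask) + X_patch * X_mask`. With a zero mask
#' the output is bit-identical to the normal image; with a unit mask it
#' equals the pasted-patch image.
#'
#' @param normal,patch numeric matrices of identical shape.
#' @param mask numeric matrix in `[0, 1]`, same shape.
#' @return blended matrix.
#' @export
blend_images <- function(normal, patch, mask) {
  if (!all(dim(normal) == dim(patch)) || !all(dim(normal) == dim(mask)))
    stop("blend inputs must share one shape")
  if (min(mask) < 0 || max(mask) > 1) stop("mask values must lie in [0, 1]")
  normal * (1 - mask) + patch * mask
}

#' Anatomy-aware paste augmentation (end to end)
#'
#' Cut -> paste -> blurred shape -> anatomical mask -> blend. Pixels where
#' the mask is zero are bit-identical to the input; in mode `"full"` every
#' changed pixel lies inside the lung mask. Deterministic given `rng_seed`.
#'
#' @param image normal radiograph (matrix in `[0, 1]`).
#' @param lung binary lung mask (`X_seg`).
#' @param params an [augment_params()].
#' @param rng_seed integer seed.
#' @return an `augmented_sample`: list with `image` (the pseudo-anomalous
#'   radiograph), `pretext_label = 1L`, and `provenance` (patch spec, shape
#'   minus its grids, seeds, mode).
#' @export
paste_augment <- function(image, lung, params = augment_params(nrow(image)),
                          rng_seed = 1L) {
  check_image(image)
  if (params$mode != "no_segmentation" && sum(lung) == 0)
    stop("lung mask is empty; skip augmentation for this image")
  shape_lung <- if (params$mode == "no_segmentation")
    matrix(1, nrow(image), ncol(image)) else lung
  # The lung-overlap constraint binds the paste position and the shape
  # jointly: a paste box far from the lung fields admits no valid shape, so
  # rejection sampling redraws both until the constraints are satisfiable.
  shape <- NULL
  for (outer in seq_len(20L)) {
    spec <- cut_patch(image, mix_seed(rng_seed, "cut", outer), params)
    paste_box <- c(spec$crop_box[1] + spec$paste_offset[1],
                   spec$crop_box[2] + spec$paste_offset[2],
                   spec$crop_box[3], spec$crop_box[4])
    shape <- tryCatch(
      render_blur_shape(shape_lung, paste_box,
                        mix_seed(rng_seed, "shape", outer), params),
      error = function(e) e)
    if (!inherits(shape, "error")) break
  }
  if (inherits(shape, "error"))
    stop("augmentation failed after 20 cut/paste redraws: ",
         conditionMessage(shape))
  patch <- render_pasted_patch(image, spec)
  mask <- make_anatomical_mask(lung, shape, params$mode)
  out <- blend_images(image, patch, mask)
  prov <- list(patch = spec,
               shape = shape[c("kind", "center", "bbox", "v", "r")],
               paste_box = paste_box, mode = params$mode,
               rng_seed = as.integer(rng_seed))
  structure(list(image = out, pretext_label = 1L, provenance = prov),
            class = "augmented_sample")
}
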