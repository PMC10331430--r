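# Synthetic chest-radiograph phantoms with ground-truth lung masks.
#
# The phantom emulates the structure the segmentation and augmentation
# stages assume: dark lung fields, a bright mediastinal band, rib arcs as
# nuisance structure, smooth vignetting, additive noise. Composition order
# is fixed: background gradient -> mediastinal band -> dark lung ellipses ->
# rib arcs -> vignette -> noise -> clip to [0, 1].

#' Specification of a synthetic radiograph phantom
#'
#' Geometry is expressed in pixels of the square working grid. When `seed`
#' is given, lung geometry is jittered around anatomically plausible
#' defaults (centers +/- 2% of frame, semi-axes +/- 8%, rotation +/- 3
#' degrees) so a population of phantoms shows realistic inter-subject
#' variation; the returned spec is still a complete, deterministic record of
#' the geometry.
#'
#' @param image_size side length in pixels (square image), default 256.
#' @param seed optional integer; jitters the lung geometry deterministically.
#' @param lung_ellipse_params list of two ellipses, each
#'   `list(center = c(row, col), semi = c(row_semi, col_semi), rot = radians)`.
#' @param mediastinum_width_frac width of the bright central band as a
#'   fraction of image width, in (0, 1).
#' @param rib_count rib arcs per side (nuisance structure), default 8.
#' @param vessel_count bright vascular streaks radiating from each hilum,
#'   default 12; the pulmonary texture every radiograph shows. Without it
#'   lung interiors are implausibly homogeneous (and a pasted lung patch
#'   would be invisible).
#' @param noise_sigma additive Gaussian noise sd in intensity units, in
#'   `[0, 0.2]`.
#' @param vignette_strength corner darkening in `[0, 1]`.
#' @param rng_seed seed consumed by the renderer (noise, rib jitter).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, seed = NULL,
                         lung_ellipse_params = NULL,
                         mediastinum_width_frac = 0.18,
                         rib_count = 8L,
                         vessel_count = 12L,
                         noise_sigma = 0.02,
                         vignette_strength = 0.15,
                         rng_seed = 1L) {
  S <- as.integer(image_size)
  stopifnot(S >= 16)
  if (is.null(lung_ellipse_params)) {
    jit <- function(n, amt) if (is.null(seed)) rep(0, n) else runif(n, -amt, amt)
    sc <- function(n, amt) if (is.null(seed)) rep(1, n) else runif(n, 1 - amt, 1 + amt)
    draw <- function() {
      j_c <- jit(4, 0.015); j_s <- sc(4, 0.08); j_r <- jit(2, 0.05)
      list(
        list(center = S * c(0.50 + j_c[1], 0.30 + j_c[2]),
             semi   = S * c(0.26, 0.13) * j_s[1:2],
             rot    = -0.10 + j_r[1]),
        list(center = S * c(0.50 + j_c[3], 0.70 + j_c[4]),
             semi   = S * c(0.26, 0.13) * j_s[3:4],
             rot    = 0.10 + j_r[2])
      )
    }
    lung_ellipse_params <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  spec <- structure(list(
    image_size = S,
    lung_ellipse_params = lung_ellipse_params,
    mediastinum_width_frac = mediastinum_width_frac,
    rib_count = as.integer(rib_count),
    vessel_count = as.integer(vessel_count),
    noise_sigma = noise_sigma,
    vignette_strength = vignette_strength,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  S <- spec$image_size
  stopifnot(spec$mediastinum_width_frac > 0, spec$mediastinum_width_frac < 1,
            spec$rib_count >= 0, spec$vessel_count >= 0,
            spec$noise_sigma >= 0, spec$noise_sigma <= 0.2,
            spec$vignette_strength >= 0, spec$vignette_strength <= 1)
  for (e in spec$lung_ellipse_params) {
    ext_r <- sqrt((e$semi[1] * cos(e$rot))^2 + (e$semi[2] * sin(e$rot))^2)
    ext_c <- sqrt((e$semi[1] * sin(e$rot))^2 + (e$semi[2] * cos(e$rot))^2)
    if (e$center[1] - ext_r < 1 || e$center[1] + ext_r > S - 2 ||
        e$center[2] - ext_c < 1 || e$center[2] + ext_c > S - 2)
      stop("invalid phantom geometry: lung ellipse extends outside the image ",
           "bounds (center ", paste(round(e$center, 1), collapse = ","),
           ", extent ", round(ext_r, 1), "x", round(ext_c, 1),
           " in a ", S, "px frame)")
    # mediastinal-band overlap <= 20% of the ellipse area
    m <- ellipse_mask(S, e$center, e$semi, e$rot)
    half_bw <- spec$mediastinum_width_frac * S / 2
    cols <- abs(col(m) - 1 - (S - 1) / 2) <= half_bw
    if (sum(m & cols) > 0.2 * sum(m))
      stop("invalid phantom geometry: lung ellipse overlaps the mediastinal ",
           "band by more than 20% of its area")
  }
  invisible(spec)
}

#' Rasterize an ellipse as a binary mask
#'
#' Analytic raster: pixel (r, c) (0-based) is foreground iff the rotated
#' quadratic form is `<= 1`.
#'
#' @param S image side; `center`, `semi` in pixels; `rot` in radians.
#' @return binary matrix `S x S`.
#' @export
ellipse_mask <- function(S, center, semi, rot = 0) {
  q <- ellipse_quadform(S, center, semi, rot)
  (q <= 1) * 1
}

ellipse_quadform <- function(S, center, semi, rot = 0) {
  r <- matrix(0:(S - 1), S, S) - center[1]
  c <- matrix(0:(S - 1), S, S, byrow = TRUE) - center[2]
  u <- cos(rot) * r + sin(rot) * c
  w <- -sin(rot) * r + cos(rot) * c
  (u / semi[1])^2 + (w / semi[2])^2
}

#' Render a normal phantom radiograph
#'
#' Deterministic given the spec (including `rng_seed`). The returned ground
#' truth `lung_truth` is exactly the union of the analytic ellipse rasters;
#' the rendered lung interior uses a slightly soft sigmoidal edge so the
#' boundary is not a 1-px step, as on a real radiograph.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_sample`: list with `image` (matrix in `[0,1]`),
#'   `lung_truth` (binary matrix), `label` (`"normal"`), `anomaly_truth`
#'   (all-zero matrix), and `spec`.
#' @export
generate_normal_phantom <- function(spec) {
  validate_phantom_spec(spec)
  S <- spec$image_size
  rowf <- matrix(0:(S - 1), S, S) / (S - 1)
  colf <- matrix(0:(S - 1), S, S, byrow = TRUE) / (S - 1)

  img <- 0.66 + 0.08 * (rowf - 0.5)                       # soft-tissue gradient
  half_bw <- spec$mediastinum_width_frac / 2
  img <- img + 0.20 * exp(-((colf - 0.5) / half_bw)^4)    # mediastinal band

  truth <- matrix(0, S, S)
  soft <- matrix(0, S, S)
  for (e in spec$lung_ellipse_params) {
    q <- ellipse_quadform(S, e$center, e$semi, e$rot)
    truth <- pmax(truth, (q <= 1) * 1)
    soft <- pmax(soft, 1 / (1 + exp((q - 1) / 0.06)))
  }
  img <- img - 0.38 * soft                                # dark lung fields

  out <- with_seed(spec$rng_seed, {
    im <- img
    if (spec$vessel_count > 0) {
      # pulmonary vasculature: bright streaks radiating from each hilum,
      # stamped as small Gaussian dots along line segments
      kw <- max(0.7, S / 160)                    # vessel half-width in px
      kspan <- (-as.integer(ceiling(3 * kw))):(as.integer(ceiling(3 * kw)))
      kern <- outer(exp(-kspan^2 / (2 * kw^2)), exp(-kspan^2 / (2 * kw^2)))
      vlayer <- matrix(0, S, S)   # max-composited so amplitudes never stack
      for (e in spec$lung_ellipse_params) {
        medial <- if (e$center[2] < S / 2) 1 else -1
        hil <- c(e$center[1], e$center[2] + medial * 0.55 * e$semi[2])
        for (vk in seq_len(spec$vessel_count)) {
          ang <- runif(1, -1.25, 1.25) +
            (if (medial > 0) pi else 0)          # fan away from the hilum
          len <- runif(1, 0.5, 1.05) * e$semi[1]
          amp <- runif(1, 0.03, 0.06)
          nstep <- max(4L, as.integer(len))
          ts <- seq(0, 1, length.out = nstep)
          rr0 <- hil[1] + sin(ang) * len * ts + cumsum(rnorm(nstep, 0, 0.4))
          cc0 <- hil[2] + cos(ang) * len * ts
          for (sidx in seq_len(nstep)) {
            r0 <- round(rr0[sidx]); c0 <- round(cc0[sidx])
            rs <- r0 + kspan; cs <- c0 + kspan
            rok <- rs >= 1 & rs <= S; cok <- cs >= 1 & cs <= S
            if (!any(rok) || !any(cok)) next
            taper <- 1 - 0.6 * ts[sidx]          # vessels thin distally
            vlayer[rs[rok], cs[cok]] <- pmax(
              vlayer[rs[rok], cs[cok]],
              amp * taper * kern[rok, cok, drop = FALSE] *
                soft[rs[rok], cs[cok], drop = FALSE])  # only over lung
          }
        }
      }
      im <- im + vlayer
      # low-amplitude parenchymal mottle confined to the lung fields
      fr <- matrix(0:(S - 1), S, S) / S
      fc <- matrix(0:(S - 1), S, S, byrow = TRUE) / S
      mot <- matrix(0, S, S)
      for (kk in 1:3) {
        f <- runif(2, 4, 11); ph <- runif(2, 0, 2 * pi)
        mot <- mot + cos(2 * pi * f[1] * fr + ph[1]) *
                     cos(2 * pi * f[2] * fc + ph[2])
      }
      im <- im + 0.018 * mot * soft
    }
    if (spec$rib_count > 0) {
      rr <- matrix(0:(S - 1), S, S)
      for (e in spec$lung_ellipse_params) {
        ext_c <- sqrt((e$semi[1] * sin(e$rot))^2 + (e$semi[2] * cos(e$rot))^2)
        incol <- abs(colf * (S - 1) - e$center[2]) <= ext_c + 0.02 * S
        rows0 <- seq(e$center[1] - e$semi[1] * 0.85,
                     e$center[1] + e$semi[1] * 0.85,
                     length.out = spec$rib_count) + runif(spec$rib_count, -2, 2)
        curv <- runif(1, 0.3, 0.6) / S
        dc2 <- (colf * (S - 1) - e$center[2])^2
        for (r0 in rows0) {
          arc <- r0 - curv * dc2                          # bow upward laterally
          im <- im + 0.08 * exp(-(rr - arc)^2 / (2 * 1.2^2)) * incol
        }
      }
    }
    d2 <- (rowf - 0.5)^2 + (colf - 0.5)^2
    im <- im * (1 - spec$vignette_strength * d2 / 0.5)    # vignette
    if (spec$noise_sigma > 0)
      im <- im + matrix(rnorm(S * S, sd = spec$noise_sigma), S, S)
    im
  })

  structure(list(
    image = clip01(out),
    lung_truth = truth,
    label = "normal",
    anomaly_truth = matrix(0, S, S),
    spec = spec
  ), class = "phantom_sample")
}

#' Inject a bright lung opacity into a normal phantom
#'
#' Adds an elliptical Gaussian-profile blob (peak amplitude drawn from
#' `amplitude_range`, clipped into `[0,1]`) centered at a random pixel of
#' the ground-truth lung mask. `anomaly_truth` marks pixels where the added
#' amplitude exceeds 10% of the peak; placements whose truth region falls
#' less than half inside the lung are rejected and redrawn. The blob profile
#' is truncated at three Gaussian widths, so pixels outside that bounded
#' neighborhood are untouched.
#'
#' @param sample a normal `phantom_sample`.
#' @param rng_seed integer seed for all draws.
#' @param amplitude_range peak added intensity, default `c(0.2, 0.5)`.
#' @return an abnormal `phantom_sample` copy.
#' @export
inject_opacity <- function(sample, rng_seed, amplitude_range = c(0.2, 0.5)) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (!identical(sample$label, "normal"))
    stop("inject_opacity requires a normal sample")
  if (sum(sample$lung_truth) == 0) stop("lung_truth is empty")
  if (max(amplitude_range) <= 0)
    stop("zero-amplitude opacity is invalid: it would leave the image ",
         "unchanged while claiming an anomaly")
  S <- nrow(sample$image)
  lung_idx <- which(sample$lung_truth == 1, arr.ind = TRUE)

  draw <- function() {
    amp <- runif(1, amplitude_range[1], amplitude_range[2])
    for (attempt in 1:100) {
      ctr <- lung_idx[sample.int(nrow(lung_idx), 1), ] - 1  # 0-based
      sig <- runif(2, 0.035, 0.08) * S                      # Gaussian widths
      r <- matrix(0:(S - 1), S, S) - ctr[1]
      c <- matrix(0:(S - 1), S, S, byrow = TRUE) - ctr[2]
      q <- (r / sig[1])^2 + (c / sig[2])^2
      add <- amp * exp(-q / 2)
      add[q > 9] <- 0                                       # 3-sigma truncation
      truthm <- (add > 0.1 * amp) * 1
      if (sum(truthm & sample$lung_truth) >= 0.5 * sum(truthm))
        return(list(add = add, truth = truthm))
    }
    stop("could not place an opacity at least half inside the lung mask ",
         "after 100 attempts")
  }
  res <- with_seed(rng_seed, draw())

  out <- sample
  out$image <- clip01(sample$image + res$add)
  out$label <- "abnormal"
  out$anomaly_truth <- res$truth
  out
}

#' Generate a labeled phantom dataset
#'
#' Convenience generator for pipelines and tests: `n_normal` normal and
#' `n_abnormal` opacity-injected phantoms with per-sample jittered anatomy,
#' all seeded from one master seed.
#'
#' @param n_normal,n_abnormal sample counts.
#' @param image_size working resolution.
#' @param seed master seed.
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data.frame: id, label, seed).
#' @export
phantom_dataset <- function(n_normal, n_abnormal = 0, image_size = 256L,
                            seed = 1L) {
  n <- n_normal + n_abnormal
  samples <- vector("list", n)
  man <- data.frame(id = character(n), label = character(n), seed = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    abn <- i > n_normal
    sp <- phantom_spec(image_size, seed = mix_seed(seed, "spec", i),
                       rng_seed = mix_seed(seed, "render", i))
    s <- generate_normal_phantom(sp)
    if (abn) s <- inject_opacity(s, mix_seed(seed, "opacity", i))
    id <- sprintf("%s_%04d", if (abn) "abn" else "nrm", i)
    samples[[i]] <- s
    man$id[i] <- id
    man$label[i] <- s$label
    man$seed[i] <- sp$rng_seed
  }
  list(samples = samples, manifest = man)
}
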