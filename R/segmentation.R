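# Annotation-free lung-field segmentation.
#
# Pipeline: CLAHE local histogram equalization -> Otsu binarization (dark
# foreground: lungs are radiolucent) -> morphological opening (kills specks
# and rib-edge fragments) -> border clearing (peripheral soft tissue and
# vignetted corners touch the frame) -> disc dilation (recovers the full
# lung extent lost to the conservative threshold) -> minimum-component-area
# filtering (drops vessels/clavicle fragments). 8-connectivity throughout.

#' Segmentation parameters
#'
#' Defaults are stated at the 256x256 working resolution and scale
#' proportionally with `image_size`: opening radius 2 px, dilation radius
#' 8 px, minimum component area `t = 2%` of the frame. CLAHE uses clip
#' limit 2.0 (relative to the uniform tile histogram) on an 8x8 tile grid.
#'
#' @param image_size resolution the radii/area threshold are resolved at.
#' @param clahe_clip_limit positive real; multiples of the mean bin count.
#' @param clahe_tile_grid integer pair (rows, cols) of tiles.
#' @param otsu_polarity `"dark_foreground"` (lungs, default) or
#'   `"bright_foreground"`.
#' @param opening_radius,dilation_radius disc radii in pixels.
#' @param t minimum connected-component area in pixels.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(image_size = 256L,
                       clahe_clip_limit = 2.0,
                       clahe_tile_grid = c(8L, 8L),
                       otsu_polarity = c("dark_foreground", "bright_foreground"),
                       opening_radius = NULL,
                       dilation_radius = NULL,
                       t = NULL) {
  S <- as.integer(image_size)
  otsu_polarity <- match.arg(otsu_polarity)
  if (is.null(opening_radius)) opening_radius <- max(1L, as.integer(round(2 * S / 256)))
  if (is.null(dilation_radius)) dilation_radius <- max(1L, as.integer(round(8 * S / 256)))
  if (is.null(t)) t <- as.integer(ceiling(0.02 * S * S))
  stopifnot(t >= 1, opening_radius >= 0, dilation_radius >= 0,
            clahe_clip_limit > 0, all(clahe_tile_grid >= 1))
  structure(list(
    clahe_clip_limit = clahe_clip_limit,
    clahe_tile_grid = as.integer(clahe_tile_grid),
    otsu_polarity = otsu_polarity,
    opening_radius = as.integer(opening_radius),
    dilation_radius = as.integer(dilation_radius),
    t = as.integer(t)
  ), class = "seg_params")
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise 256-bin histograms are clipped at
#' `clip_limit * n_tile_pixels / 256`, the excess redistributed uniformly,
#' and each pixel is mapped through a bilinear interpolation of the four
#' surrounding tile CDFs (border tiles replicated). Output in `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params a [seg_params()]; only the CLAHE fields are used.
#' @return equalized matrix, same shape.
#' @export
equalize_local_histogram <- function(image, params = seg_params(nrow(image))) {
  check_image(image)
  gr <- params$clahe_tile_grid[1]; gc <- params$clahe_tile_grid[2]
  H <- nrow(image); W <- ncol(image)
  if (H < gr || W < gc)
    stop("image (", H, "x", W, ") is smaller than one CLAHE tile grid (",
         gr, "x", gc, ")")
  nbins <- 256L
  bins <- pmin(floor(image * nbins) + 1L, nbins)

  row_edges <- round(seq(0, H, length.out = gr + 1))
  col_edges <- round(seq(0, W, length.out = gc + 1))
  maps <- matrix(0, nbins, gr * gc)           # per-tile CDF lookup tables
  centers_r <- numeric(gr); centers_c <- numeric(gc)
  for (tj in seq_len(gc)) {
    for (ti in seq_len(gr)) {
      rs <- (row_edges[ti] + 1):row_edges[ti + 1]
      cs <- (col_edges[tj] + 1):col_edges[tj + 1]
      tb <- bins[rs, cs]
      n <- length(tb)
      h <- tabulate(tb, nbins)
      clip <- max(1, params$clahe_clip_limit * n / nbins)
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / nbins
      maps[, (tj - 1) * gr + ti] <- cumsum(h) / n
      if (tj == 1) centers_r[ti] <- (row_edges[ti] + row_edges[ti + 1] - 1) / 2
      if (ti == 1) centers_c[tj] <- (col_edges[tj] + col_edges[tj + 1] - 1) / 2
    }
  }

  interp_idx <- function(pos, centers) {
    # neighboring tile indices and weight toward the upper one, clamped
    i1 <- findInterval(pos, centers)
    i0 <- pmax(i1, 1); i1 <- pmin(i1 + 1, length(centers))
    w <- ifelse(i1 > i0, (pos - centers[i0]) / (centers[i1] - centers[i0]), 0)
    list(lo = i0, hi = i1, w = pmin(pmax(w, 0), 1))
  }
  ri <- interp_idx(0:(H - 1), centers_r)
  ci <- interp_idx(0:(W - 1), centers_c)

  tile_at <- function(tr, tc) (tc - 1) * gr + tr
  look <- function(tr_vec, tc_vec) {
    tid <- matrix(tile_at(rep(tr_vec, times = W), rep(tc_vec, each = H)), H, W)
    matrix(maps[cbind(as.vector(bins), as.vector(tid))], H, W)
  }
  wr <- matrix(ri$w, H, W); wc <- matrix(ci$w, H, W, byrow = TRUE)
  out <- (1 - wr) * (1 - wc) * look(ri$lo, ci$lo) +
         (1 - wr) * wc       * look(ri$lo, ci$hi) +
         wr       * (1 - wc) * look(ri$hi, ci$lo) +
         wr       * wc       * look(ri$hi, ci$hi)
  clip01(out)
}

#' Otsu threshold of a 256-bin histogram
#'
#' Exhaustive scan over all candidate cuts: the threshold after bin `k`
#' maximizes the between-class variance `w0 w1 (mu0 - mu1)^2`. Ties are
#' broken toward the smallest threshold. Returned on the `[0, 1]` intensity
#' scale as the upper edge `k / 256` of the optimal lower class.
#'
#' @param image numeric matrix in `[0, 1]` with at least two distinct values.
#' @param nbins histogram resolution (default 256).
#' @return threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  check_image(image)
  if (length(unique(as.vector(image))) < 2)
    stop("Otsu threshold undefined: image is constant")
  bins <- pmin(floor(image * nbins) + 1L, nbins)
  counts <- tabulate(bins, nbins)
  k <- otsu_cut(counts)
  k / nbins
}

# Optimal cut index k (lower class = bins 1..k) for a histogram of counts.
otsu_cut <- function(counts) {
  nbins <- length(counts)
  n <- sum(counts)
  centers <- seq_len(nbins) - 0.5
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * centers) / n
  mt <- m0[nbins]
  sb <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  cand <- which(w0 > 0 & w0 < 1)
  if (length(cand) == 0) stop("Otsu cut undefined: degenerate histogram")
  cand[which.max(sb[cand])]            # which.max takes the first maximizer
}

#' Binarize an image by Otsu's method
#'
#' With `dark_foreground` (default; lungs are dark) pixels `<=` threshold
#' become foreground, otherwise pixels `>` threshold do.
#'
#' @inheritParams otsu_threshold
#' @param polarity which intensity class is foreground.
#' @return binary matrix.
#' @export
binarize_otsu <- function(image, polarity = c("dark_foreground",
                                              "bright_foreground")) {
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(image)
  if (polarity == "dark_foreground") (image <= thr) * 1 else (image > thr) * 1
}

#' Morphological opening / dilation with a disc structuring element
#'
#' Discrete disc: offsets with `dr^2 + dc^2 <= radius^2`. Radius 0 is the
#' identity. Pixels outside the image count as background for erosion.
#'
#' @param mask binary matrix.
#' @param radius disc radius in pixels.
#' @return binary matrix.
#' @export
morph_open <- function(mask, radius) {
  check_mask(mask)
  m <- matrix(as.integer(mask), nrow(mask))
  out <- .cpp_dilate(.cpp_erode(m, as.integer(radius)), as.integer(radius))
  matrix(as.numeric(out), nrow(mask))
}

#' @rdname morph_open
#' @export
morph_dilate <- function(mask, radius) {
  check_mask(mask)
  out <- .cpp_dilate(matrix(as.integer(mask), nrow(mask)), as.integer(radius))
  matrix(as.numeric(out), nrow(mask))
}

#' Connected-component labeling
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (integer matrix, 0 = background) and `sizes`
#'   (pixel count per label).
#' @export
label_components <- function(mask, connectivity = 8L) {
  check_mask(mask)
  lab <- .cpp_label(matrix(as.integer(mask), nrow(mask)),
                    as.integer(connectivity))
  k <- max(lab)
  list(labels = lab, sizes = if (k > 0) tabulate(lab[lab > 0], k) else integer(0))
}

#' Remove components connected to the image border
#'
#' Every 8-connected component containing at least one border pixel is
#' cleared; interior components pass through untouched.
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return binary matrix.
#' @export
clear_border <- function(mask, connectivity = 8L) {
  lc <- label_components(mask, connectivity)
  lab <- lc$labels
  H <- nrow(lab); W <- ncol(lab)
  border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  border <- border[border > 0]
  out <- mask
  out[lab %in% border] <- 0
  out
}

#' Drop components smaller than a minimum area
#'
#' Components with fewer than `t` pixels are zeroed; the rest are retained
#' verbatim. `t = 1` is the identity.
#'
#' @param mask binary matrix.
#' @param t minimum component area in pixels (`>= 1`).
#' @param connectivity 8 (default) or 4.
#' @return binary matrix.
#' @export
filter_components <- function(mask, t, connectivity = 8L) {
  stopifnot(t >= 1)
  lc <- label_components(mask, connectivity)
  if (length(lc$sizes) == 0) return(mask)
  small <- which(lc$sizes < t)
  out <- mask
  out[lc$labels %in% small] <- 0
  out
}

#' Segment the lung fields of a radiograph
#'
#' Runs the full pipeline (equalize, binarize, open, clear border, dilate,
#' filter by area). An empty result is returned with a warning rather than
#' an error so heterogeneous batches can skip failures.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params a [seg_params()]; defaults resolved at the image's own
#'   resolution.
#' @return binary lung mask, same shape as `image`.
#' @export
segment_lungs <- function(image, params = seg_params(nrow(image))) {
  check_image(image)
  eq <- equalize_local_histogram(image, params)
  bw <- binarize_otsu(eq, params$otsu_polarity)
  bw <- morph_open(bw, params$opening_radius)
  bw <- clear_border(bw)
  bw <- morph_dilate(bw, params$dilation_radius)
  out <- filter_components(bw, params$t)
  if (sum(out) == 0)
    warning("lung segmentation produced an empty mask")
  out
}
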