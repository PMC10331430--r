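#' @useDynLib lungpaste, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif dnorm
#' @importFrom utils write.csv read.csv
NULL

# Deterministic seed substreams -------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams (data, init, augmentation, splits, ...). Mixing is a simple
#' multiplicative-congruential hash kept below 2^31 so the result is always a
#' valid R seed.
#'
#' @param seed integer master seed.
#' @param ... further integers or strings naming the substream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
mix_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    for (x in as.double(p)) {
      h <- (h * 69069 + (x %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645L + 1L)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers never perturb the global RNG
#' stream. Used by every sampling operation to honour its determinism
#' contract.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Image containers ---------------------------------------------------------

#' Validate a radiograph intensity grid
#'
#' Radiograph images are plain numeric matrices with finite values in
#' `[0, 1]` (radiographic display convention: air/lung dark, bone bright).
#'
#' @param img numeric matrix.
#' @param arg name used in error messages.
#' @return the matrix, invisibly validated.
#' @export
check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", arg))
  if (any(!is.finite(img)))
    stop(sprintf("%s contains non-finite values", arg))
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("%s values must lie in [0, 1]", arg))
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("%s must be a numeric matrix", arg))
  if (!all(mask %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", arg))
  invisible(mask)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary matrices of identical shape.
#' @return real in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# Gaussian blur -------------------------------------------------------------

#' Separable Gaussian blur with zero padding
#'
#' The kernel is truncated at three standard deviations and normalized to
#' unit sum, so blurring never increases the maximum value. Zero padding is
#' the natural boundary condition for opacity fields that live amid zeros.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` is the identity.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in -h:h) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + h + 1]
    }
    B
  }
  Bh <- band(nrow(img))
  Bw <- band(ncol(img))
  Bh %*% img %*% t(Bw)
}

# Grayscale image file I/O --------------------------------------------------

#' Read / write 8-bit grayscale images
#'
#' PNG is used when the `png` package is available; portable graymap
#' (`.pgm`, binary P5 or plain P2) is always supported as a dependency-free
#' fallback. Values are scaled to/from `[0, 1]`.
#'
#' @param path file path; format chosen by extension (`.png` or `.pgm`).
#' @param img numeric matrix in `[0, 1]` (for writing).
#' @return `read_gray` returns a numeric matrix in `[0, 1]`.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package; use .pgm instead")
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    return(x)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image extension: ", ext)
}

#' @rdname read_gray
#' @export
write_gray <- function(img, path) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package; use .pgm instead")
    png::writePNG(img, path)
    return(invisible(path))
  }
  if (ext == "pgm") {
    write_pgm(img, path)
    return(invisible(path))
  }
  stop("unsupported image extension: ", ext)
}

#' Default grayscale image extension for this installation
#' @return `"png"` if the png package is installed, else `"pgm"`.
#' @export
default_image_ext <- function() {
  if (requireNamespace("png", quietly = TRUE)) "png" else "pgm"
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  tok <- function() {
    # whitespace/comment-tolerant token scanner
    repeat {
      ch <- readChar(con, 1)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        while (ch != "\n") ch <- readChar(con, 1)
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  n <- w * h
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  } else if (magic == "P2") {
    raw <- integer(0)
    while (length(raw) < n) {
      ln <- readLines(con, 1)
      raw <- c(raw, as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    }
  } else stop("not a PGM file: ", path)
  matrix(raw / mx, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path, binary = TRUE) {
  v <- as.integer(round(t(img) * 255))  # row-major order
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
              eos = NULL)
    writeBin(as.raw(v), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    writeLines(paste(v, collapse = " "), con)
  }
  invisible(path)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
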