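# Kernel-density anomaly scoring.
#
# The density of a query embedding z against the normal-training bank
# {z_i} is A(z) = (1/N) sum_i K(z - z_i) with the unit-bandwidth Gaussian
# kernel K(z) = exp(-||z||^2 / 2) (the proportionality constant is
# irrelevant after min-max normalization and fixed to 1). Low density means
# anomalous, so the raw anomaly score is -log A(z), computed stably via
# log-sum-exp: high-dimensional densities underflow double precision long
# before the ranking degrades.

#' KDE raw anomaly scores
#'
#' Returns `-log A(z)` per query with
#' `A(z) = (1/N) sum_i exp(-||z - z_i||^2 / (2 h^2))`, evaluated by
#' log-sum-exp. Higher = more anomalous.
#'
#' @param queries numeric `m x D` matrix (or length-D vector) of query
#'   embeddings.
#' @param bank numeric `N x D` matrix of reference (training) embeddings.
#' @param bandwidth Gaussian kernel bandwidth `h`, default 1 (the kernel
#'   exactly as stated).
#' @return numeric vector of `m` raw scores.
#' @export
kde_score <- function(queries, bank, bandwidth = 1) {
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  if (is.null(dim(bank))) bank <- matrix(bank, nrow = 1)
  if (nrow(bank) == 0) stop("empty reference bank")
  if (ncol(queries) != ncol(bank))
    stop("embedding dimension mismatch: queries ", ncol(queries),
         ", bank ", ncol(bank))
  # squared distances via the expansion ||q||^2 + ||b||^2 - 2 q.b
  qn <- rowSums(queries^2)
  bn <- rowSums(bank^2)
  d2 <- outer(qn, bn, "+") - 2 * queries %*% t(bank)
  d2 <- pmax(d2, 0)
  e <- -d2 / (2 * bandwidth^2)
  m <- apply(e, 1, max)
  logdens <- m + log(rowMeans(exp(e - m)))
  -logdens
}

#' KDE density of a single query (convenience wrapper)
#'
#' The density itself, `A(z)`; underflows for distant queries in high
#' dimension — prefer [kde_score()] (its negative log) for ranking.
#'
#' @inheritParams kde_score
#' @param z length-D query vector.
#' @return non-negative scalar density.
#' @export
kde_density <- function(z, bank, bandwidth = 1) {
  exp(-kde_score(matrix(z, nrow = 1), bank, bandwidth))
}

#' Min-max normalize scores to `[0, 1]`
#'
#' Over the provided set; the minimum maps to 0 and the maximum to 1. A
#' constant input has no order information and maps to all 0.5 with a
#' warning.
#'
#' @param raw_scores numeric vector, length `>= 2`.
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(raw_scores) {
  if (length(raw_scores) == 0) stop("no scores to normalize")
  if (length(raw_scores) < 2) stop("need at least 2 scores to normalize")
  rng <- range(raw_scores)
  if (diff(rng) == 0) {
    warning("constant scores: normalizing to all 0.5")
    return(rep(0.5, length(raw_scores)))
  }
  (raw_scores - rng[1]) / diff(rng)
}

#' Select the F1-maximizing decision threshold
#'
#' Exhaustive scan over candidate cuts — midpoints of consecutive sorted
#' unique scores plus the `-Inf`/`+Inf` extremes — with the decision rule
#' `score >= threshold` implies abnormal (positive class). Ties in F1 are
#' broken toward the lower threshold (higher sensitivity). F1 of an
#' all-negative prediction is defined as 0.
#'
#' @param normalized_scores numeric vector.
#' @param labels 0/1 vector (1 = abnormal); both classes required.
#' @return list with `threshold`, `f1_at_threshold`.
#' @export
select_threshold <- function(normalized_scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("threshold selection needs both classes")
  u <- sort(unique(normalized_scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  f1s <- vapply(cand, function(th)
    accuracy_f1(normalized_scores, labels, th)["f1"], 0)
  best <- which.max(f1s)               # first maximum = lowest threshold
  list(threshold = cand[best], f1_at_threshold = unname(f1s[best]))
}

#' Average an ensemble of normalized score sets
#'
#' Per-image arithmetic mean of the normalized scores of several models
#' over the same images, re-normalized min-max.
#'
#' @param score_sets list (length `>= 2`) of equally long numeric vectors;
#'   if named, names must agree across sets.
#' @return numeric vector of ensemble scores in `[0, 1]`.
#' @export
ensemble_scores <- function(score_sets) {
  if (length(score_sets) < 2) stop("need at least 2 score sets")
  n <- length(score_sets[[1]])
  nm <- names(score_sets[[1]])
  for (s in score_sets) {
    if (length(s) != n) stop("score sets are misaligned (unequal lengths)")
    if (!is.null(nm) && !identical(names(s), nm))
      stop("score sets are misaligned (image ids differ)")
  }
  m <- rowMeans(do.call(cbind, score_sets))
  out <- normalize_scores(m)
  names(out) <- nm
  out
}
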