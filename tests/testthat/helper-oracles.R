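# Independent brute-force oracles. Deliberately naive implementations kept
# free of any package internals, used to pin down the fast paths.

# Flood-fill connected-component labeling (queue-based, 4- or 8-conn).
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] != 0 && lab[r, c] == 0) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

oracle_clear_border <- function(mask, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  bad <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  bad <- bad[bad > 0]
  out <- mask
  out[lab %in% bad] <- 0
  out
}

oracle_filter_components <- function(mask, t, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  out <- mask
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab))) if (sum(lab == k) < t) out[lab == k] <- 0
  out
}

# Direct-definition erosion/dilation with a disc structuring element.
oracle_erode <- function(mask, radius) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0) next
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      r <- i + off$dr[k]; c <- j + off$dc[k]
      if (r < 1 || r > H || c < 1 || c > W || mask[r, c] == 0) {
        keep <- FALSE; break
      }
    }
    if (keep) out[i, j] <- 1
  }
  out
}

oracle_dilate <- function(mask, radius) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0) next
    for (k in seq_len(nrow(off))) {
      r <- i + off$dr[k]; c <- j + off$dc[k]
      if (r >= 1 && r <= H && c >= 1 && c <= W) out[r, c] <- 1
    }
  }
  out
}

# Exhaustive Otsu: between-class variance computed from first principles for
# every candidate cut; returns the (smallest) argmax cut index.
oracle_otsu_cut <- function(counts) {
  nb <- length(counts)
  centers <- seq_len(nb) - 0.5
  n <- sum(counts)
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(nb - 1)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nb] * centers[(k + 1):nb]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  best_k
}

# Double-loop Gaussian KDE raw scores (log via direct density when it does
# not underflow; the comparison cases are built small enough for that).
oracle_kde <- function(queries, bank) {
  m <- nrow(queries)
  out <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(nrow(bank)))
      s <- s + exp(-sum((queries[i, ] - bank[j, ])^2) / 2)
    out[i] <- -log(s / nrow(bank))
  }
  out
}

# All-pairs AUC with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

oracle_f1_at <- function(scores, labels, thr) {
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# Enumerate every cut (all midpoints plus extremes) and return the best F1.
oracle_best_f1 <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  max(vapply(cand, function(th) oracle_f1_at(scores, labels, th), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shannon_entropy <- function(x, nbins = 64) {
  h <- tabulate(pmin(floor(x * nbins) + 1L, nbins), nbins)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p))
}
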