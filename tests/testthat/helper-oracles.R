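# Independent brute-force oracles used by unit and acceptance tests.
# These are written against the definitions, not against the package code:
# direct set counts for overlap metrics, all-pairs boundary distances for
# HD95, exhaustive concordant-pair counting for AUC, and an exhaustive
# threshold sweep for the Youden index.

oracle_overlap <- function(p, t) {
  p <- which(p > 0); t <- which(t > 0)
  ni <- length(intersect(p, t)); nu <- length(union(p, t))
  if (length(p) + length(t) == 0) return(c(dsc = 1, iou = 1))
  c(dsc = 2 * ni / (length(p) + length(t)), iou = ni / nu)
}

oracle_rve <- function(p, t) abs(sum(p > 0) - sum(t > 0)) / sum(t > 0) * 100

# boundary: foreground voxel with a face-adjacent background neighbour
# (or on the volume border), found by explicit neighbour loops
oracle_boundary <- function(b) {
  d <- dim(b)
  idx <- which(b, arr.ind = TRUE)
  on_b <- apply(idx, 1, function(v) {
    for (a in 1:3) for (s in c(-1L, 1L)) {
      n <- v; n[a] <- n[a] + s
      if (n[a] < 1 || n[a] > d[a]) return(TRUE)
      if (!b[n[1], n[2], n[3]]) return(TRUE)
    }
    FALSE
  })
  idx[on_b, , drop = FALSE] - 1L
}

oracle_hd95 <- function(p, t, spacing, percentile = 0.95) {
  bp <- sweep(oracle_boundary(p), 2, spacing, `*`)
  bt <- sweep(oracle_boundary(t), 2, spacing, `*`)
  # explicit all-pairs distance matrix
  dmat <- sqrt(outer(bp[, 1], bt[, 1], `-`)^2 +
                 outer(bp[, 2], bt[, 2], `-`)^2 +
                 outer(bp[, 3], bt[, 3], `-`)^2)
  d <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  unname(stats::quantile(d, percentile, type = 7))
}

# AUC by exhaustive pair enumeration with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive Youden sweep over all candidate thresholds
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores, Inf)))
  best <- -Inf; best_thr <- NA
  for (th in cand) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    J <- sens + spec - 1
    if (J > best + 1e-12) { best <- J; best_thr <- th }
  }
  c(threshold = best_thr, J = best)
}

random_binary_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dim = dims)
}
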