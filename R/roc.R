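# ROC/AUC machinery: rank-based AUC with DeLong variance and confidence
# intervals, Youden-optimal thresholds, confusion matrices at a threshold,
# and the paired DeLong test for comparing two AUCs.

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}

# variance/covariance that degrade to 0 (not NA) for single-observation
# placement sets, so one-positive or one-negative designs stay defined
var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)
cov0 <- function(m) if (nrow(m) < 2L) matrix(0, 2, 2) else stats::cov(m)

# DeLong placement values: V10 (per positive), V01 (per negative), using
# midranks; AUC is their common mean.
delong_placements <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- sum(r_all[seq_len(m)] - r_pos) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney probability of concordance with half credit
#' for ties (midrank estimator); the curve is swept over all distinct score
#' thresholds (prediction positive iff score >= threshold).  The 95% CI
#' uses the DeLong variance with a normal approximation, clipped to
#' \[0, 1\].
#'
#' @param scores continuous scores, higher = more AI-like.
#' @param labels binary 0/1, both classes present.
#' @return An `ROCResult`: list(thresholds, tpr, fpr, auc, ci95, se).
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  pl <- delong_placements(scores, labels)
  var_auc <- var0(pl$v10) / pl$m + var0(pl$v01) / pl$n
  se <- sqrt(max(var_auc, 0))
  ci <- pmin(pmax(pl$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = pl$auc,
                 ci95 = ci, se = se),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("<ROCResult> AUC %.4f (95%% CI %.4f-%.4f), %d thresholds\n",
              x$auc, x$ci95[1], x$ci95[2], length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Exhaustive sweep over the ROC candidate cut-offs for the threshold
#' maximizing `J = sensitivity + specificity - 1`.  Ties are broken toward
#' the lowest threshold (maximizing sensitivity, the screening-friendly
#' choice); a message is emitted when the tie-break applies.
#'
#' @param roc an [roc_auc()] result.
#' @return `c(threshold = , J = )`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "ROCResult"))
  if (length(roc$thresholds) < 2L)
    stop("ROC must contain at least 2 candidate thresholds")
  J <- roc$tpr - roc$fpr
  best <- max(J)
  cand <- which(J >= best - 1e-12)
  finite <- roc$thresholds[cand][is.finite(roc$thresholds[cand])]
  if (length(cand) > 1L)
    message("Youden tie over ", length(cand),
            " thresholds; lowest threshold chosen")
  thr <- if (length(finite)) min(finite) else min(roc$thresholds[cand])
  c(threshold = thr, J = best)
}

#' Confusion matrix at a threshold
#'
#' Prediction positive iff `score >= threshold`; accuracy, sensitivity and
#' specificity derived from the counts.
#'
#' @param scores continuous scores.
#' @param labels binary 0/1.
#' @param threshold decision cut-off.
#' @return A `ConfusionMatrix`: list(tp, fp, tn, fn, accuracy, sensitivity,
#'   specificity, threshold).
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  confusion_from_counts(tp, fp, tn, fn, threshold)
}

confusion_from_counts <- function(tp, fp, tn, fn, threshold = NA_real_) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat(sprintf(paste0("<ConfusionMatrix> TP %d FP %d TN %d FN %d | acc %.2f%%",
                     " sens %.2f%% spec %.2f%% @ %.3g\n"),
              x$tp, x$fp, x$tn, x$fn, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$threshold))
  invisible(x)
}

#' Rebuild a confusion matrix from class composition and printed rates
#'
#' Given a dataset's positive/negative composition and printed sensitivity
#' and specificity (percent, as rounded in a report), reconstructs the
#' integer counts (`tp = round(sens/100 * n_pos)` etc.) and the implied
#' accuracy -- the arithmetic that lets published per-side tables be
#' checked exactly.
#'
#' @param n_pos,n_neg class composition.
#' @param sens_pct,spec_pct printed sensitivity and specificity in percent.
#' @return A `ConfusionMatrix`.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sens_pct, spec_pct) {
  tp <- round(sens_pct / 100 * n_pos)
  tn <- round(spec_pct / 100 * n_neg)
  confusion_from_counts(tp, n_neg - tn, tn, n_pos - tp)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Midrank placement-value estimates of the AUC covariance structure; the
#' paired variance of the AUC difference feeds a two-sided normal test.
#' A degenerate zero-variance comparison (e.g. identical score vectors)
#' is reported with `p = 1` and `degenerate = TRUE`.
#'
#' @param scores_a,scores_b score vectors for the same instances.
#' @param labels binary 0/1 labels shared by both score sets.
#' @param paired must be `TRUE` (unpaired comparison is out of scope).
#' @return A `DelongResult`: list(auc_a, auc_b, difference, variance, z,
#'   p_value, degenerate).
#' @export
delong_test <- function(scores_a, scores_b, labels, paired = TRUE) {
  if (!paired) stop("only the paired DeLong test is implemented")
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- cov0(cbind(pa$v10, pb$v10))
  s01 <- cov0(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    return(structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
                          variance = 0, z = NA_real_, p_value = 1,
                          degenerate = TRUE),
                     class = "DelongResult"))
  }
  z <- diff / sqrt(var_diff)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
                 variance = var_diff, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE),
            class = "DelongResult")
}

#' @export
print.DelongResult <- function(x, ...) {
  cat(sprintf("<DelongResult> AUC %.4f vs %.4f, diff %.4f, z %.3f, p %.4g%s\n",
              x$auc_a, x$auc_b, x$difference,
              if (is.na(x$z)) 0 else x$z, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
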