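# Segmentation evaluation: DSC, IOU, RVE and HD95, with spacing-aware
# boundary distances, per-side and whole-image aggregation.

as_binary_array <- function(x) {
  if (inherits(x, "CTVolume")) x <- x$voxels
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x > 0
}

#' Overlap metrics (DSC and IOU)
#'
#' `dsc = 2|P intersect T| / (|P| + |T|)`; `iou = |P intersect T| / |P union T|`.
#' When both masks are empty both metrics are 1 by convention (perfect
#' absence is not penalised); a message is emitted when this triggers.
#'
#' @param pred,truth binary masks (logical/numeric arrays or `LabelMask`s;
#'   non-zero = foreground), aligned grids.
#' @return `c(dsc = , iou = )`, fractions in \[0, 1\].
#' @export
overlap_metrics <- function(pred, truth) {
  p <- as_binary_array(pred); t <- as_binary_array(truth)
  if (!all(dim(p) == dim(t)))
    stop("mask shapes do not match: ", paste(dim(p), collapse = "x"),
         " vs ", paste(dim(t), collapse = "x"))
  np <- sum(p); nt <- sum(t)
  if (np == 0 && nt == 0) {
    message("both masks empty; returning (1, 1) by convention")
    return(c(dsc = 1, iou = 1))
  }
  ni <- sum(p & t)
  c(dsc = 2 * ni / (np + nt), iou = ni / (np + nt - ni))
}

#' Relative volume error (percent)
#'
#' `|V_pred - V_truth| / V_truth * 100`, volumes as voxel counts (spacing
#' cancels on aligned grids).
#'
#' @inheritParams overlap_metrics
#' @return percentage (>= 0).
#' @export
rve <- function(pred, truth) {
  p <- as_binary_array(pred); t <- as_binary_array(truth)
  if (!all(dim(p) == dim(t))) stop("mask shapes do not match")
  nt <- sum(t)
  if (nt == 0) stop("RVE undefined: truth mask is empty")
  abs(sum(p) - nt) / nt * 100
}

# boundary voxels: foreground with at least one face-adjacent background
# neighbour (volume border counts as having an outside background neighbour)
boundary_voxels <- function(b) {
  d <- dim(b)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- b
  inner <- pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  which(b & !inner, arr.ind = TRUE) - 1L
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Pooled symmetric definition: the 95th percentile (linear interpolation,
#' `stats::quantile` type 7) of the union of directed boundary-to-boundary
#' nearest distances pred -> truth and truth -> pred, in world mm.  A
#' boundary voxel is a foreground voxel with a face-adjacent background
#' neighbour.  Errors if either mask is empty (the metric is reported as
#' missing, never as 0).
#'
#' @inheritParams overlap_metrics
#' @param spacing mm triple (taken from `pred` when it is a `CTVolume`).
#' @param percentile quantile of the pooled distances, default 0.95.
#' @return distance in mm.
#' @export
hd95 <- function(pred, truth, spacing = NULL, percentile = 0.95) {
  if (is.null(spacing)) {
    spacing <- if (inherits(pred, "CTVolume")) pred$spacing else c(1, 1, 1)
  }
  p <- as_binary_array(pred); t <- as_binary_array(truth)
  if (!all(dim(p) == dim(t))) stop("mask shapes do not match")
  if (!any(p) || !any(t))
    stop("HD95 undefined: empty mask (reported as missing, not 0)")
  bp <- sweep(boundary_voxels(p), 2, spacing, `*`)
  bt <- sweep(boundary_voxels(t), 2, spacing, `*`)
  d <- c(cpp_min_dists(bp, bt), cpp_min_dists(bt, bp))
  unname(stats::quantile(d, percentile, type = 7))
}

#' Evaluate a predicted label mask against ground truth
#'
#' Computes DSC, IOU (both percent), RVE (percent) and HD95 (mm) for the
#' left gland (label 1), right gland (label 2) and the whole image (union
#' of foreground labels, or the side average with `whole = "average"`).
#' Sides absent from the truth are reported as `NA` (flagged missing).
#'
#' @param pred,truth aligned `LabelMask`s.
#' @param whole `"union"` (default) or `"average"`.
#' @return A `SegMetricsReport` data.frame with rows whole/left/right and
#'   columns dsc, iou, rve, hd95.
#' @export
evaluate_segmentation <- function(pred, truth, whole = c("union", "average")) {
  whole <- match.arg(whole)
  stopifnot(is_mask(pred), is_mask(truth),
            all(dim(pred$voxels) == dim(truth$voxels)))
  one <- function(pb, tb) {
    if (!any(tb))
      return(c(dsc = NA_real_, iou = NA_real_, rve = NA_real_,
               hd95 = NA_real_))
    ov <- suppressMessages(overlap_metrics(pb, tb))
    h <- if (any(pb)) hd95(pb, tb, spacing = truth$spacing) else NA_real_
    c(dsc = 100 * ov[["dsc"]], iou = 100 * ov[["iou"]],
      rve = rve(pb, tb), hd95 = h)
  }
  left <- one(pred$voxels == 1L, truth$voxels == 1L)
  right <- one(pred$voxels == 2L, truth$voxels == 2L)
  whole_row <- if (whole == "union")
    one(pred$voxels > 0L, truth$voxels > 0L)
  else colMeans(rbind(left, right), na.rm = TRUE)
  out <- as.data.frame(rbind(whole = whole_row, left = left, right = right))
  out$region <- rownames(out)
  class(out) <- c("SegMetricsReport", "data.frame")
  out[, c("region", "dsc", "iou", "rve", "hd95")]
}

#' Aggregate per-patient segmentation reports
#'
#' Unweighted per-patient mean and standard deviation per region and
#' metric, the usual cohort-table style.
#'
#' @param reports list of [evaluate_segmentation()] outputs.
#' @return data.frame with region, metric, mean, sd, n.
#' @export
aggregate_seg_reports <- function(reports) {
  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- as.data.frame(reports[[i]])
    r$patient <- i
    r
  }))
  out <- list()
  for (region in unique(long$region))
    for (metric in c("dsc", "iou", "rve", "hd95")) {
      v <- long[long$region == region, metric]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        region = region, metric = metric,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v))
    }
  do.call(rbind, out)
}
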