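# Cleaning of raw network output: connected-component noise removal, hole
# filling and laterality assignment.  Default pipeline order is
# components -> remove noise (keep largest per label) -> fill holes, so
# that hole filling cannot merge specks into glands first.

#' Connected components of a label mask
#'
#' Per foreground label, labels maximal connected components under the
#' requested neighbourhood order.
#'
#' @param mask a `LabelMask`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `ComponentSet`: list with `connectivity` and `components`, a
#'   data.frame with label, component id, voxel count, centroid (0-based
#'   voxel coordinates) and bounding box.
#' @export
find_components <- function(mask, connectivity = 26) {
  stopifnot(is_mask(mask), connectivity %in% c(6, 18, 26))
  dims <- dim(mask$voxels)
  rows <- list()
  for (lab in sort(setdiff(unique(as.vector(mask$voxels)), 0L))) {
    cc <- cpp_cc_label(mask$voxels == lab, dims, as.integer(connectivity))
    for (comp in seq_len(max(cc))) {
      idx <- which(cc == comp, arr.ind = TRUE) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, component = comp, n_voxels = nrow(idx),
        cx = mean(idx[, 1]), cy = mean(idx[, 2]), cz = mean(idx[, 3]),
        x0 = min(idx[, 1]), x1 = max(idx[, 1]),
        y0 = min(idx[, 2]), y1 = max(idx[, 2]),
        z0 = min(idx[, 3]), z1 = max(idx[, 3]))
    }
  }
  comps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), component = integer(), n_voxels = integer(),
               cx = numeric(), cy = numeric(), cz = numeric(),
               x0 = integer(), x1 = integer(), y0 = integer(), y1 = integer(),
               z0 = integer(), z1 = integer())
  structure(list(connectivity = connectivity, components = comps),
            class = "ComponentSet")
}

#' Remove noise components
#'
#' Either keeps exactly the largest connected component per foreground
#' label (ties broken toward the component whose first voxel comes first
#' in scan order, i.e. the lower component id) or drops components below a
#' voxel-count threshold.
#'
#' @param mask a `LabelMask`.
#' @param policy `"keep-largest"` or `"min-size"`.
#' @param min_size voxel-count threshold for `"min-size"`.
#' @param connectivity neighbourhood order (default 26).
#' @return The cleaned `LabelMask`.
#' @export
remove_noise_components <- function(mask, policy = c("keep-largest", "min-size"),
                                    min_size = 10, connectivity = 26) {
  policy <- match.arg(policy)
  if (policy == "min-size" && min_size <= 0)
    stop("min_size must be positive")
  dims <- dim(mask$voxels)
  out <- mask$voxels
  for (lab in sort(setdiff(unique(as.vector(mask$voxels)), 0L))) {
    cc <- cpp_cc_label(mask$voxels == lab, dims, as.integer(connectivity))
    if (max(cc) == 0L) next
    sizes <- tabulate(cc[cc > 0L])
    keep <- if (policy == "keep-largest") which.max(sizes)
            else which(sizes >= min_size)
    drop <- cc > 0L & !(cc %in% keep)
    out[drop] <- 0L
    if (!any(out == lab))
      warning("label ", lab, " entirely removed by noise filtering")
  }
  label_mask(out, mask$spacing, mask$orientation, mask$origin, strict = FALSE)
}

#' Fill internal holes
#'
#' Per foreground label, fills background cavities that are not
#' 6-connected to the volume border.  Never removes a foreground voxel;
#' idempotent.
#'
#' @param mask a `LabelMask`.
#' @return The filled `LabelMask`.
#' @export
fill_holes <- function(mask) {
  stopifnot(is_mask(mask))
  dims <- dim(mask$voxels)
  out <- mask$voxels
  for (lab in sort(setdiff(unique(as.vector(mask$voxels)), 0L))) {
    bg <- out != lab
    cc <- cpp_cc_label(bg, dims, 6L)
    border_ids <- unique(c(cc[1, , ], cc[dims[1], , ],
                           cc[, 1, ], cc[, dims[2], ],
                           cc[, , 1], cc[, , dims[3]]))
    border_ids <- border_ids[border_ids > 0L]
    cavity <- bg & !(cc %in% border_ids) & out == 0L
    out[cavity] <- lab
  }
  label_mask(out, mask$spacing, mask$orientation, mask$origin, strict = FALSE)
}

#' Assign laterality to a binary adrenal mask
#'
#' Labels each connected component of a binary (gland vs background) mask
#' as left (1) or right (2) by the sign of its centroid's world coordinate
#' along the patient left-right axis relative to the volume's mid-sagittal
#' plane (components on the patient-left side of the grid midline get
#' label 1).  With both components on one side, the one nearer the midline
#' is reassigned to the empty side, with a warning.
#'
#' @param mask a binary `LabelMask` (any non-zero voxel counts as gland) or
#'   an already-sided mask, in which case sides are audited and returned.
#' @param connectivity neighbourhood order for component detection.
#' @return A `LabelMask` with labels in \{0, 1, 2\}.
#' @export
assign_laterality <- function(mask, connectivity = 26) {
  stopifnot(is_mask(mask))
  dims <- dim(mask$voxels)
  bin <- mask$voxels > 0L
  if (!any(bin))
    return(label_mask(array(0L, dims), mask$spacing, mask$orientation,
                      mask$origin))
  cc <- cpp_cc_label(bin, dims, as.integer(connectivity))
  ncomp <- max(cc)
  # world x (RAS: +x is patient right, -x is patient left)
  cent_x <- vapply(seq_len(ncomp), function(i) {
    idx <- which(cc == i, arr.ind = TRUE) - 1L
    mean(voxel_to_world(mask, idx)[, 1])
  }, numeric(1))
  corners <- rbind(c(0, 0, 0), dim(mask$voxels) - 1)
  mid_x <- mean(range(voxel_to_world(mask, as.matrix(expand.grid(
    corners[, 1], corners[, 2], corners[, 3])))[, 1]))
  side <- ifelse(cent_x < mid_x, 1L, 2L)   # -x side = patient left
  if (ncomp == 2L && length(unique(side)) == 1L) {
    warning("both components on one side of the midline; ",
            "reassigning the one nearer the midline")
    nearer <- which.min(abs(cent_x - mid_x))
    side[nearer] <- if (side[-nearer] == 1L) 2L else 1L
  }
  out <- array(0L, dims)
  for (i in seq_len(ncomp)) out[cc == i] <- side[i]
  label_mask(out, mask$spacing, mask$orientation, mask$origin)
}

#' Default postprocessing pipeline
#'
#' components -> keep largest per label -> fill holes.
#'
#' @param mask raw predicted `LabelMask`.
#' @param connectivity neighbourhood order for noise removal.
#' @return Cleaned `LabelMask`.
#' @export
postprocess_mask <- function(mask, connectivity = 26) {
  fill_holes(remove_noise_components(mask, "keep-largest",
                                     connectivity = connectivity))
}
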