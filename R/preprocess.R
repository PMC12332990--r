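# Normalisation chain for nonenhanced abdominal CT: reorientation to PLI,
# resampling to a fixed spacing, abdominal-window intensity normalisation,
# plus training-time patch sampling and augmentation.

#' Preprocessing configuration
#'
#' Defaults follow the standard recipe for this task: PLI orientation,
#' (1, 1, 3) mm spacing, abdominal window W = 350 / L = 40 HU, 96^3 input
#' patches.  Augmentation strengths are configuration, not claims.
#'
#' @param target_orientation 3-letter axis code.
#' @param target_spacing mm triple.
#' @param window_width,window_level abdominal window in HU.
#' @param patch_size voxel triple; components at least 8.
#' @param foreground_bias fraction of sampled patches forced to contain
#'   gland voxels (counters foreground-background imbalance).
#' @param noise_sigma_aug augmentation noise sd on the normalized scale.
#' @param rotation_range_deg maximum magnitude of the random in-plane
#'   rotation angle.
#' @param seed integer.
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(target_orientation = "PLI",
                              target_spacing = c(1, 1, 3),
                              window_width = 350, window_level = 40,
                              patch_size = c(96, 96, 96),
                              foreground_bias = 0.5,
                              noise_sigma_aug = 0.02,
                              rotation_range_deg = 15, seed = 1) {
  stopifnot(window_width > 0, all(patch_size >= 8),
            foreground_bias >= 0, foreground_bias <= 1,
            all(target_spacing > 0))
  structure(list(target_orientation = validate_orientation(target_orientation),
                 target_spacing = as.numeric(target_spacing),
                 window_width = window_width, window_level = window_level,
                 patch_size = as.integer(patch_size),
                 foreground_bias = foreground_bias,
                 noise_sigma_aug = noise_sigma_aug,
                 rotation_range_deg = rotation_range_deg,
                 seed = as.integer(seed)),
            class = "PreprocessConfig")
}

#' Reorient a volume to a target axis code
#'
#' Permutes and flips the voxel grid so that the orientation code equals
#' `target`; every voxel keeps its world position (the origin is updated
#' accordingly).  Masks keep their integer labels.
#'
#' @param volume `CTVolume` or `LabelMask`.
#' @param target 3-letter axis code.
#' @return The reoriented object, same class.
#' @export
reorient <- function(volume, target) {
  stopifnot(inherits(volume, "CTVolume"))
  target <- validate_orientation(target)
  src <- strsplit(volume$orientation, "")[[1]]
  tgt <- strsplit(target, "")[[1]]
  axis_of <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  perm <- match(axis_of[tgt], axis_of[src])
  flip <- src[perm] != tgt

  vox <- aperm(volume$voxels, perm)
  spacing <- volume$spacing[perm]
  dims_src <- dim(volume$voxels)
  # world coordinate of the voxel that becomes index (0,0,0)
  idx0 <- rep(0, 3)
  idx0[perm[flip]] <- dims_src[perm[flip]] - 1
  origin <- as.numeric(voxel_to_world(volume, idx0))
  for (a in which(flip)) {
    idx <- rep(list(bquote()), 3)
    idx[[a]] <- rev(seq_len(dim(vox)[a]))
    vox <- do.call(`[`, c(list(vox), idx, drop = FALSE))
  }
  if (is_mask(volume)) label_mask(vox, spacing, target, origin, strict = FALSE)
  else ct_volume(vox, spacing, target, origin)
}

round_half_up <- function(x) floor(x + 0.5)

#' Resample to a target spacing
#'
#' Output dimensions are `round(dims * spacing / target_spacing)` (round
#' half away from zero, minimum 1).  Images are interpolated trilinearly,
#' masks by nearest neighbour (no new label values).  Voxel (0,0,0) centres
#' of input and output grids coincide.
#'
#' @param volume `CTVolume` or `LabelMask`.
#' @param target_spacing mm triple, strictly positive.
#' @return Resampled object, same class.
#' @export
resample <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "CTVolume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stop("target spacing must be 3 strictly positive numbers")
  dims <- dim(volume$voxels)
  odims <- pmax(1L, as.integer(round_half_up(dims * volume$spacing /
                                               target_spacing)))
  scale <- target_spacing / volume$spacing
  out <- cpp_resample3d(as.numeric(volume$voxels), dims, odims, scale,
                        nearest = is_mask(volume))
  if (is_mask(volume))
    label_mask(out, target_spacing, volume$orientation, volume$origin,
               strict = FALSE)
  else ct_volume(out, target_spacing, volume$orientation, volume$origin)
}

#' Abdominal-window intensity normalisation
#'
#' Truncates HU to the window `[level - width/2, level + width/2]` and
#' rescales linearly to \[0, 1\]:
#' `out = clamp((hu - (level - width/2)) / width, 0, 1)`.
#' With the default W = 350 / L = 40, HU below -135 map to 0 and above
#' +215 to 1.
#'
#' @param volume `CTVolume` in HU.
#' @param width window width in HU.
#' @param level window centre in HU.
#' @return `CTVolume` with intensities in \[0, 1\].
#' @export
window_normalize <- function(volume, width = 350, level = 40) {
  stopifnot(inherits(volume, "CTVolume"), width > 0)
  v <- (volume$voxels - (level - width / 2)) / width
  v[v < 0] <- 0; v[v > 1] <- 1
  ct_volume(v, volume$spacing, volume$orientation, volume$origin)
}

#' Full preprocessing chain
#'
#' reorient -> resample -> window-normalize (image only); the mask follows
#' the same geometric steps.  Idempotent once the volume is canonical.
#'
#' @param volume `CTVolume` in HU.
#' @param mask optional aligned `LabelMask`.
#' @param config a [preprocess_config()].
#' @return `list(volume, mask)`.
#' @export
preprocess_volume <- function(volume, mask = NULL,
                              config = preprocess_config()) {
  v <- reorient(volume, config$target_orientation)
  v <- resample(v, config$target_spacing)
  # idempotency: an already window-normalized volume sits in [0,1], a range
  # no HU-valued CT occupies, so windowing is skipped on a second pass
  rng <- range(v$voxels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    v <- window_normalize(v, config$window_width, config$window_level)
  m <- NULL
  if (!is.null(mask)) {
    m <- reorient(mask, config$target_orientation)
    m <- resample(m, config$target_spacing)
  }
  list(volume = v, mask = m)
}

pad_to_size <- function(arr, size, value) {
  dims <- dim(arr)
  if (all(dims >= size)) return(list(arr = arr, offset = c(0L, 0L, 0L)))
  pad_before <- pmax(0L, as.integer(floor((size - dims) / 2)))
  newdims <- pmax(dims, size)
  out <- array(value, dim = newdims)
  out[pad_before[1] + seq_len(dims[1]),
      pad_before[2] + seq_len(dims[2]),
      pad_before[3] + seq_len(dims[3])] <- arr
  list(arr = out, offset = pad_before)
}

#' Sample training patches
#'
#' Randomly crops `n` aligned image/mask patches of `config$patch_size`.
#' A `foreground_bias` fraction is forced to contain at least one gland
#' voxel (the crop is centred near a random foreground voxel).  Volumes
#' smaller than the patch are zero-padded symmetrically (background label
#' for masks).
#'
#' @param volume preprocessed `CTVolume` (intensities in \[0,1\]).
#' @param mask aligned `LabelMask`.
#' @param config a [preprocess_config()].
#' @param n number of patches.
#' @param seed overrides `config$seed` when given.
#' @return list of `PatchPair`s: `list(image, mask, source_id, corner)`
#'   with `corner` the 0-based voxel offset in the (padded) source grid.
#' @export
sample_patches <- function(volume, mask, config = preprocess_config(),
                           n = 1, seed = NULL) {
  stopifnot(n >= 1, all(dim(volume$voxels) == dim(mask$voxels)))
  set.seed(if (is.null(seed)) config$seed else seed)
  ps <- config$patch_size
  pim <- pad_to_size(volume$voxels, ps, 0)
  pmk <- pad_to_size(mask$voxels, ps, 0L)
  dims <- dim(pim$arr)
  fg <- which(pmk$arr > 0, arr.ind = TRUE)
  n_fg <- round(config$foreground_bias * n)
  if (nrow(fg) == 0L && n_fg > 0) {
    warning("mask has no foreground voxels; returning unbiased patches")
    n_fg <- 0L
  }
  lapply(seq_len(n), function(i) {
    if (i <= n_fg) {
      v <- fg[sample.int(nrow(fg), 1), ]
      lo <- pmax(1L, v - ps + 1L)
      hi <- pmin(v, dims - ps + 1L)
      corner <- vapply(1:3, function(a)
        if (lo[a] >= hi[a]) lo[a] else sample(lo[a]:hi[a], 1), integer(1))
    } else {
      corner <- vapply(1:3, function(a)
        if (dims[a] == ps[a]) 1L else sample.int(dims[a] - ps[a] + 1L, 1),
        integer(1))
    }
    img <- pim$arr[corner[1] + seq_len(ps[1]) - 1L,
                   corner[2] + seq_len(ps[2]) - 1L,
                   corner[3] + seq_len(ps[3]) - 1L, drop = FALSE]
    mk <- pmk$arr[corner[1] + seq_len(ps[1]) - 1L,
                  corner[2] + seq_len(ps[2]) - 1L,
                  corner[3] + seq_len(ps[3]) - 1L, drop = FALSE]
    list(image = img, mask = mk, source_id = NA_character_,
         corner = corner - 1L)
  })
}

#' Augment a patch pair
#'
#' Adds Gaussian noise (sd `noise_sigma_aug`, re-clamped to \[0,1\]) and
#' applies one random in-plane rotation about the inferior-superior axis,
#' the same angle for image (trilinear) and mask (nearest neighbour).
#' In-plane only: with anisotropic (1,1,3) spacing, out-of-plane rotation
#' would destroy the thin gland.
#'
#' @param pair a `PatchPair` from [sample_patches()].
#' @param config a [preprocess_config()].
#' @param seed integer; deterministic per seed.
#' @return Augmented `PatchPair`.
#' @export
augment <- function(pair, config = preprocess_config(), seed = 1) {
  set.seed(seed)
  img <- pair$image; mk <- pair$mask
  dims <- dim(img)
  if (config$noise_sigma_aug > 0) {
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sigma_aug),
                       dim = dims)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  if (config$rotation_range_deg > 0) {
    theta <- stats::runif(1, -config$rotation_range_deg,
                          config$rotation_range_deg) * pi / 180
    img <- cpp_rotate_inplane(as.numeric(img), dims, theta, FALSE, 0)
    mk <- array(as.integer(cpp_rotate_inplane(as.numeric(mk), dims, theta,
                                              TRUE, 0)), dim = dims)
  }
  list(image = img, mask = mk, source_id = pair$source_id,
       corner = pair$corner)
}
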