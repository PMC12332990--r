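# Synthetic abdominal CT phantoms with paired adrenal masks and per-side
# AI labels.  A phantom is: an air background, a soft-tissue body ellipsoid,
# a bright spine block at the posterior midline, one bi-lobed (inverted-V)
# gland per side, optional nodule spheres, then additive Gaussian noise.
# The per-side AI label applies the clinical 1 cm rule to the nodule's
# shortest diameter.

AI_DIAMETER_CUTOFF_MM <- 10

#' Specify a synthetic CT phantom
#'
#' All geometry is in mm inside the field of view `dims * spacing`; the grid
#' is generated natively in PLI orientation (axes increase toward Posterior,
#' Left, Inferior).  HU palette defaults: air -1000, body +40, gland +30,
#' spine +300.
#'
#' @param dims grid size, default `c(96, 96, 48)`.
#' @param spacing voxel spacing in mm, default `c(1, 1, 3)`.
#' @param body_hu,gland_hu,spine_hu,air_hu mean intensities (HU).
#' @param gland_geometry optional list with elements `left` and `right`,
#'   each `list(center, lobe_offset, semi_axes)` in mm (see
#'   [default_gland_geometry()]).
#' @param nodule_left,nodule_right `NULL` or `list(diameter, contrast)`:
#'   shortest diameter in mm and added HU contrast over the gland.
#' @param noise_sigma Gaussian acquisition-noise standard deviation (HU).
#' @param seed integer; fully determines the phantom.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(dims = c(96, 96, 48), spacing = c(1, 1, 3),
                         body_hu = 40, gland_hu = 30, spine_hu = 300,
                         air_hu = -1000, gland_geometry = NULL,
                         nodule_left = NULL, nodule_right = NULL,
                         noise_sigma = 5, seed = 1) {
  dims <- as.integer(dims); spacing <- as.numeric(spacing)
  stopifnot(length(dims) == 3L, all(dims >= 8L), all(spacing > 0))
  for (nd in list(nodule_left, nodule_right))
    if (!is.null(nd) && (is.null(nd$diameter) || nd$diameter <= 0))
      stop("nodule shortest diameter must be positive")
  if (is.null(gland_geometry))
    gland_geometry <- default_gland_geometry(dims, spacing)
  structure(list(dims = dims, spacing = spacing, body_hu = body_hu,
                 gland_hu = gland_hu, spine_hu = spine_hu, air_hu = air_hu,
                 gland_geometry = gland_geometry,
                 nodule_left = nodule_left, nodule_right = nodule_right,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Default bi-lobed gland geometry for a given field of view
#'
#' Each gland is the union of two ellipsoidal lobes splayed in the
#' posterior-left plane, giving the thin inverted-V silhouette of an
#' adrenal gland; sizes are fixed in mm, positions are fractions of the
#' field of view (anterior-lateral to the spine).
#'
#' @param dims,spacing phantom grid and spacing.
#' @return list with `left` and `right` geometry.
#' @export
default_gland_geometry <- function(dims, spacing) {
  fov <- dims * spacing
  side_geom <- function(lat_sign) {
    center <- c(0.56, 0.5 + lat_sign * 0.16, 0.5) * fov
    list(center = center,
         lobe_offset = c(2, lat_sign * 3, 0),
         semi_axes = c(3, 5.5, 9))
  }
  list(left = side_geom(+1), right = side_geom(-1))   # axis 2 increases to L
}

# logical array of an ellipsoid support, 0-based voxel centres in mm
ellipsoid_support <- function(dims, spacing, center, semi) {
  u <- lapply(1:3, function(a) {
    (((0:(dims[a] - 1)) * spacing[a] - center[a]) / semi[a])^2
  })
  outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`) <= 1
}

gland_support <- function(dims, spacing, geom) {
  ellipsoid_support(dims, spacing, geom$center + geom$lobe_offset,
                    geom$semi_axes) |
    ellipsoid_support(dims, spacing, geom$center - geom$lobe_offset,
                      geom$semi_axes)
}

#' Generate a synthetic phantom
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume, mask, left_label, right_label)`: the noisy HU
#'   `CTVolume`, the noiseless ground-truth `LabelMask` (1 = left gland,
#'   2 = right gland, nodules included), and the per-side AI labels
#'   (1 iff nodule shortest diameter exceeds 10 mm).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$dims; s <- spec$spacing; fov <- d * s
  hu <- array(spec$air_hu, dim = d)
  body <- ellipsoid_support(d, s, fov / 2, 0.45 * fov)
  hu[body] <- spec$body_hu
  # spine: posterior midline block, full z extent
  spine <- ellipsoid_support(d, s, c(0.70, 0.5, 0.5) * fov,
                             c(0.10 * fov[1], 0.10 * fov[2], 10 * fov[3]))
  hu[spine & body] <- spec$spine_hu

  mask <- array(0L, dim = d)
  labels <- c(left = 0L, right = 0L)
  for (side in c("left", "right")) {
    geom <- spec$gland_geometry[[side]]
    g <- gland_support(d, s, geom)
    if (!all(body[g]))
      stop("gland '", side, "' extends outside the body region")
    nd <- spec[[paste0("nodule_", side)]]
    if (!is.null(nd)) {
      ncenter <- if (is.null(nd$center)) geom$center + c(0, 0, 4) else nd$center
      if (sqrt(sum((ncenter - geom$center)^2)) > sum(geom$semi_axes) + nd$diameter)
        stop("nodule '", side, "' placed outside its gland's neighbourhood")
      nsup <- ellipsoid_support(d, s, ncenter, rep(nd$diameter / 2, 3))
      hu[g] <- spec$gland_hu
      hu[nsup] <- spec$gland_hu + nd$contrast
      g <- g | nsup
      labels[[side]] <- as.integer(nd$diameter > AI_DIAMETER_CUTOFF_MM)
    } else {
      hu[g] <- spec$gland_hu
    }
    mask[g] <- if (side == "left") 1L else 2L
  }

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
  }
  list(volume = ct_volume(hu, s, "PLI"),
       mask = label_mask(mask, s, "PLI"),
       left_label = labels[["left"]], right_label = labels[["right"]])
}

derive_seeds <- function(seed, n, salt = 0L) {
  # documented fan-out: one master seed yields a reproducible seed per item
  set.seed(as.integer(seed) + salt)
  sample.int(.Machine$integer.max %/% 2, n)
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` phantom image/mask NIfTI pairs with randomized gland geometry
#' and nodules, plus a cohort manifest.  AI-positive sides draw nodule
#' shortest diameters from 12-24 mm; AI-negative sides carry either no
#' nodule or a sub-centimetre one (5-8 mm, probability 0.3), so diameters
#' straddle the 10 mm rule but never sit on it.
#'
#' @param n number of phantoms.
#' @param prevalence fraction of records with any AI.
#' @param laterality_weights probabilities of (left-only, right-only,
#'   bilateral) among AI-positive records; default follows the development
#'   cohort mix (about 0.65/0.14/0.21).
#' @param contrast_range HU contrast range for nodules, default `c(20, 60)`.
#' @param dims,spacing phantom grid.
#' @param noise_sigma acquisition noise (HU).
#' @param seed master seed; per-record seeds are derived from it.
#' @param out_dir output directory.
#' @return The cohort manifest data.frame (all records in split "train"
#'   until [split_cohort()] is applied), with attribute `prevalence`.
#' @export
generate_cohort <- function(n, prevalence = 0.5,
                            laterality_weights = c(0.65, 0.14, 0.21),
                            contrast_range = c(20, 60),
                            dims = c(96, 96, 48), spacing = c(1, 1, 3),
                            noise_sigma = 5, seed = 1, out_dir = tempfile()) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            all(laterality_weights >= 0))
  if (prevalence > 0 && n * prevalence < 1)
    warning("n * prevalence < 1; cohort may contain no AI-positive record")
  laterality_weights <- laterality_weights / sum(laterality_weights)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    has_ai <- stats::rbinom(1, 1, prevalence) == 1
    lat <- if (has_ai) sample(c("left", "right", "both"), 1,
                              prob = laterality_weights) else "none"
    # keep nodules inside small fields of view
    dmax <- if (min(dims[1:2] * spacing[1:2]) < 64) 16 else 24
    nodule_for <- function(side) {
      positive <- lat == side || lat == "both"
      if (positive) {
        list(diameter = stats::runif(1, 12, dmax),
             contrast = stats::runif(1, contrast_range[1], contrast_range[2]))
      } else if (stats::runif(1) < 0.3) {
        list(diameter = stats::runif(1, 5, 8),
             contrast = stats::runif(1, contrast_range[1], contrast_range[2]))
      } else NULL
    }
    geom <- default_gland_geometry(dims, spacing)
    for (side in c("left", "right")) {
      geom[[side]]$center <- geom[[side]]$center + stats::runif(3, -2, 2)
      geom[[side]]$semi_axes <- geom[[side]]$semi_axes * stats::runif(3, 0.9, 1.1)
    }
    spec <- phantom_spec(dims = dims, spacing = spacing,
                         gland_geometry = geom,
                         nodule_left = nodule_for("left"),
                         nodule_right = nodule_for("right"),
                         noise_sigma = noise_sigma, seed = seeds[i])
    ph <- generate_phantom(spec)
    id <- sprintf("phantom_%03d", i)
    img <- file.path(out_dir, paste0(id, "_img.nii.gz"))
    msk <- file.path(out_dir, paste0(id, "_msk.nii.gz"))
    save_volume(ph$volume, img)
    save_volume(ph$mask, msk)
    rows[[i]] <- data.frame(id = id, image = img, mask = msk,
                            left_label = ph$left_label,
                            right_label = ph$right_label,
                            split = "train", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "prevalence") <-
    mean(manifest$left_label | manifest$right_label)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Stratified train/validation split
#'
#' Assigns records to train and valid splits with stratified random
#' sampling on AI presence (either side), preserving stratum proportions
#' within one record.
#'
#' @param manifest cohort manifest data.frame.
#' @param ratio length-2 fractions summing to 1, default `c(0.7, 0.3)`.
#' @param seed integer.
#' @return The manifest with the `split` column reassigned.
#' @export
split_cohort <- function(manifest, ratio = c(0.7, 0.3), seed = 1) {
  stopifnot(abs(sum(ratio) - 1) < 1e-9, all(ratio >= 0))
  set.seed(seed)
  strata <- as.integer(manifest$left_label | manifest$right_label)
  manifest$split <- "train"
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warning("stratum ", s, " has fewer than 2 records; assigned to train")
      next
    }
    n_train <- round(length(idx) * ratio[1])
    shuffled <- sample(idx)
    if (n_train < length(idx))
      manifest$split[shuffled[(n_train + 1):length(idx)]] <- "valid"
  }
  manifest
}
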