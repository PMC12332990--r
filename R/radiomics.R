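# Per-gland radiomic features: first-order statistics, 3-D shape, and four
# texture families (gray-level co-occurrence, run-length, size-zone,
# neighbourhood gray-tone difference) computed on the windowed [0,1] image
# with fixed-bin-width discretization, followed by staged feature selection
# (variance filter -> correlation filter -> L1-penalised logistic ranking).

#' Extract per-side gland regions
#'
#' @param volume preprocessed `CTVolume` (windowed intensities).
#' @param mask aligned `LabelMask` (1 = left, 2 = right).
#' @return list of `GlandRegion`s (one per present side): side, 0-based
#'   voxel indices, intensities, spacing, volume in mm^3 and bounding box.
#'   Absent sides are omitted with a message; an empty mask returns an
#'   empty list with a warning.
#' @export
extract_gland_regions <- function(volume, mask) {
  stopifnot(inherits(volume, "CTVolume"), is_mask(mask),
            all(dim(volume$voxels) == dim(mask$voxels)))
  if (!any(mask$voxels > 0L)) {
    warning("empty mask: no gland regions")
    return(list())
  }
  out <- list()
  for (side in c("left", "right")) {
    lab <- if (side == "left") 1L else 2L
    sel <- mask$voxels == lab
    if (!any(sel)) {
      message("side '", side, "' absent from mask; omitted")
      next
    }
    idx <- which(sel, arr.ind = TRUE) - 1L
    out[[side]] <- structure(
      list(side = side, idx = idx,
           intensities = volume$voxels[sel],
           spacing = volume$spacing,
           volume_mm3 = nrow(idx) * prod(volume$spacing),
           bbox = apply(idx, 2, range)),
      class = "GlandRegion")
  }
  out
}

# dense level crop of a region: 0 outside the region, 1..G inside
region_level_crop <- function(region, bin_width) {
  lev <- pmax(1L, as.integer(floor(region$intensities / bin_width)) + 1L)
  b <- region$bbox
  dims <- b[2, ] - b[1, ] + 1L
  crop <- array(0L, dims)
  local_idx <- sweep(region$idx, 2, b[1, ]) + 1L
  crop[local_idx] <- lev
  crop
}

skewness <- function(x) {
  s <- stats::sd(x); if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
kurtosis <- function(x) {
  s <- stats::sd(x); if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

first_order_features <- function(x, bin_width) {
  lev <- pmax(1L, as.integer(floor(x / bin_width)) + 1L)
  p <- tabulate(lev); p <- p[p > 0] / length(lev)
  c(fo_mean = mean(x), fo_median = stats::median(x), fo_min = min(x),
    fo_max = max(x), fo_range = diff(range(x)), fo_variance = stats::var(x) *
      (length(x) - 1) / length(x),
    fo_sd = stats::sd(x), fo_skewness = skewness(x), fo_kurtosis = kurtosis(x),
    fo_energy = sum(x^2), fo_rms = sqrt(mean(x^2)),
    fo_entropy = -sum(p * log2(p)), fo_uniformity = sum(p^2),
    fo_p10 = unname(stats::quantile(x, 0.1)),
    fo_p90 = unname(stats::quantile(x, 0.9)),
    fo_iqr = unname(diff(stats::quantile(x, c(0.25, 0.75)))),
    fo_mad = mean(abs(x - mean(x))))
}

shape_features <- function(region) {
  sp <- region$spacing
  idx <- region$idx
  n <- nrow(idx)
  vol <- n * prod(sp)
  # exposed faces, spacing-aware
  b <- region$bbox
  dims <- b[2, ] - b[1, ] + 1L
  occ <- array(FALSE, dims)
  occ[sweep(idx, 2, b[1, ]) + 1L] <- TRUE
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  pad <- array(FALSE, dims + 2L)
  pad[1 + seq_len(dims[1]), 1 + seq_len(dims[2]), 1 + seq_len(dims[3])] <- occ
  exposed <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[1 + s[1] + seq_len(dims[1]),
              1 + s[2] + seq_len(dims[2]),
              1 + s[3] + seq_len(dims[3])]
    exposed <- exposed + sum(occ & !nb) * face_area[which(s != 0)]
  }
  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / exposed
  # principal axes of the voxel cloud in mm
  pts <- sweep(idx, 2, sp, `*`)
  ext <- (b[2, ] - b[1, ] + 1L) * sp
  if (n >= 3) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  } else {
    elong <- flat <- 0
  }
  # max 3-D diameter from (subsampled) boundary points
  bpts <- pts
  if (nrow(bpts) > 400) {
    keep <- round(seq(1, nrow(bpts), length.out = 400))
    bpts <- bpts[keep, , drop = FALSE]
  }
  maxdiam <- if (nrow(bpts) > 1) max(stats::dist(bpts)) else 0
  c(shape_volume_mm3 = vol, shape_surface_mm2 = exposed,
    shape_surface_to_volume = exposed / vol, shape_sphericity = sphericity,
    shape_max_diameter_mm = maxdiam, shape_elongation = elong,
    shape_flatness = flat,
    shape_extent_x_mm = ext[1], shape_extent_y_mm = ext[2],
    shape_extent_z_mm = ext[3])
}

.texture_dirs <- local({
  d <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    if (any(vapply(d, function(u) all(u == -v), logical(1)))) next
    d[[length(d) + 1L]] <- v
  }
  d   # 13 unique 3-D directions (half-space)
})

shift_pairs <- function(crop, off) {
  d <- dim(crop)
  rx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
  ry <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
  rz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
  a <- crop[rx - off[1], ry - off[2], rz - off[3], drop = FALSE]
  b <- crop[rx, ry, rz, drop = FALSE]
  keep <- a > 0L & b > 0L
  cbind(a[keep], b[keep])
}

glcm_features <- function(crop, G) {
  M <- matrix(0, G, G)
  for (off in .texture_dirs) {
    pr <- shift_pairs(crop, off)
    if (nrow(pr)) {
      tab <- table(factor(pr[, 1], levels = 1:G), factor(pr[, 2], levels = 1:G))
      M <- M + tab + t(tab)    # symmetric accumulation
    }
  }
  if (sum(M) == 0) M[1, 1] <- 1
  P <- M / sum(M)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0) sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
          else 1
  nz <- P[P > 0]
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = -sum(nz * log2(nz)),
    glcm_correlation = corr)
}

glrlm_features <- function(crop, G) {
  d <- dim(crop)
  runs <- list()
  idx_all <- which(crop > 0L, arr.ind = TRUE)
  for (off in .texture_dirs) {
    # run starts: in-region voxels whose predecessor along -off differs
    prev <- idx_all - matrix(off, nrow(idx_all), 3, byrow = TRUE)
    inside <- prev[, 1] >= 1 & prev[, 1] <= d[1] &
      prev[, 2] >= 1 & prev[, 2] <= d[2] &
      prev[, 3] >= 1 & prev[, 3] <= d[3]
    same <- rep(FALSE, nrow(idx_all))
    if (any(inside))
      same[inside] <- crop[prev[inside, , drop = FALSE]] ==
        crop[idx_all[inside, , drop = FALSE]] &
        crop[prev[inside, , drop = FALSE]] > 0L
    starts <- idx_all[!same, , drop = FALSE]
    for (r in seq_len(nrow(starts))) {
      pos <- starts[r, ]
      g <- crop[matrix(pos, 1)]
      len <- 1L
      repeat {
        nxt <- pos + off
        if (any(nxt < 1) || any(nxt > d) || crop[matrix(nxt, 1)] != g) break
        len <- len + 1L
        pos <- nxt
      }
      runs[[length(runs) + 1L]] <- c(g, len)
    }
  }
  rm_ <- do.call(rbind, runs)
  Nr <- nrow(rm_)
  gl <- rm_[, 1]; rl <- rm_[, 2]
  Nvox <- sum(crop > 0L) * length(.texture_dirs)
  gln <- sum(tapply(rep(1, Nr), gl, sum)^2) / Nr
  rln <- sum(tapply(rep(1, Nr), rl, sum)^2) / Nr
  c(glrlm_sre = mean(1 / rl^2), glrlm_lre = mean(rl^2),
    glrlm_gln = gln, glrlm_rln = rln, glrlm_rp = Nr / Nvox,
    glrlm_lglre = mean(1 / gl^2), glrlm_hglre = mean(gl^2))
}

glszm_features <- function(crop, G) {
  d <- dim(crop)
  zones <- list()
  for (g in sort(unique(crop[crop > 0L]))) {
    cc <- cpp_cc_label(crop == g, d, 26L)
    if (max(cc) > 0)
      for (z in tabulate(cc[cc > 0L]))
        zones[[length(zones) + 1L]] <- c(g, z)
  }
  zm <- do.call(rbind, zones)
  Nz <- nrow(zm)
  gl <- zm[, 1]; sz <- zm[, 2]
  Nvox <- sum(crop > 0L)
  c(glszm_sae = mean(1 / sz^2), glszm_lae = mean(sz^2),
    glszm_gln = sum(tapply(rep(1, Nz), gl, sum)^2) / Nz,
    glszm_szn = sum(tapply(rep(1, Nz), sz, sum)^2) / Nz,
    glszm_zp = Nz / Nvox,
    glszm_lglze = mean(1 / gl^2), glszm_hglze = mean(gl^2))
}

ngtdm_features <- function(crop, G) {
  d <- dim(crop)
  inreg <- crop > 0L
  nsum <- array(0, d); ncnt <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    rx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ry <- max(1, 1 + dy):min(d[2], d[2] + dy)
    rz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    src <- crop[rx - dx, ry - dy, rz - dz, drop = FALSE]
    srcin <- src > 0L
    nsum[rx, ry, rz] <- nsum[rx, ry, rz] + src * srcin
    ncnt[rx, ry, rz] <- ncnt[rx, ry, rz] + srcin
  }
  has_nb <- inreg & ncnt > 0
  N <- sum(has_nb)
  gi <- crop[has_nb]
  abar <- nsum[has_nb] / ncnt[has_nb]
  levs <- sort(unique(gi))
  s <- vapply(levs, function(g) sum(abs(g - abar[gi == g])), numeric(1))
  p <- vapply(levs, function(g) sum(gi == g), numeric(1)) / N
  Ngp <- length(levs)
  eps <- 1e-12
  coars <- 1 / (sum(p * s) + eps)
  if (Ngp > 1) {
    pij <- outer(p, p); dij <- outer(levs, levs, `-`)
    contr <- (sum(pij * dij^2) / (Ngp * (Ngp - 1))) * (sum(s) / N)
    busy <- sum(p * s) / (sum(abs(outer(levs * p, levs * p, `-`))) + eps)
    num_c <- 0
    for (a in seq_len(Ngp)) for (b in seq_len(Ngp))
      num_c <- num_c + abs(levs[a] - levs[b]) *
        (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    complexity <- num_c / N
    strength <- sum(outer(p, p, `+`) * dij^2) / (sum(s) + eps)
  } else {
    contr <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coars, ngtdm_contrast = contr, ngtdm_busyness = busy,
    ngtdm_complexity = complexity, ngtdm_strength = strength)
}

#' Extract radiomic features from a gland region
#'
#' Deterministic vector over six families (first-order, shape, GLCM,
#' GLRLM, GLSZM, NGTDM).  Intensity features use fixed-bin-width
#' discretization (default 0.04 on the windowed \[0,1\] scale, about 14 HU),
#' shape features are spacing-aware, and texture matrices aggregate the 13
#' unique 3-D directions symmetrically, so features are invariant to
#' translation and left-right mirroring.  Regions with fewer than 2 voxels
#' get `NA` texture features (first-order and shape are still computed).
#'
#' @param region a `GlandRegion` from [extract_gland_regions()].
#' @param bin_width intensity bin width on the windowed scale.
#' @return named numeric feature vector.
#' @export
extract_features <- function(region, bin_width = 0.04) {
  stopifnot(inherits(region, "GlandRegion"), nrow(region$idx) >= 1)
  fo <- first_order_features(region$intensities, bin_width)
  sh <- shape_features(region)
  crop <- region_level_crop(region, bin_width)
  G <- max(crop)
  if (nrow(region$idx) < 2L) {
    tex <- setNames(rep(NA_real_, 25),
                    c(names(glcm_features(array(1L, c(2, 1, 1)), 1)),
                      names(glrlm_features(array(1L, c(2, 1, 1)), 1)),
                      names(glszm_features(array(1L, c(2, 1, 1)), 1)),
                      names(ngtdm_features(array(1L, c(2, 1, 1)), 1))))
    return(c(fo, sh, tex))
  }
  c(fo, sh, glcm_features(crop, G), glrlm_features(crop, G),
    glszm_features(crop, G), ngtdm_features(crop, G))
}

#' Build a per-side feature table for a cohort
#'
#' Runs [extract_gland_regions()] + [extract_features()] for every
#' manifest record, using either the ground-truth masks (`mask_source =
#' "manifest"`) or a parallel named vector of predicted mask paths.
#'
#' @param manifest cohort manifest data.frame.
#' @param mask_paths optional named character vector (names = patient ids)
#'   overriding the manifest mask paths.
#' @param pre_config a [preprocess_config()] applied to each image/mask.
#' @param bin_width passed to [extract_features()].
#' @return A `FeatureTable` data.frame: id, side, label, split, then one
#'   column per feature.
#' @export
build_feature_table <- function(manifest, mask_paths = NULL,
                                pre_config = preprocess_config(),
                                bin_width = 0.04) {
  rows <- list()
  for (r in seq_len(nrow(manifest))) {
    rec <- manifest[r, ]
    vol <- load_volume(rec$image)
    mpath <- if (is.null(mask_paths)) rec$mask else mask_paths[[rec$id]]
    msk <- load_volume(mpath, as_mask = TRUE, strict_labels = FALSE)
    pp <- preprocess_volume(vol, msk, pre_config)
    regions <- suppressMessages(extract_gland_regions(pp$volume, pp$mask))
    for (side in names(regions)) {
      fv <- extract_features(regions[[side]], bin_width)
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, side = side,
        label = if (side == "left") rec$left_label else rec$right_label,
        split = rec$split, t(fv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("FeatureTable", "data.frame")
  out
}

feature_columns <- function(table)
  setdiff(names(table), c("id", "side", "label", "split"))

#' Staged feature selection
#'
#' Three stages on the requested side's rows: (1) drop near-zero-variance
#' columns; (2) among pairs with absolute Pearson correlation above
#' `cor_threshold`, drop the later column (first occurrence kept); (3)
#' L1-penalised logistic regression on standardized features -- the
#' selected set is the support of the smallest-penalty model with at most
#' `cap` nonzero coefficients along the glmnet path.
#'
#' @param table a `FeatureTable`.
#' @param side `"left"` or `"right"`.
#' @param cap maximum number of selected features.
#' @param var_threshold minimum variance kept by stage 1.
#' @param cor_threshold correlation-filter threshold.
#' @param split restrict to rows of this split (`NULL` = all rows).
#' @return A `FeatureSelection`: list(side, selected, trace) where trace
#'   records surviving counts per stage.
#' @export
select_features <- function(table, side = c("left", "right"), cap = 24,
                            var_threshold = 1e-8, cor_threshold = 0.95,
                            split = NULL) {
  side <- match.arg(side)
  rows <- table[table$side == side, ]
  if (!is.null(split)) rows <- rows[rows$split %in% split, ]
  y <- rows$label
  if (length(unique(y)) < 2L)
    stop("side '", side, "' has a single class; cannot select features")
  X <- as.matrix(rows[, feature_columns(table)])
  X[!is.finite(X)] <- 0
  trace <- c(input = ncol(X))
  keep <- apply(X, 2, stats::var) > var_threshold
  X <- X[, keep, drop = FALSE]
  trace <- c(trace, variance = ncol(X))
  if (ncol(X) > 1) {
    cm <- abs(stats::cor(X))
    drop <- rep(FALSE, ncol(X))
    for (j in seq_len(ncol(X) - 1)) {
      if (drop[j]) next
      later <- (j + 1):ncol(X)
      drop[later][cm[j, later] > cor_threshold & !drop[later]] <- TRUE
    }
    X <- X[, !drop, drop = FALSE]
  }
  trace <- c(trace, correlation = ncol(X))
  fit <- glmnet::glmnet(scale(X), y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  nz <- fit$df
  ok <- which(nz <= cap & nz > 0)
  if (length(ok)) {
    lam_idx <- ok[which.max(nz[ok])]   # densest model within the cap
    beta <- as.matrix(fit$beta)[, lam_idx]
    selected <- names(beta)[beta != 0]
    selected <- selected[order(-abs(beta[selected]))]
  } else {
    selected <- utils::head(colnames(X), cap)
  }
  trace <- c(trace, l1 = length(selected))
  structure(list(side = side, selected = selected, trace = trace),
            class = "FeatureSelection")
}
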