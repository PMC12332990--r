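#' @useDynLib adrenalseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile sd var cor median rnorm runif rbinom predict
#'   binomial glm coef pnorm qnorm setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- containers -------------------------------------------------------------

# Letters name the patient-space direction in which each grid index
# increases, under the NIfTI RAS+ world convention:
#   R = +x, L = -x, A = +y, P = -y, S = +z, I = -z.
.axis_dirs <- list(
  R = c(1, 0, 0), L = c(-1, 0, 0),
  A = c(0, 1, 0), P = c(0, -1, 0),
  S = c(0, 0, 1), I = c(0, 0, -1)
)

validate_orientation <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("orientation code must be a 3-letter string, got: ",
         deparse(code), call. = FALSE)
  letters3 <- strsplit(toupper(code), "")[[1]]
  groups <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  if (!all(letters3 %in% names(groups)) ||
      length(unique(groups[letters3])) != 3L)
    stop("orientation code must use one letter from each of {R,L}, {A,P}, ",
         "{S,I}; got '", code, "'", call. = FALSE)
  paste(letters3, collapse = "")
}

orientation_dirs <- function(code) {
  code <- validate_orientation(code)
  letters3 <- strsplit(code, "")[[1]]
  m <- vapply(letters3, function(l) .axis_dirs[[l]], numeric(3))
  unname(m) # 3x3, column j = world direction of grid axis j
}

#' Construct a CT volume
#'
#' A `CTVolume` is a 3-D scalar grid (Hounsfield units, or normalized
#' \[0,1\] after windowing) with voxel spacing in mm, a 3-letter orientation
#' code giving the patient-space direction of each grid axis (RAS+ world
#' convention), and the world coordinates of voxel (0,0,0).  Voxel indices
#' are 0-based in all world-coordinate computations.
#'
#' @param voxels 3-D numeric array.
#' @param spacing numeric length-3, mm per voxel, all positive.
#' @param orientation 3-letter axis code, e.g. `"PLI"`.
#' @param origin world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `CTVolume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), orientation = "PLI",
                      origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(dim(voxels) < 1L)) stop("grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  structure(
    list(voxels = voxels, spacing = spacing,
         orientation = validate_orientation(orientation),
         origin = as.numeric(origin)),
    class = "CTVolume"
  )
}

#' Construct a label mask
#'
#' A `LabelMask` is a 3-D integer grid aligned to a [ct_volume()]:
#' 0 = background, 1 = left adrenal, 2 = right adrenal.
#'
#' @inheritParams ct_volume
#' @param strict enforce values in \{0,1,2\}.
#' @return An object of class `LabelMask`.
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1), orientation = "PLI",
                       origin = c(0, 0, 0), strict = TRUE) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  v <- as.numeric(voxels)
  if (any(abs(v - round(v)) > 1e-6)) {
    bad <- unique(v[abs(v - round(v)) > 1e-6])
    stop("mask contains non-integer values: ",
         paste(utils::head(signif(bad, 6), 5), collapse = ", "))
  }
  iv <- array(as.integer(round(v)), dim = dim(voxels))
  if (strict && !all(iv %in% 0:2)) {
    bad <- setdiff(unique(as.vector(iv)), 0:2)
    stop("mask labels outside {0,1,2}: ", paste(bad, collapse = ", "))
  }
  obj <- ct_volume(iv, spacing, orientation, origin)
  class(obj) <- c("LabelMask", "CTVolume")
  obj
}

is_mask <- function(x) inherits(x, "LabelMask")

#' @export
print.CTVolume <- function(x, ...) {
  cat(sprintf("<%s> %s  spacing %s mm  orientation %s  range [%g, %g]\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ","), x$orientation,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# 3x4 voxel->world affine (RAS+), 0-based indices.
volume_affine <- function(vol) {
  d <- orientation_dirs(vol$orientation)
  cbind(sweep(d, 2, vol$spacing, `*`), vol$origin)
}

# World coordinate of 0-based voxel index (vectorised: idx is n x 3).
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  aff <- volume_affine(vol)
  t(aff[, 1:3] %*% t(idx) + aff[, 4])
}

# Orientation code from a 3x3 direction matrix (columns snap to the
# dominant axis; oblique affines are rejected rather than silently fixed).
orientation_from_matrix <- function(m) {
  letters_pos <- c("R", "A", "S"); letters_neg <- c("L", "P", "I")
  code <- character(3)
  axes <- integer(3)
  for (j in 1:3) {
    k <- which.max(abs(m[, j]))
    axes[j] <- k
    code[j] <- if (m[k, j] >= 0) letters_pos[k] else letters_neg[k]
  }
  if (length(unique(axes)) != 3L)
    stop("affine is not axis-aligned; cannot derive an orientation code")
  paste(code, collapse = "")
}

# ---- NIfTI-1 ----------------------------------------------------------------

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "numeric", size = 4, signed = TRUE),
  `64`  = list(what = "numeric", size = 8, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Load a NIfTI volume or mask
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`, little-endian).  The affine is
#' taken from the sform when `sform_code > 0`, otherwise from `pixdim` with
#' an identity rotation; the orientation code is always derived from the
#' affine, never trusted from free-text header fields.
#'
#' @param path file to read.
#' @param as_mask return a [label_mask()]; values must be integral.
#' @param strict_labels with `as_mask`, require labels in \{0,1,2\}.
#' @return A `CTVolume` or `LabelMask`.
#' @export
load_volume <- function(path, as_mask = FALSE, strict_labels = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", hdr_size, "): ", path)
  readBin(con, "raw", 36)                                    # unused fields
  dim8 <- readBin(con, "integer", 8, size = 2, endian = "little")
  readBin(con, "raw", 14)                                    # intent_p*, intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 4)                                     # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = "little")
  readBin(con, "raw", 134)                                   # through qform_code
  sform_code <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "numeric", 6, size = 4, endian = "little")    # quaternion
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = "little"),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic in ", path)
  if (dim8[1] < 3) stop("expected a 3-D NIfTI volume, got dim[0] = ", dim8[1])
  dims <- dim8[2:4]

  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  readBin(con, "raw", max(0, round(vox_offset) - 348))
  n <- prod(dims) * max(1, prod(pmax(dim8[5:8][seq_len(dim8[1] - 3)], 1)))
  raw_vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                      endian = "little")
  vals <- as.numeric(raw_vals[seq_len(prod(dims))])
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  if (sform_code > 0) {
    rot <- srow[, 1:3]
    spacing <- sqrt(colSums(rot^2))
    if (any(spacing <= 0)) stop("degenerate sform in ", path)
    dirm <- sweep(rot, 2, spacing, `/`)
    orientation <- orientation_from_matrix(dirm)
    origin <- srow[, 4]
  } else {
    spacing <- ifelse(pixdim[2:4] > 0, pixdim[2:4], 1)
    orientation <- "RAS"
    origin <- c(0, 0, 0)
  }
  vox <- array(vals, dim = dims)
  if (as_mask) {
    nonint <- abs(vals - round(vals)) > 1e-4
    if (any(nonint))
      stop("mask file contains non-integer values: ",
           paste(utils::head(signif(unique(vals[nonint]), 6), 5),
                 collapse = ", "))
    label_mask(vox, spacing, orientation, origin, strict = strict_labels)
  } else {
    ct_volume(vox, spacing, orientation, origin)
  }
}

#' Save a volume or mask as NIfTI-1
#'
#' Writes single-file NIfTI-1 with the affine encoded in the sform (code 1).
#' Images are stored as float64, masks as int16.
#'
#' @param volume a `CTVolume` or `LabelMask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param create_parents create missing parent directories.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, create_parents = TRUE) {
  stopifnot(inherits(volume, "CTVolume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    if (!create_parents) stop("directory does not exist: ", dir)
    dir.create(dir, recursive = TRUE)
  }
  mask <- is_mask(volume)
  dims <- dim(volume$voxels)
  aff <- volume_affine(volume)

  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)
  writeBin(raw(36), con)
  wi(c(3, dims, 1, 1, 1, 1), 2)                 # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                      # intent
  wi(if (mask) 4 else 64, 2)                    # datatype (int16 / float64)
  wi(if (mask) 16 else 64, 2)                   # bitpix
  wi(0, 2)                                      # slice_start
  wf(c(1, volume$spacing, 0, 0, 0, 0))          # pixdim (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope / inter
  wi(0, 2); writeBin(as.raw(c(0, 10)), con)     # slice_end/code, units mm+s
  wf(c(0, 0, 0, 0)); wi(c(0, 0), 4)             # cal/slice_duration/gl*
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0, 1), 2)                                # qform 0, sform 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternion
  wf(t(aff))                                    # srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # no extensions
  if (mask) {
    writeBin(as.integer(volume$voxels), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(volume$voxels), con, size = 8, endian = "little")
  }
  invisible(path)
}

# ---- cohort manifest --------------------------------------------------------

#' Read / write a cohort manifest
#'
#' A manifest is a delimited text table with one row per patient:
#' `id, image, mask, left_label, right_label, split`.
#'
#' @param path file path.
#' @return `read_manifest` returns a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "mask", "left_label", "right_label", "split")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
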