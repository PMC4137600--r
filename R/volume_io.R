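# Shared spatial data model: a PhaseVolume is one 3D scalar image in
# Hounsfield units on a regular anisotropic grid; a Series4D is an ordered
# set of PhaseVolumes (one per breathing phase) on an identical grid; a
# BinaryMask is a logical voxel set on the same grid.
#
# Coordinate convention used throughout the package: arrays are indexed
# [x, y, z] (z = slice axis); the physical position of the voxel at 1-based
# index (i, j, k) is origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz), i.e. the
# node-at-voxel-center convention with 0-based offsets.

PHASE_LABELS <- seq(0L, 90L, 10L)

#' Construct a single-phase 3D volume
#'
#' A `phase_volume` holds one 3D scalar image in Hounsfield units (HU)
#' together with its voxel spacing and physical origin, and optionally the
#' breathing-phase label (percentage of the respiratory cycle) when the
#' volume is part of a 4D series.
#'
#' @param voxels Numeric 3D array of intensities in HU, indexed `[x, y, z]`
#'   with `z` the slice axis.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm/voxel; all
#'   components must be strictly positive.
#' @param origin Numeric length-3 vector, physical position (mm) of the
#'   voxel at index `(1, 1, 1)`.
#' @param phase_label Optional breathing-phase percentage, one of
#'   0, 10, ..., 90.
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         phase_label = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values (mm/voxel)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  if (!is.null(phase_label)) {
    phase_label <- as.integer(phase_label)
    if (!phase_label %in% PHASE_LABELS)
      stop("'phase_label' must be one of 0, 10, ..., 90")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         phase_label = phase_label),
    class = "phase_volume")
}

#' Construct a 4D series from per-phase volumes
#'
#' All phases must share identical array dimensions and voxel spacing, and
#' phase labels must be strictly increasing. Volumes without labels are
#' assigned 0, 10, ..., 90 in order.
#'
#' @param phases List of [phase_volume] objects, one per breathing phase.
#' @return An object of class `series_4d`.
#' @export
series_4d <- function(phases) {
  if (!length(phases)) stop("'phases' must be a non-empty list")
  if (!all(vapply(phases, inherits, logical(1), "phase_volume")))
    stop("all elements of 'phases' must be phase_volume objects")
  d1 <- dim(phases[[1L]]$voxels); s1 <- phases[[1L]]$spacing
  for (p in phases) {
    if (!identical(dim(p$voxels), d1))
      stop("all phases must have identical array dimensions")
    if (max(abs(p$spacing - s1)) > 1e-9)
      stop("all phases must have identical voxel spacing")
  }
  labs <- vapply(phases, function(p) {
    if (is.null(p$phase_label)) NA_integer_ else p$phase_label
  }, integer(1))
  if (anyNA(labs)) {
    if (length(phases) > length(PHASE_LABELS))
      stop("more than 10 unlabeled phases")
    labs <- PHASE_LABELS[seq_along(phases)]
    for (i in seq_along(phases)) phases[[i]]$phase_label <- labs[i]
  }
  if (any(diff(labs) <= 0)) stop("phase labels must be strictly increasing")
  structure(list(phases = phases), class = "series_4d")
}

#' Construct a binary voxel mask
#'
#' @param voxels Logical 3D array aligned to a [phase_volume] grid.
#' @param spacing,origin Grid metadata as in [phase_volume].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (anyNA(voxels)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' Mask volume in cubic centimetres
#'
#' `volume_cc(mask)` is the number of true voxels times the voxel volume
#' `dx*dy*dz / 1000`.
#'
#' @param mask A [binary_mask].
#' @return Volume in cc (ml).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<phase_volume> %dx%dx%d voxels, spacing (%g, %g, %g) mm",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$phase_label)) cat(sprintf(", phase %d%%", x$phase_label))
  cat(sprintf(", HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %dx%dx%d voxels, %d foreground (%.3f cc)\n",
              d[1], d[2], d[3], sum(x$voxels), volume_cc(x)))
  invisible(x)
}

#' @export
print.series_4d <- function(x, ...) {
  labs <- vapply(x$phases, `[[`, integer(1), "phase_label")
  cat(sprintf("<series_4d> %d phases (%s%%), grid %s\n", length(x$phases),
              paste(labs, collapse = ","),
              paste(dim(x$phases[[1]]$voxels), collapse = "x")))
  invisible(x)
}

# Physical positions (mm) of the true voxels of a logical array.
voxel_positions_mm <- function(voxels, spacing, origin) {
  idx <- which(voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  dimnames(idx) <- NULL
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

#' Read a single-phase volume from disk
#'
#' Reads either one NIfTI file (`.nii` / `.nii.gz`) or a directory of DICOM
#' slices forming one 3D volume. Intensities are returned in HU: for DICOM,
#' the rescale slope/intercept from the file metadata are applied. Arrays
#' are returned in `[x, y, z]` order with `z` the slice axis; no spatial
#' reorientation is performed (axes are taken as stored).
#'
#' @param path Path to a NIfTI file or a DICOM directory.
#' @param format One of `"auto"`, `"nifti"`, `"dicom"`; `"auto"` picks
#'   DICOM for a directory and NIfTI otherwise.
#' @param phase_label Optional breathing-phase percentage for the volume.
#' @return A [phase_volume].
#' @export
read_phase_volume <- function(path, format = c("auto", "nifti", "dicom"),
                              phase_label = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") {
    return(read_dicom_series(path, phase_label = phase_label))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti image attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("not a 3D volume: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (any(!is.finite(origin))) origin <- c(0, 0, 0)
  phase_volume(arr, spacing = spacing, origin = origin,
               phase_label = phase_label)
}

#' Read a directory of per-phase NIfTI volumes as a 4D series
#'
#' Files are matched by the glob `*.nii*`; the phase label is parsed from
#' the last number in each file name (e.g. `phase_40.nii.gz` is the 40%
#' phase); files without a number are labeled 0, 10, ... in sorted order.
#'
#' @param dir Directory containing one NIfTI file per phase.
#' @param pattern Optional regular expression applied to base names to
#'   select the phase files (e.g. `"^phase_"` when the directory also
#'   holds mask files).
#' @return A [series_4d].
#' @export
read_series <- function(dir, pattern = NULL) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!is.null(pattern)) files <- files[grepl(pattern, basename(files))]
  if (!length(files)) stop("no NIfTI files found in ", dir)
  labs <- suppressWarnings(vapply(files, function(f) {
    m <- regmatches(basename(f), gregexpr("[0-9]+", basename(f)))[[1]]
    if (length(m)) as.integer(m[length(m)]) else NA_integer_
  }, integer(1)))
  if (anyNA(labs) || anyDuplicated(labs)) labs <- rep(NA_integer_,
                                                      length(files))
  ord <- if (anyNA(labs)) seq_along(files) else order(labs)
  phases <- lapply(seq_along(ord), function(i) {
    f <- files[ord[i]]
    lab <- if (anyNA(labs)) NULL else labs[ord[i]]
    read_phase_volume(f, "nifti", phase_label = lab)
  })
  series_4d(phases)
}

as_nifti_image <- function(arr, spacing, origin) {
  attr(arr, "pixdim") <- spacing
  img <- RNifti::asNifti(arr)
  xfm <- diag(4)
  diag(xfm)[1:3] <- spacing
  xfm[1:3, 4] <- origin
  RNifti::qform(img) <- structure(xfm, code = 2L)
  RNifti::sform(img) <- structure(xfm, code = 2L)
  img
}

#' Write a binary mask to NIfTI
#'
#' Masks are stored as integer values in `{0, 1}` with the grid metadata
#' of the mask; a write/read round trip reproduces the mask exactly.
#'
#' @param mask A [binary_mask].
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  img <- as_nifti_image(arr, mask$spacing, mask$origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel is foreground.
#'
#' @param path NIfTI file path.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_phase_volume(path, "nifti")
  binary_mask(v$voxels != 0, spacing = v$spacing, origin = v$origin)
}

#' Write a phase volume to NIfTI
#'
#' @param vol A [phase_volume].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_volume <- function(vol, path) {
  stopifnot(inherits(vol, "phase_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- as_nifti_image(vol$voxels, vol$spacing, vol$origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a COG/volume trajectory to CSV
#'
#' The file has the fixed header
#' `phase,cog_x_mm,cog_y_mm,cog_z_mm,volume_cc` and one row per phase.
#'
#' @param traj A `trajectory` (see [compute_trajectory]) or a data frame
#'   with those five columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  need <- c("phase", "cog_x_mm", "cog_y_mm", "cog_z_mm", "volume_cc")
  if (!all(need %in% names(df))) stop("trajectory is missing columns")
  if (nrow(df) == 0L) stop("trajectory is empty")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory]
#'
#' @param path CSV path.
#' @return A `trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("phase", "cog_x_mm", "cog_y_mm", "cog_z_mm", "volume_cc")
  if (!all(need %in% names(df))) stop("not a trajectory CSV: ", path)
  structure(df[need], class = c("trajectory", "data.frame"))
}
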