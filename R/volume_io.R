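#' 3D MR angiography volume
#'
#' Container for a 3D time-of-flight MRA intensity grid together with the
#' geometric metadata the pipeline needs: which array axis runs
#' cranio-caudally, whether slice index increases from the brachiocephalic
#' branch towards the carotid bifurcation, and the voxel size in mm.
#'
#' @param voxels 3D numeric array of non-negative, finite intensities.
#' @param slice_axis Integer in 1:3; the array axis that runs cranio-caudally.
#' @param slice_direction `+1` if slice index increases from the
#'   brachiocephalic branch towards the bifurcation, `-1` otherwise.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param meta Named list of scan annotations (`animal_id`, `side`
#'   (`"RCCA"`/`"LCCA"`), `contrast` (`"pre"`/`"post"`), `probe`,
#'   `treatment`, `week`). Free-form; carried along unmodified.
#'
#' @return An object of class `mra_volume`.
#' @export
mra_volume <- function(voxels, slice_axis = 3L, slice_direction = 1L,
                       voxel_size = c(1, 1, 1), meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("all intensities must be finite", call. = FALSE)
  if (any(voxels < 0))
    stop("all intensities must be >= 0", call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3)
    stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  if (dim(voxels)[slice_axis] < 2L)
    stop("volume must have at least 2 slices along the slice axis",
         call. = FALSE)
  if (!slice_direction %in% c(-1L, 1L))
    stop("`slice_direction` must be +1 or -1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers", call. = FALSE)
  structure(
    list(voxels = voxels, slice_axis = slice_axis,
         slice_direction = as.integer(slice_direction),
         voxel_size = voxel_size, meta = meta),
    class = "mra_volume"
  )
}

#' @export
print.mra_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mra_volume> %d x %d x %d, slice axis %d (direction %+d)\n",
              d[1], d[2], d[3], x$slice_axis, x$slice_direction))
  cat(sprintf("  voxel size: %s mm; intensity range [%.3g, %.3g]\n",
              paste(signif(x$voxel_size, 3), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of cranio-caudal slices in a volume
#' @param vol An [mra_volume()].
#' @return Integer slice count along the slice axis.
#' @export
n_slices <- function(vol) {
  stopifnot(inherits(vol, "mra_volume"))
  dim(vol$voxels)[vol$slice_axis]
}

#' Anatomical landmark slice indices
#'
#' Four ordered slice indices (0-based, along the cranio-caudal axis)
#' delimiting the carotid extent and the shear-modifying cuff:
#' brachiocephalic branch, proximal cuff end, distal cuff end, carotid
#' bifurcation.
#'
#' @param branch,cuff_proximal,cuff_distal,bifurcation 0-based slice indices
#'   satisfying `branch < cuff_proximal <= cuff_distal < bifurcation`.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(branch, cuff_proximal, cuff_distal, bifurcation) {
  v <- c(branch = branch, cuff_proximal = cuff_proximal,
         cuff_distal = cuff_distal, bifurcation = bifurcation)
  if (any(!is.finite(v)) || any(v != floor(v)) || any(v < 0))
    stop("landmark slice indices must be non-negative integers", call. = FALSE)
  v <- stats::setNames(as.integer(v), names(v))
  if (!(v[1] < v[2] && v[2] <= v[3] && v[3] < v[4]))
    stop("landmarks must satisfy branch < cuff_proximal <= cuff_distal < bifurcation",
         call. = FALSE)
  structure(as.list(v), class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("<landmarks> branch %d | cuff %d-%d | bifurcation %d (0-based slices)\n",
              x$branch, x$cuff_proximal, x$cuff_distal, x$bifurcation))
  invisible(x)
}

validate_landmarks <- function(lm, n_slices) {
  stopifnot(inherits(lm, "landmarks"))
  if (lm$bifurcation >= n_slices)
    stop(sprintf("landmarks exceed volume extent (bifurcation %d, %d slices)",
                 lm$bifurcation, n_slices), call. = FALSE)
  invisible(lm)
}

file_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  stop("unrecognized volume format (expect .nii, .nii.gz, .tif or .tiff): ",
       path, call. = FALSE)
}

#' Read a 3D MRA volume from NIfTI or multi-page TIFF
#'
#' NIfTI is the canonical on-disk format and round-trips intensities
#' exactly; multi-page TIFF stacks are accepted with the page axis as the
#' slice axis. TIFF float storage is unit-range, so TIFF intensities are
#' read as stored (in `[0, 1]`); every downstream step (threshold
#' selection, binarization, area counting) is invariant to the intensity
#' scale.
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @param meta Scan annotations to attach (see [mra_volume()]).
#' @param slice_axis,slice_direction Geometry overrides; by convention
#'   volumes are stored realigned (slice axis last, direction `+1`).
#' @param voxel_size Override for the voxel size; for NIfTI the header
#'   `pixdim` is used when this is `NULL`.
#' @return An [mra_volume()].
#' @export
read_volume <- function(path, meta = list(), slice_axis = 3L,
                        slice_direction = 1L, voxel_size = NULL) {
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim = dim(img))
    if (is.null(voxel_size)) {
      pd <- RNifti::pixdim(img)
      voxel_size <- if (length(pd) >= 3 && all(pd[1:3] > 0)) pd[1:3] else c(1, 1, 1)
    }
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- simplify2array(lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse any colour channels
      p
    }))
    if (length(dim(vox)) != 3L)
      stop("TIFF stack must contain at least 2 pages", call. = FALSE)
    if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
    slice_axis <- 3L  # page axis
  }
  mra_volume(vox, slice_axis = slice_axis, slice_direction = slice_direction,
             voxel_size = voxel_size, meta = meta)
}

#' Write a 3D MRA volume to NIfTI or multi-page TIFF
#'
#' NIfTI output stores intensities as doubles and `voxel_size` in the
#' header `pixdim`, so `read_volume(write_volume(v))` is voxel-identical.
#' TIFF output is uncompressed 32-bit float and requires unit-range
#' intensities (the TIFF convention); rescale with
#' `vol$voxels / max(vol$voxels)` first if needed. TIFF round-trips are
#' exact at single precision. NIfTI volumes are written in their stored
#' orientation; TIFF stacks are realigned so pages run cranio-caudally.
#'
#' @param vol An [mra_volume()].
#' @param path Destination path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mra_volume"))
  fmt <- file_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("directory not writable: ", dir, call. = FALSE)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$voxel_size
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    v <- realign_craniocaudal(vol)
    if (max(v$voxels) > 1)
      stop("TIFF output requires unit-range intensities; rescale first ",
           "or use NIfTI for absolute intensities", call. = FALSE)
    pages <- lapply(seq_len(dim(v$voxels)[3]), function(s) v$voxels[, , s])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  invisible(path)
}

#' Realign a volume into the cranio-caudal convention
#'
#' Pure axis permutation and/or slice-order reversal bringing the
#' cranio-caudal axis to the last array axis with slice index increasing
#' from the brachiocephalic branch (direction `+1`). The multiset of voxel
#' intensities is unchanged and the operation is idempotent.
#'
#' @param vol An [mra_volume()].
#' @return An [mra_volume()] with `slice_axis = 3` and `slice_direction = +1`.
#' @export
realign_craniocaudal <- function(vol) {
  stopifnot(inherits(vol, "mra_volume"))
  vox <- vol$voxels
  vsz <- vol$voxel_size
  if (vol$slice_axis != 3L) {
    perm <- c(setdiff(1:3, vol$slice_axis), vol$slice_axis)
    vox <- aperm(vox, perm)
    vsz <- vsz[perm]
  }
  if (vol$slice_direction == -1L) {
    vox <- vox[, , rev(seq_len(dim(vox)[3])), drop = FALSE]
  }
  mra_volume(vox, slice_axis = 3L, slice_direction = 1L,
             voxel_size = vsz, meta = vol$meta)
}

#' Read landmark annotations from a YAML sidecar
#'
#' @param path YAML file with fields `branch_slice`, `cuff_proximal_slice`,
#'   `cuff_distal_slice`, `bifurcation_slice` (0-based slice indices) and
#'   optionally a `meta` block.
#' @return A [landmarks()] object; any `meta` block is attached as an
#'   attribute.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("branch_slice", "cuff_proximal_slice", "cuff_distal_slice",
            "bifurcation_slice")
  if (!all(need %in% names(y)))
    stop("landmark file must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  lm <- landmarks(y$branch_slice, y$cuff_proximal_slice,
                  y$cuff_distal_slice, y$bifurcation_slice)
  if (!is.null(y$meta)) attr(lm, "meta") <- y$meta
  lm
}

#' Write landmark annotations to a YAML sidecar
#'
#' @param lm A [landmarks()] object.
#' @param path Destination YAML path.
#' @param meta Optional named list (e.g. `animal_id`, `side`, `week`)
#'   stored under a `meta` block.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, meta = NULL) {
  stopifnot(inherits(lm, "landmarks"))
  y <- list(branch_slice = lm$branch, cuff_proximal_slice = lm$cuff_proximal,
            cuff_distal_slice = lm$cuff_distal, bifurcation_slice = lm$bifurcation)
  if (!is.null(meta)) y$meta <- meta
  yaml::write_yaml(y, path)
  invisible(path)
}
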