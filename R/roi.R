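#' Delineate the carotid ROI by seeded connected-component selection
#'
#' Returns the 26-connected on-component of the binarized volume that
#' contains the seed point, excluding every other bright structure
#' (e.g. nearby vessels or artefacts). This mirrors the auto-selection of
#' the carotid in the vendor analysis software.
#'
#' @param binvol A [binarize()] result.
#' @param seed_point Integer length-3, 1-based array coordinates of a
#'   voxel inside the vessel lumen (e.g. the lumen centre at the
#'   brachiocephalic branch slice).
#' @return A logical 3D array, `TRUE` on the selected component.
#' @export
delineate_carotid_roi <- function(binvol, seed_point) {
  stopifnot(inherits(binvol, "binary_volume"))
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L)
    stop("`seed_point` must be three array coordinates", call. = FALSE)
  d <- dim(binvol$mask)
  if (any(seed_point < 1) || any(seed_point > d))
    stop("seed point outside the volume", call. = FALSE)
  if (!binvol$mask[seed_point[1], seed_point[2], seed_point[3]])
    stop("seed point is not an on-voxel (background or below threshold)",
         call. = FALSE)
  roi <- cc26_from_seed(as.logical(binvol$mask), d, seed_point)
  dim(roi) <- d
  roi
}

#' Per-slice lumen area curve from a binarized volume
#'
#' `areas[s]` counts the voxels that are on and inside the ROI within
#' slice `s` (slice axis last, i.e. after [realign_craniocaudal()]).
#'
#' @param binvol A [binarize()] result with slice axis 3.
#' @param roi Optional logical mask of the same shape (from
#'   [delineate_carotid_roi()]); `NULL` counts all on-voxels.
#' @param pixel_area Optional in-plane pixel area (mm^2) to scale counts.
#' @return An [area_curve()].
#' @export
compute_area_curve <- function(binvol, roi = NULL, pixel_area = NULL) {
  stopifnot(inherits(binvol, "binary_volume"))
  if (binvol$slice_axis != 3L)
    stop("binarized volume must be realigned (slice axis last)", call. = FALSE)
  m <- binvol$mask
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(m)))
      stop("ROI shape does not match the mask", call. = FALSE)
    m <- m & roi
  }
  counts <- apply(m, 3, sum)
  if (!is.null(pixel_area)) counts <- counts * pixel_area
  area_curve(counts, pixel_area = pixel_area)
}
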