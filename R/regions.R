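#' Partition carotid slices into shear-stress regions R1-R5
#'
#' The cuffed carotid is divided along the cranio-caudal axis using the
#' four anatomical landmarks. The span from the brachiocephalic branch to
#' the slice before the proximal cuff end is split into three contiguous
#' runs R1, R2, R3 (R1 adjacent to the branch) of sizes as equal as
#' possible; a remainder of 1 slice goes to R1, a remainder of 2 to R1 and
#' R2. R4 is the closed interval of slices within the cuff, and R5 runs
#' from the slice after the distal cuff end to the bifurcation. Slices
#' outside `[branch, bifurcation]` are labelled `"outside"`.
#'
#' @param landmarks A [landmarks()] object (0-based slice indices).
#' @param n_slices Total number of slices along the cranio-caudal axis.
#' @return An object of class `region_partition`: list with `labels`
#'   (character vector of length `n_slices`, entry `s + 1` giving the label
#'   of 0-based slice `s`) and `n_slices`.
#' @export
partition_regions <- function(landmarks, n_slices) {
  validate_landmarks(landmarks, n_slices)
  b <- landmarks$branch; cp <- landmarks$cuff_proximal
  cd <- landmarks$cuff_distal; bf <- landmarks$bifurcation
  span_a <- cp - b                     # slices b .. cp-1
  if (span_a < 3)
    stop("span from branch to cuff must contain at least 3 slices",
         call. = FALSE)
  base <- span_a %/% 3
  rem <- span_a %% 3
  sizes <- base + c(rem >= 1, rem >= 2, FALSE)
  labels <- rep("outside", n_slices)
  pos <- b
  for (r in 1:3) {
    labels[(pos + 1):(pos + sizes[r])] <- paste0("R", r)
    pos <- pos + sizes[r]
  }
  labels[(cp + 1):(cd + 1)] <- "R4"
  labels[(cd + 2):(bf + 1)] <- "R5"
  structure(list(labels = labels, n_slices = as.integer(n_slices)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", x$n_slices, "slices\n")
  for (r in c("R1", "R2", "R3", "R4", "R5")) {
    s <- region_slices(x, r)
    cat(sprintf("  %s: slices %d-%d (%d)\n", r, min(s), max(s), length(s)))
  }
  invisible(x)
}

#' Slices assigned to one region
#'
#' @param partition A [partition_regions()] result.
#' @param region One of `"R1"` ... `"R5"` or `"outside"`.
#' @return 0-based slice indices belonging to `region`.
#' @export
region_slices <- function(partition, region) {
  stopifnot(inherits(partition, "region_partition"))
  which(partition$labels == region) - 1L
}

#' Per-slice lumen area curve
#'
#' @param areas Numeric vector, one non-negative value per slice (on-pixel
#'   counts, optionally scaled to mm^2).
#' @param pixel_area In-plane pixel area in mm^2 used to scale the counts,
#'   or `NULL` for raw counts.
#' @return An object of class `area_curve`.
#' @export
area_curve <- function(areas, pixel_area = NULL) {
  areas <- as.numeric(areas)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be finite and >= 0", call. = FALSE)
  structure(list(areas = areas, n_slices = length(areas),
                 pixel_area = pixel_area),
            class = "area_curve")
}

#' @export
print.area_curve <- function(x, ...) {
  cat(sprintf("<area_curve> %d slices, total %.6g%s\n", x$n_slices,
              sum(x$areas), if (is.null(x$pixel_area)) " px" else " mm^2"))
  invisible(x)
}

#' Region-wise pre/post AUC difference
#'
#' The area under the per-slice lumen-area curve is taken by the rectangle
#' rule with unit slice width (a plain sum over the region's slices), so on
#' binary data the pre-minus-post difference equals a voxel count. Bound
#' iron particles darken lumen voxels in the post-contrast scan, so binding
#' yields a positive `delta_auc`; negative values (post brighter than pre)
#' are permitted and flagged.
#'
#' @param pre_curve,post_curve [area_curve()]s of equal length from the
#'   pre- and registered post-contrast binarized volumes.
#' @param partition A [partition_regions()] result of the same length.
#' @param region Region label present in the partition.
#' @return A one-row [tibble::tibble()] with `region`, `auc_pre`,
#'   `auc_post`, `delta_auc` and `negative_signal`.
#' @export
delta_auc <- function(pre_curve, post_curve, partition, region) {
  stopifnot(inherits(pre_curve, "area_curve"),
            inherits(post_curve, "area_curve"),
            inherits(partition, "region_partition"))
  if (pre_curve$n_slices != post_curve$n_slices)
    stop("pre and post curves differ in length", call. = FALSE)
  if (pre_curve$n_slices != partition$n_slices)
    stop("partition length does not match the curves", call. = FALSE)
  sl <- region_slices(partition, region)
  if (length(sl) == 0)
    stop("region ", region, " not present in partition", call. = FALSE)
  auc_pre <- sum(pre_curve$areas[sl + 1])
  auc_post <- sum(post_curve$areas[sl + 1])
  d <- auc_pre - auc_post
  tibble::tibble(region = region, auc_pre = auc_pre, auc_post = auc_post,
                 delta_auc = d, negative_signal = d < 0)
}

#' AUC differences for all five regions
#'
#' @inheritParams delta_auc
#' @param regions Region labels to evaluate.
#' @return A [tibble::tibble()] with one row per region.
#' @export
delta_auc_all <- function(pre_curve, post_curve, partition,
                          regions = paste0("R", 1:5)) {
  dplyr::bind_rows(lapply(regions, function(r)
    delta_auc(pre_curve, post_curve, partition, r)))
}
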