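#' Select the session threshold on the control carotid
#'
#' Otsu's method on a 256-bin histogram spanning the observed intensity
#' range: the returned threshold maximizes the between-class variance of
#' the two-class split. Following the study protocol, the threshold is
#' selected once on the control carotid (LCCA) and then applied to every
#' carotid in the same scan session.
#'
#' @param control An [mra_volume()] (the control carotid), or a numeric
#'   array.
#' @param roi Optional logical mask restricting the histogram.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity (numeric scalar). Voxels strictly above
#'   it are classified as lumen by [binarize()].
#' @export
select_threshold <- function(control, roi = NULL, n_bins = 256L) {
  v <- if (inherits(control, "mra_volume")) control$voxels else control
  v <- as.numeric(v)
  if (!is.null(roi)) v <- v[as.logical(roi)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("cannot select a threshold on constant intensities", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  total <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  mt <- m0[n_bins]
  # candidate cut after bin k: classes are bins 1..k and k+1..n_bins
  k <- seq_len(n_bins - 1)
  wb <- w0[k]; wf <- total - wb
  valid <- wb > 0 & wf > 0
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mt * wb[valid] / total - m0[k][valid])^2 /
    (wb[valid] / total * (1 - wb[valid] / total))
  # ties (empty bins between well-separated modes) resolve to the middle
  # of the tied plateau, placing the threshold mid-gap
  mx <- max(sigma_b)
  tied <- which(sigma_b >= mx * (1 - 1e-12))
  best <- tied[(length(tied) + 1) %/% 2]
  breaks[best + 1]
}

#' Binarize a volume at a threshold
#'
#' @param vol An [mra_volume()].
#' @param threshold Finite intensity; voxels strictly above it are on.
#' @return An object of class `binary_volume`: list with logical `mask`
#'   (same shape/axes as the source), `threshold_used`, `slice_axis`,
#'   `slice_direction` and `voxel_size`.
#' @export
binarize <- function(vol, threshold) {
  stopifnot(inherits(vol, "mra_volume"))
  if (!is.finite(threshold))
    stop("`threshold` must be finite", call. = FALSE)
  structure(
    list(mask = vol$voxels > threshold, threshold_used = threshold,
         slice_axis = vol$slice_axis, slice_direction = vol$slice_direction,
         voxel_size = vol$voxel_size, meta = vol$meta),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d; %d on-voxels (threshold %.4g)\n",
              d[1], d[2], d[3], sum(x$mask), x$threshold_used))
  invisible(x)
}
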