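#' Phantom configuration for paired pre/post-contrast carotid volumes
#'
#' Describes a synthetic single-vessel time-of-flight angiography phantom:
#' a bright tubular lumen on a dark background, with region-dependent
#' plaque narrowing of the lumen and, in the post-contrast volume, a
#' fraction of lumen-wall voxels turned hypointense to emulate endothelial
#' MPIO binding.
#'
#' @param grid_shape Three positive integers; the acquisition grid
#'   (default `c(256, 256, 64)`, the in-vivo acquisition matrix). The
#'   third axis is cranio-caudal.
#' @param landmarks A [landmarks()] object, or `NULL` for proportional
#'   defaults: a margin of ~6% of the axis (at least 2 slices) before the
#'   branch and after the bifurcation — the anatomical landmarks are
#'   interior points of the imaged volume, as in a real neck scan — with
#'   the cuff from 50% to 72% of the axis.
#' @param lumen_radius Per-slice lumen radius in voxels: a scalar or a
#'   vector of length `grid_shape[3]`. Default `max(3, round(min(nx, ny) / 10))`.
#' @param lumen_intensity,background_intensity Mean bright / dark values
#'   (lumen must exceed background). Defaults 100 and 20.
#' @param noise_sigma Standard deviation of additive Gaussian noise;
#'   default 5% of the lumen-background gap. Use 0 for exact oracles.
#' @param rician If `TRUE`, use Rician (magnitude) noise instead of
#'   additive Gaussian.
#' @param binding_fraction Named numeric, fraction in `[0, 1]` of each
#'   region's lumen-wall voxels turned hypointense in the post volume.
#'   Missing regions default to 0 (so R4 and control arteries are 0).
#' @param plaque_narrowing Named numeric, fractional lumen radius
#'   reduction in `[0, 1)` per region; missing regions default to 0.
#' @param seed Integer seed making the phantom a pure function of the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(256, 256, 64),
                           landmarks = NULL,
                           lumen_radius = NULL,
                           lumen_intensity = 100,
                           background_intensity = 20,
                           noise_sigma = 0.05 * (lumen_intensity - background_intensity),
                           rician = FALSE,
                           binding_fraction = numeric(),
                           plaque_narrowing = numeric(),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2))
    stop("`grid_shape` must be three integers >= 2", call. = FALSE)
  nz <- grid_shape[3]
  if (is.null(landmarks)) {
    margin <- max(2, round(0.06 * nz))
    landmarks <- plaquemra::landmarks(margin, round(0.50 * nz),
                                      round(0.72 * nz), nz - 1 - margin)
  }
  validate_landmarks(landmarks, nz)
  if (is.null(lumen_radius))
    lumen_radius <- max(3, round(min(grid_shape[1:2]) / 10))
  if (length(lumen_radius) == 1L) lumen_radius <- rep(lumen_radius, nz)
  if (length(lumen_radius) != nz)
    stop("`lumen_radius` must be scalar or one value per slice", call. = FALSE)
  if (any(lumen_radius < 1))
    stop("lumen radius must be >= 1 voxel", call. = FALSE)
  if (max(lumen_radius) > min(grid_shape[1:2]) / 2 - 1)
    stop("lumen radius exceeds grid bounds", call. = FALSE)
  if (lumen_intensity <= background_intensity)
    stop("`lumen_intensity` must exceed `background_intensity`", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  regions <- paste0("R", 1:5)
  bf <- stats::setNames(rep(0, 5), regions)
  bf[names(binding_fraction)] <- binding_fraction
  if (any(bf < 0 | bf > 1))
    stop("`binding_fraction` values must lie in [0, 1]", call. = FALSE)
  pn <- stats::setNames(rep(0, 5), regions)
  pn[names(plaque_narrowing)] <- plaque_narrowing
  if (any(pn < 0 | pn >= 1))
    stop("`plaque_narrowing` values must lie in [0, 1)", call. = FALSE)
  structure(
    list(grid_shape = grid_shape, landmarks = landmarks,
         lumen_radius = as.numeric(lumen_radius),
         lumen_intensity = lumen_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma, rician = isTRUE(rician),
         binding_fraction = bf, plaque_narrowing = pn,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Effective (narrowed) lumen radius of each slice.
effective_radii <- function(config) {
  part <- partition_regions(config$landmarks, config$grid_shape[3])
  shrink <- rep(0, config$grid_shape[3])
  for (r in paste0("R", 1:5)) {
    sl <- region_slices(part, r)
    shrink[sl + 1] <- config$plaque_narrowing[[r]]
  }
  pmax(config$lumen_radius * (1 - shrink), 1)
}

#' Generate a paired pre/post-contrast phantom
#'
#' The pre-contrast volume is a noisy bright tube on a dark background with
#' region-dependent plaque narrowing. The post-contrast volume is the same
#' tube with, per region, a seeded random subset of lumen-wall voxels
#' (the outermost ~1.5-voxel ring, where particles adhere to the
#' endothelium) set to the background intensity before noise is added.
#' The returned `truth` records exactly how many voxels were flipped per
#' region, which is the oracle for the downstream AUC-difference
#' statistic. The output is a pure function of `(config, seed)`.
#'
#' @param config A [phantom_config()].
#' @param seed Overrides `config$seed` when given.
#' @param meta Scan annotations copied onto both volumes (`contrast` is
#'   set to `"pre"`/`"post"` automatically).
#' @return A list with elements `pre` and `post` ([mra_volume()]s),
#'   `landmarks`, and `truth` (named integer vector, flipped lumen-wall
#'   voxels per region R1-R5).
#' @export
generate_phantom_pair <- function(config, seed = config$seed, meta = list()) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  radii <- effective_radii(config)
  part <- partition_regions(config$landmarks, nz)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)

  pre <- array(config$background_intensity, dims)
  for (s in seq_len(nz)) {
    disk <- d2 <= radii[s]^2
    slice <- pre[, , s]
    slice[disk] <- config$lumen_intensity
    pre[, , s] <- slice
  }

  regions <- paste0("R", 1:5)
  truth <- stats::setNames(integer(5), regions)
  post <- pre
  with_seed(seed, {
    for (r in regions) {
      f <- config$binding_fraction[[r]]
      sl <- region_slices(part, r)
      if (f <= 0 || length(sl) == 0) next
      cand <- integer(0)
      for (s in sl + 1) {
        ring <- which(d2 <= radii[s]^2 & d2 > (radii[s] - 1.5)^2)
        if (length(ring) == 0) ring <- which(d2 <= radii[s]^2)
        cand <- c(cand, ring + (s - 1) * nx * ny)
      }
      n_flip <- round(f * length(cand))
      if (n_flip > 0) {
        flip <- sample(cand, n_flip)
        post[flip] <- config$background_intensity
        truth[[r]] <- as.integer(n_flip)
      }
    }
    if (config$noise_sigma > 0) {
      n <- length(pre)
      if (config$rician) {
        pre <- sqrt((pre + stats::rnorm(n, 0, config$noise_sigma))^2 +
                      stats::rnorm(n, 0, config$noise_sigma)^2)
        post <- sqrt((post + stats::rnorm(n, 0, config$noise_sigma))^2 +
                       stats::rnorm(n, 0, config$noise_sigma)^2)
      } else {
        pre <- pmax(pre + stats::rnorm(n, 0, config$noise_sigma), 0)
        post <- pmax(post + stats::rnorm(n, 0, config$noise_sigma), 0)
      }
      dim(pre) <- dims; dim(post) <- dims
    }
  })

  meta_pre <- utils::modifyList(meta, list(contrast = "pre"))
  meta_post <- utils::modifyList(meta, list(contrast = "post"))
  list(pre = mra_volume(pre, meta = meta_pre),
       post = mra_volume(post, meta = meta_post),
       landmarks = config$landmarks,
       truth = truth)
}
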