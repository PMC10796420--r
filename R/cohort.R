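#' Generate a full synthetic imaging cohort
#'
#' For every animal in every arm and every imaging week, generates a
#' paired pre/post-contrast phantom for the cuffed right carotid (RCCA)
#' and the untreated left carotid control (LCCA). The RCCA follows the
#' design's per-(arm, week, region) binding trajectory, with each animal's
#' binding fraction drawn from a truncated normal around the trajectory
#' mean (between-animal spread); the LCCA has zero binding and zero
#' narrowing. Histology sections are generated at the final week only.
#' Per-(animal, week, side) seeds are derived deterministically from the
#' master seed, so the whole cohort is a pure function of
#' `(design, config, seed)`.
#'
#' @param design A [cohort_design()].
#' @param config A [phantom_config()] giving the imaging geometry; its
#'   `binding_fraction` is overridden per animal/week and its
#'   `plaque_narrowing` by the design (RCCA only).
#' @param seed Master integer seed.
#' @return A list of class `mra_cohort` with elements `design`, `config`,
#'   `seed`, `animals` (nested scans with volumes, landmarks and truth),
#'   `truth` (tidy tibble of flipped-voxel counts), and `histology`.
#' @export
generate_cohort <- function(design, config, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(config, "phantom_config"))
  regions <- paste0("R", 1:5)
  animals <- list()
  truth_rows <- list()
  k <- 0L
  for (g in seq_len(nrow(design$groups))) {
    probe <- design$groups$probe[g]
    treatment <- design$groups$treatment[g]
    for (a in seq_len(design$groups$n_animals[g])) {
      animal_id <- sprintf("%s_%s_%02d", sub("-MPIO", "", probe), treatment, a)
      scans <- list()
      for (w in design$weeks) {
        k <- k + 1L
        s_rcca <- derive_seed(seed, 2L * k)
        s_lcca <- derive_seed(seed, 2L * k + 1L)
        bnd <- design$binding[design$binding$probe == probe &
                                design$binding$treatment == treatment &
                                design$binding$week == w, ]
        frac <- stats::setNames(bnd$mean_fraction[match(regions, bnd$region)],
                                regions)
        sdev <- stats::setNames(bnd$sd_fraction[match(regions, bnd$region)],
                                regions)
        frac_a <- with_seed(s_rcca,
                            rtruncnorm(5, frac, sdev, 0, 1))
        names(frac_a) <- regions
        meta <- list(animal_id = animal_id, probe = probe,
                     treatment = treatment, week = w)
        cfg_r <- phantom_config(
          grid_shape = config$grid_shape, landmarks = config$landmarks,
          lumen_radius = config$lumen_radius,
          lumen_intensity = config$lumen_intensity,
          background_intensity = config$background_intensity,
          noise_sigma = config$noise_sigma, rician = config$rician,
          binding_fraction = frac_a, plaque_narrowing = design$narrowing
        )
        cfg_l <- phantom_config(
          grid_shape = config$grid_shape, landmarks = config$landmarks,
          lumen_radius = config$lumen_radius,
          lumen_intensity = config$lumen_intensity,
          background_intensity = config$background_intensity,
          noise_sigma = config$noise_sigma, rician = config$rician
        )
        rcca <- generate_phantom_pair(cfg_r, seed = derive_seed(s_rcca, 1L),
                                      meta = c(meta, side = "RCCA"))
        lcca <- generate_phantom_pair(cfg_l, seed = derive_seed(s_lcca, 1L),
                                      meta = c(meta, side = "LCCA"))
        scans[[as.character(w)]] <- list(week = w, RCCA = rcca, LCCA = lcca)
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          animal_id = animal_id, probe = probe, treatment = treatment,
          week = w, side = rep(c("RCCA", "LCCA"), each = 5),
          region = rep(regions, 2),
          truth_count = c(rcca$truth, lcca$truth)
        )
      }
      animals[[animal_id]] <- list(animal_id = animal_id, probe = probe,
                                   treatment = treatment, scans = scans)
    }
  }
  histology <- generate_histology_table(design, seed = derive_seed(seed, 999983L))
  structure(
    list(design = design, config = config, seed = as.integer(seed),
         animals = animals, truth = dplyr::bind_rows(truth_rows),
         histology = histology),
    class = "mra_cohort"
  )
}

#' @export
print.mra_cohort <- function(x, ...) {
  cat("<mra_cohort>", length(x$animals), "animals x",
      length(x$design$weeks), "weeks, grid",
      paste(x$config$grid_shape, collapse = "x"), "\n")
  invisible(x)
}

#' Quantify every artery of a cohort
#'
#' Runs the full image-analysis pipeline on each (animal, week, side):
#' the session threshold is selected on the control LCCA by Otsu's method
#' and applied to both carotids of that scan session, then each artery is
#' realigned, registered, binarized, delineated, and reduced to per-region
#' AUC differences. Results are joined with the generator's ground truth.
#'
#' @param cohort An [generate_cohort()] result.
#' @param sides Which arteries to quantify (default both).
#' @param search_radius Registration search window in voxels. The
#'   generator does not misalign paired scans, so a small window suffices.
#' @param threshold Fixed absolute threshold overriding the per-session
#'   Otsu selection, or `NULL`.
#' @return A [tibble::tibble()] with one row per (animal, week, side,
#'   region): identifiers, `auc_pre`, `auc_post`, `delta_auc`,
#'   `negative_signal`, `threshold`, `shift_*`, and `truth_count`.
#' @export
quantify_cohort <- function(cohort, sides = c("RCCA", "LCCA"),
                            search_radius = 1L, threshold = NULL) {
  stopifnot(inherits(cohort, "mra_cohort"))
  rows <- list()
  for (an in cohort$animals) {
    for (scan in an$scans) {
      thr <- threshold %||% select_threshold(scan$LCCA$pre)
      for (side in sides) {
        pair <- scan[[side]]
        res <- quantify_arteries(pair$pre, pair$post, pair$landmarks,
                                 threshold = thr,
                                 search_radius = search_radius)
        prov <- attr(res, "provenance")
        res$animal_id <- an$animal_id
        res$probe <- an$probe
        res$treatment <- an$treatment
        res$week <- scan$week
        res$side <- side
        res$threshold <- thr
        res$shift_x <- prov$shift[1]
        res$shift_y <- prov$shift[2]
        res$shift_z <- prov$shift[3]
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(
    out, cohort$truth,
    by = c("animal_id", "probe", "treatment", "week", "side", "region")
  )
  dplyr::select(out, dplyr::all_of(c(
    "animal_id", "probe", "treatment", "week", "side", "region",
    "auc_pre", "auc_post", "delta_auc", "negative_signal",
    "threshold", "shift_x", "shift_y", "shift_z", "truth_count"
  )))
}

#' Write a cohort to disk
#'
#' Emits NIfTI volumes and landmark YAML sidecars per (animal, week,
#' side, contrast) plus `histology.csv` and `truth.csv`, mirroring how a
#' real study export would be laid out.
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mra_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, showWarnings = FALSE)
  for (an in cohort$animals) {
    for (scan in an$scans) {
      for (side in c("RCCA", "LCCA")) {
        pair <- scan[[side]]
        stem <- sprintf("%s_w%02d_%s", an$animal_id, scan$week, side)
        write_volume(pair$pre, file.path(vol_dir, paste0(stem, "_pre.nii.gz")))
        write_volume(pair$post, file.path(vol_dir, paste0(stem, "_post.nii.gz")))
        write_landmarks(pair$landmarks,
                        file.path(vol_dir, paste0(stem, "_landmarks.yaml")),
                        meta = list(animal_id = an$animal_id,
                                    side = side, week = scan$week))
      }
    }
  }
  utils::write.csv(cohort$histology, file.path(dir, "histology.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
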