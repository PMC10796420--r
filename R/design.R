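#' Study design for a synthetic cuff-implantation cohort
#'
#' Encodes the four study arms (dual-targeted vs IgG-control particles,
#' statin-treated vs untreated), the imaging weeks, the per-(arm, week,
#' region) MPIO binding-fraction trajectories with between-animal spread,
#' the region-dependent plaque narrowing, and the histology effect
#' profiles (biomarker means and AHA feature-flag probabilities per arm
#' and region).
#'
#' The default trajectories emulate the study's qualitative patterns:
#' untreated dual-targeted animals accrue binding in the low-shear
#' upstream regions R1/R2 (high, non-decreasing over weeks 15-30) and
#' modestly in R3; the oscillatory-shear R5 and the in-cuff R4 are
#' negligible; statin-treated and IgG-control arms show no quantifiable
#' binding. `effect = "null"` zeroes every binding trajectory and makes
#' all histology distributions identical across regions, for type-I
#' calibration.
#'
#' @param n_animals Named integer defaults `c(8, 8, 5, 5)` for
#'   DT-untreated, DT-statin, IgG-untreated, IgG-statin.
#' @param weeks Strictly increasing imaging weeks post cuff implantation.
#' @param binding_sd_rel Between-animal relative spread of the binding
#'   fraction (sd = `binding_sd_rel * mean`).
#' @param n_sections Histology sections per animal per region.
#' @param effect `"default"` (study-patterned) or `"null"` (all effects
#'   zero).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_animals = c(8, 8, 5, 5),
                          weeks = c(10, 15, 20, 30),
                          binding_sd_rel = 0.2,
                          n_sections = 3L,
                          effect = c("default", "null")) {
  effect <- match.arg(effect)
  if (length(n_animals) != 4L || any(n_animals < 1))
    stop("`n_animals` must give four positive group sizes", call. = FALSE)
  if (length(weeks) < 1L || any(diff(weeks) <= 0))
    stop("`weeks` must be strictly increasing", call. = FALSE)
  groups <- tibble::tibble(
    probe = c("DT-MPIO", "DT-MPIO", "IgG-MPIO", "IgG-MPIO"),
    treatment = c("none", "statin", "none", "statin"),
    n_animals = as.integer(n_animals)
  )

  regions <- paste0("R", 1:5)
  # Binding-fraction means for the untreated dual-targeted arm, by week.
  # Weeks beyond/between the defaults interpolate on the 10/15/20/30 grid.
  traj_weeks <- c(10, 15, 20, 30)
  traj <- list(
    R1 = c(0, 0.15, 0.30, 0.45),
    R2 = c(0, 0.15, 0.30, 0.45),
    R3 = c(0, 0.05, 0.08, 0.10),
    R4 = c(0, 0, 0, 0),
    R5 = c(0, 0, 0, 0)
  )
  binding <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    do.call(rbind, lapply(weeks, function(w) {
      mean_f <- vapply(regions, function(r) {
        if (effect == "null" || groups$probe[g] == "IgG-MPIO" ||
            groups$treatment[g] == "statin") 0
        else stats::approx(traj_weeks, traj[[r]], xout = w, rule = 2)$y
      }, numeric(1))
      tibble::tibble(probe = groups$probe[g], treatment = groups$treatment[g],
                     week = w, region = regions, mean_fraction = mean_f,
                     sd_fraction = binding_sd_rel * mean_f)
    }))
  }))

  narrowing <- c(R1 = 0.3, R2 = 0.3, R3 = 0.15, R4 = 0, R5 = 0.05)
  if (effect == "null") narrowing[] <- 0

  hist_regions <- c("R1", "R2", "R3", "R5")
  markers <- c("pct_moma2", "pct_vcam1", "pct_cd62p", "pct_oilredo",
               "pct_sma", "pct_collagen", "pct_necrotic_core")
  means_none <- rbind(
    pct_moma2 = c(35, 33, 20, 8),
    pct_vcam1 = c(30, 28, 18, 7),
    pct_cd62p = c(28, 26, 16, 6),
    pct_oilredo = c(40, 38, 25, 10),
    pct_sma = c(12, 14, 20, 30),
    pct_collagen = c(15, 16, 22, 30),
    pct_necrotic_core = c(25, 22, 12, 4)
  )
  colnames(means_none) <- hist_regions
  means_statin <- means_none
  inflam <- c("pct_moma2", "pct_vcam1", "pct_cd62p", "pct_oilredo",
              "pct_necrotic_core")
  means_statin[inflam, c("R1", "R2", "R3")] <-
    0.4 * means_none[inflam, c("R1", "R2", "R3")]
  means_statin["pct_sma", c("R2", "R3", "R5")] <-
    0.6 * means_none["pct_sma", c("R2", "R3", "R5")]
  if (effect == "null") {
    means_none[] <- means_none[, "R3"]
    means_statin <- means_none
  }
  biomarker_means <- do.call(rbind, lapply(c("none", "statin"), function(tr) {
    mm <- if (tr == "none") means_none else means_statin
    do.call(rbind, lapply(hist_regions, function(r) {
      tibble::tibble(treatment = tr, region = r, marker = markers,
                     mean = mm[markers, r], sd = 0.15 * mm[markers, r] + 1.5)
    }))
  }))

  # MPIO fluorescence tracks the probe's binding, not the plaque biology.
  fluor <- dplyr::bind_rows(
    tibble::tibble(probe = "DT-MPIO", treatment = "none",
                   region = hist_regions, mean = c(40, 38, 15, 4)),
    tibble::tibble(probe = "DT-MPIO", treatment = "statin",
                   region = hist_regions, mean = c(4, 4, 3, 2)),
    tibble::tibble(probe = "IgG-MPIO", treatment = "none",
                   region = hist_regions, mean = 1),
    tibble::tibble(probe = "IgG-MPIO", treatment = "statin",
                   region = hist_regions, mean = 1)
  )
  if (effect == "null") fluor$mean <- 1
  fluor$sd <- 0.25 * fluor$mean + 0.5

  flags <- c("foam_cells", "lipid_pools", "lipid_core", "necrotic_core",
             "surface_defect", "haemorrhage")
  probs_none <- rbind(
    R1 = c(0.90, 0.80, 0.80, 1.00, 0.41, 0.02),
    R2 = c(0.90, 0.80, 0.80, 1.00, 0.19, 0.00),
    R3 = c(1.00, 1.00, 0.33, 0.20, 0.00, 0.00),
    R5 = c(1.00, 0.50, 0.00, 0.00, 0.00, 0.00)
  )
  probs_statin <- rbind(
    R1 = c(1.00, 1.00, 1.00, 0.44, 0.16, 0.00),
    R2 = c(1.00, 0.50, 0.56, 0.00, 0.00, 0.00),
    R3 = c(1.00, 0.50, 0.47, 0.00, 0.00, 0.00),
    R5 = c(1.00, 0.50, 0.03, 0.00, 0.00, 0.00)
  )
  colnames(probs_none) <- colnames(probs_statin) <- flags
  if (effect == "null") {
    probs_none[] <- rep(probs_none["R3", ], each = 4)
    probs_statin <- probs_none
  }
  flag_probs <- do.call(rbind, lapply(c("none", "statin"), function(tr) {
    pp <- if (tr == "none") probs_none else probs_statin
    do.call(rbind, lapply(hist_regions, function(r) {
      tibble::tibble(treatment = tr, region = r, flag = flags,
                     prob = pp[r, flags])
    }))
  }))

  structure(
    list(groups = groups, weeks = as.numeric(weeks),
         binding = binding, narrowing = narrowing,
         biomarker_means = biomarker_means, fluorescence = fluor,
         flag_probs = flag_probs, n_sections = as.integer(n_sections),
         binding_sd_rel = binding_sd_rel, effect = effect),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", x$effect, "effects;",
      sum(x$groups$n_animals), "animals in 4 arms; weeks",
      paste(x$weeks, collapse = "/"), "\n")
  invisible(x)
}
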