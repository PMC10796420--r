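#' Generate a synthetic histology section table
#'
#' Emits one row per histology cross-section for every animal and region
#' (R1, R2, R3, R5; the in-cuff R4 is disease-free and yields no plaque
#' sections). Biomarker area percentages are drawn from truncated-normal
#' distributions on `[0, 100]` with the design's per-(arm, region) means;
#' MPIO fluorescence from a truncated normal on `[0, Inf)`; and the six
#' AHA feature flags from per-(arm, region) Bernoulli probabilities.
#' The table is a pure function of `(design, seed)`.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return A [tibble::tibble()] with columns `animal_id`, `probe`,
#'   `treatment`, `region`, `section`, the seven `pct_*` biomarkers,
#'   `mpio_fluorescence`, and the six logical AHA feature flags.
#' @export
generate_histology_table <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(design$flag_probs$prob < 0 | design$flag_probs$prob > 1))
    stop("AHA flag probabilities must lie in [0, 1]", call. = FALSE)
  regions <- c("R1", "R2", "R3", "R5")
  markers <- unique(design$biomarker_means$marker)
  flags <- unique(design$flag_probs$flag)
  ns <- design$n_sections

  rows <- list()
  with_seed(seed, {
    for (g in seq_len(nrow(design$groups))) {
      probe <- design$groups$probe[g]
      treatment <- design$groups$treatment[g]
      for (a in seq_len(design$groups$n_animals[g])) {
        animal_id <- sprintf("%s_%s_%02d",
                             sub("-MPIO", "", probe), treatment, a)
        for (r in regions) {
          bm <- design$biomarker_means[
            design$biomarker_means$treatment == treatment &
              design$biomarker_means$region == r, ]
          fl <- design$fluorescence[
            design$fluorescence$probe == probe &
              design$fluorescence$treatment == treatment &
              design$fluorescence$region == r, ]
          fp <- design$flag_probs[
            design$flag_probs$treatment == treatment &
              design$flag_probs$region == r, ]
          sec <- tibble::tibble(
            animal_id = animal_id, probe = probe, treatment = treatment,
            region = r, section = seq_len(ns)
          )
          for (m in markers) {
            i <- match(m, bm$marker)
            sec[[m]] <- rtruncnorm(ns, bm$mean[i], bm$sd[i], 0, 100)
          }
          sec$mpio_fluorescence <- rtruncnorm(ns, fl$mean, fl$sd, 0, Inf)
          for (f in flags) {
            i <- match(f, fp$flag)
            sec[[f]] <- stats::runif(ns) < fp$prob[i]
          }
          rows[[length(rows) + 1L]] <- sec
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}
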