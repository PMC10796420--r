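#' Plaque vulnerability index
#'
#' Ratio of destabilising to stabilising plaque content:
#' `(%% macrophage + %% necrotic core) / (%% smooth muscle cells + %% collagen)`.
#' A high index indicates a vulnerable, unstable plaque. The index is
#' undefined (an error) when the stabilising denominator is zero.
#'
#' @param pct_moma2 Macrophage (MOMA-2 immunoreactivity) area percentage.
#' @param pct_necrotic_core Necrotic-core area percentage.
#' @param pct_sma Smooth-muscle (SMA immunoreactivity) area percentage.
#' @param pct_collagen Collagen area percentage.
#' @return A [tibble::tibble()] with `numerator`, `denominator`, `index`
#'   (vectorized over the inputs).
#' @export
vulnerability_index <- function(pct_moma2, pct_necrotic_core,
                                pct_sma, pct_collagen) {
  vals <- cbind(pct_moma2, pct_necrotic_core, pct_sma, pct_collagen)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  num <- pct_moma2 + pct_necrotic_core
  den <- pct_sma + pct_collagen
  if (any(den == 0))
    stop("vulnerability index undefined: %SMA + %collagen is zero",
         call. = FALSE)
  tibble::tibble(numerator = num, denominator = den, index = num / den)
}

aha_levels <- c("I", "II", "III", "IV", "V", "VI")

#' Rule-based AHA lesion type from plaque feature flags
#'
#' Assigns the highest applicable lesion type: type VI for a surface
#' defect or intraplaque haemorrhage; else V for a necrotic core; else IV
#' for a lipid core; else III for lipid pools; else II for foam cells;
#' else I (no lesion features). Adding a feature can never lower the
#' assigned type.
#'
#' @param foam_cells,lipid_pools,lipid_core,necrotic_core,surface_defect,haemorrhage
#'   Logical vectors (recycled to a common length).
#' @return An ordered factor with levels `I < II < III < IV < V < VI`.
#' @export
classify_aha <- function(foam_cells, lipid_pools, lipid_core,
                         necrotic_core, surface_defect, haemorrhage) {
  n <- max(lengths(list(foam_cells, lipid_pools, lipid_core,
                        necrotic_core, surface_defect, haemorrhage)))
  f <- function(x) rep_len(as.logical(x), n)
  type <- rep("I", n)
  type[f(foam_cells)] <- "II"
  type[f(lipid_pools)] <- "III"
  type[f(lipid_core)] <- "IV"
  type[f(necrotic_core)] <- "V"
  type[f(surface_defect) | f(haemorrhage)] <- "VI"
  factor(type, levels = aha_levels, ordered = TRUE)
}

#' Classify the sections of a histology table
#'
#' @param sections Section table with the six logical AHA flag columns
#'   (as produced by [generate_histology_table()]).
#' @return `sections` with an `aha_type` ordered-factor column appended.
#' @export
classify_sections <- function(sections) {
  sections$aha_type <- classify_aha(
    sections$foam_cells, sections$lipid_pools, sections$lipid_core,
    sections$necrotic_core, sections$surface_defect, sections$haemorrhage
  )
  sections
}

#' Aggregate biomarkers to per-animal, per-region means
#'
#' Arithmetic mean of each biomarker percentage and of the MPIO
#' fluorescence over the sections of each (animal, region) cell. Rows for
#' the in-cuff region R4 are produced when present but flagged
#' `excluded = TRUE`, since the disease-free cuff zone is excluded from
#' the statistical comparisons.
#'
#' @param sections Histology section table (see
#'   [generate_histology_table()]).
#' @return A [tibble::tibble()] keyed by (`animal_id`, `region`) with the
#'   mean of every `pct_*` column and of `mpio_fluorescence`, `n_sections`,
#'   and the `excluded` flag. `probe`/`treatment` columns are carried
#'   through when present.
#' @export
aggregate_region_biomarkers <- function(sections) {
  if (is.null(sections) || nrow(sections) == 0)
    stop("section table is empty", call. = FALSE)
  keys <- intersect(c("animal_id", "probe", "treatment", "region"),
                    names(sections))
  vals <- intersect(c("pct_moma2", "pct_vcam1", "pct_cd62p", "pct_oilredo",
                      "pct_sma", "pct_collagen", "pct_necrotic_core",
                      "mpio_fluorescence"), names(sections))
  out <- dplyr::summarise(
    dplyr::group_by(sections, dplyr::across(dplyr::all_of(keys))),
    dplyr::across(dplyr::all_of(vals), mean),
    n_sections = dplyr::n(), .groups = "drop"
  )
  out$excluded <- out$region == "R4"
  out
}

# Round percentages to `digits` decimals so they still sum to 100
# (largest-remainder correction).
largest_remainder <- function(p, digits = 1L) {
  scale <- 10^digits
  f <- floor(p * scale)
  deficit <- round(100 * scale - sum(f))
  if (deficit > 0) {
    rem <- p * scale - f
    top <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    f[top] <- f[top] + 1
  }
  f / scale
}

#' Distribution of AHA lesion types per region
#'
#' Classifies every section with [classify_aha()] and tabulates the
#' percentage of sections of each type within each region. Percentages
#' are reported to one decimal with a largest-remainder correction so
#' they sum to exactly 100 per region.
#'
#' @param sections Histology section table.
#' @param probe,treatment Optional filters selecting one study arm.
#' @return A [tibble::tibble()] with `region`, `aha_type`, `percent` and
#'   `n_sections` (the region's section count).
#' @export
aha_distribution <- function(sections, probe = NULL, treatment = NULL) {
  if (!is.null(probe)) sections <- sections[sections$probe == probe, ]
  if (!is.null(treatment))
    sections <- sections[sections$treatment == treatment, ]
  if (nrow(sections) == 0)
    stop("no sections left after filtering", call. = FALSE)
  sections <- classify_sections(sections)
  out <- list()
  for (r in sort(unique(sections$region))) {
    sub <- sections[sections$region == r, ]
    counts <- table(factor(sub$aha_type, levels = aha_levels))
    pct <- largest_remainder(100 * as.numeric(counts) / nrow(sub))
    keep <- counts > 0
    out[[r]] <- tibble::tibble(region = r, aha_type = aha_levels[keep],
                               percent = pct[keep], n_sections = nrow(sub))
  }
  dplyr::bind_rows(out)
}
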