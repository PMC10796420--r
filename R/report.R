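#' Longitudinal summary tables and tests for a quantified cohort
#'
#' Produces the tidy tables behind the study's longitudinal figures:
#' per-(arm, week, side, region) summaries of the AUC-difference signal
#' (mean, sd, n, and the Tukey box-and-whisker five-number summary),
#' pairwise inter-region tests per arm and week (cuffed artery), per-
#' (region, week) treated-vs-untreated tests, and, when histology is
#' supplied, signal-biomarker correlations at the final imaging week.
#' Missing cells are reported as absent rows or `NA`, not errors. The
#' output is deterministic given its inputs.
#'
#' @param signals A [quantify_cohort()] table (or any table with columns
#'   `animal_id`, `probe`, `treatment`, `week`, `side`, `region`,
#'   `delta_auc`).
#' @param histology Optional histology section table; used for
#'   signal-biomarker correlations at the final week.
#' @param alpha Significance level for all tests.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @return A list of class `mra_report` with tibbles `summary`,
#'   `region_tests`, `group_tests` and `correlations` (the last may be
#'   `NULL`).
#' @export
longitudinal_report <- function(signals, histology = NULL, alpha = 0.05,
                                var_equal = TRUE,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  five <- function(x) {
    s <- grDevices::boxplot.stats(x)$stats
    tibble::tibble(whisker_low = s[1], q1 = s[2], median = s[3],
                   q3 = s[4], whisker_high = s[5])
  }
  summary_tbl <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(signals, .data$probe, .data$treatment, .data$week,
                      .data$side, .data$region),
      n = dplyr::n(),
      mean = mean(.data$delta_auc),
      sd = if (dplyr::n() > 1) stats::sd(.data$delta_auc) else NA_real_,
      five(.data$delta_auc),
      .groups = "drop"
    ),
    .data$probe, .data$treatment, .data$week, .data$side, .data$region
  )

  rcca <- signals[signals$side == "RCCA", ]
  cells <- unique(rcca[, c("probe", "treatment", "week")])
  cells <- cells[order(cells$probe, cells$treatment, cells$week), ]
  region_tests <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    sub <- rcca[rcca$probe == cells$probe[i] &
                  rcca$treatment == cells$treatment[i] &
                  rcca$week == cells$week[i], ]
    vals <- split(sub$delta_auc, sub$region)
    res <- tryCatch(compare_regions(vals, alpha = alpha,
                                    var_equal = var_equal),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(cells[i, ], res)
  }))

  gt_cells <- unique(rcca[rcca$region != "R4", c("probe", "week", "region")])
  gt_cells <- gt_cells[order(gt_cells$probe, gt_cells$week, gt_cells$region), ]
  group_tests <- dplyr::bind_rows(lapply(seq_len(nrow(gt_cells)), function(i) {
    sub <- rcca[rcca$probe == gt_cells$probe[i] &
                  rcca$week == gt_cells$week[i] &
                  rcca$region == gt_cells$region[i], ]
    a <- sub$delta_auc[sub$treatment == "none"]
    b <- sub$delta_auc[sub$treatment == "statin"]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    res <- compare_groups(a, b, alpha = alpha, var_equal = var_equal,
                          contrast = "none vs statin")
    dplyr::bind_cols(gt_cells[i, ], res)
  }))

  correlations <- NULL
  if (!is.null(histology)) {
    agg <- aggregate_region_biomarkers(histology)
    agg <- agg[!agg$excluded, ]
    final_week <- max(signals$week)
    sig <- rcca[rcca$week == final_week & rcca$region != "R4", ]
    merged <- dplyr::inner_join(
      sig, agg, by = intersect(c("animal_id", "probe", "treatment", "region"),
                               names(agg))
    )
    ys <- intersect(c("mpio_fluorescence", "pct_oilredo", "pct_moma2",
                      "pct_cd62p", "pct_vcam1", "pct_sma"), names(merged))
    correlations <- dplyr::bind_rows(lapply(ys, function(y) {
      tryCatch(
        correlate_signal_biomarkers(merged$delta_auc, merged[[y]],
                                    method = method,
                                    x_name = "delta_auc", y_name = y),
        error = function(e) tibble::tibble(x_name = "delta_auc", y_name = y,
                                           r = NA_real_, p_value = NA_real_,
                                           n = nrow(merged))
      )
    }))
    correlations$week <- final_week
  }

  structure(list(summary = summary_tbl, region_tests = region_tests,
                 group_tests = group_tests, correlations = correlations,
                 alpha = alpha),
            class = "mra_report")
}

#' @export
print.mra_report <- function(x, ...) {
  cat("<mra_report>\n")
  cat("  summary:", nrow(x$summary), "cells\n")
  cat("  region tests:", nrow(x$region_tests), "contrasts;",
      sum(x$region_tests$significant), "significant at alpha =", x$alpha, "\n")
  cat("  group tests:", nrow(x$group_tests), "contrasts;",
      sum(x$group_tests$significant), "significant\n")
  if (!is.null(x$correlations))
    cat("  correlations:", nrow(x$correlations), "biomarkers\n")
  invisible(x)
}

#' Write report tables to CSV
#'
#' Deterministic output: rerunning on the same inputs yields byte-identical
#' files.
#'
#' @param report A [longitudinal_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mra_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  wr(report$summary, "summary.csv")
  wr(report$region_tests, "region_tests.csv")
  wr(report$group_tests, "group_tests.csv")
  wr(report$correlations, "correlations.csv")
  invisible(dir)
}

#' Box-and-whisker plot of the signal by region over time
#'
#' Tukey convention (1.5 x IQR whiskers), faceted by study arm, mirroring
#' the longitudinal signal figures.
#'
#' @param signals A [quantify_cohort()] table.
#' @param side Which artery to plot.
#' @return A [ggplot2::ggplot()] object.
#' @export
plot_signal_by_region <- function(signals, side = "RCCA") {
  sub <- signals[signals$side == side, ]
  sub$week_f <- factor(sub$week)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$region, y = .data$delta_auc,
                                    fill = .data$week_f)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$probe),
                        ggplot2::vars(.data$treatment)) +
    ggplot2::labs(x = "carotid region", y = expression(Delta * "AUC (px slices)"),
                  fill = "week") +
    ggplot2::theme_bw()
}
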