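# Two-sample Student t with a defined answer on degenerate (constant)
# input: identical constant samples give t = 0, p = 1; constant samples
# with different means give |t| = Inf, p = 0.
student_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  pooled_var <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (pooled_var == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(statistic = 0, p_value = 1, df = n1 + n2 - 2))
    return(list(statistic = sign(d) * Inf, p_value = 0, df = n1 + n2 - 2))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Pairwise region comparisons of per-animal signal values
#'
#' Two-sided two-sample Student's t-tests (pooled variance by default) for
#' every pair among regions R1, R2, R3 and R5. The in-cuff region R4 is
#' excluded: it is the disease-free athero-protective zone. Raw p-values
#' are reported (matching the study's analysis); a Holm-adjusted column is
#' added for rigour.
#'
#' @param values Named list mapping region labels to numeric vectors of
#'   per-animal values; an `R4` entry is dropped.
#' @param alpha Significance level (default 0.05).
#' @param var_equal `TRUE` for Student's pooled-variance test (default),
#'   `FALSE` for Welch.
#' @return A [tibble::tibble()] with one row per region pair: `contrast`,
#'   `region_a`, `region_b`, `n1`, `n2`, `statistic`, `p_value`, `p_holm`,
#'   `significant` (`p_value < alpha`).
#' @export
compare_regions <- function(values, alpha = 0.05, var_equal = TRUE) {
  values <- values[setdiff(names(values), "R4")]
  regions <- intersect(c("R1", "R2", "R3", "R5"), names(values))
  if (length(regions) < 2)
    stop("need at least two regions to compare", call. = FALSE)
  for (r in regions) {
    if (length(values[[r]]) < 2)
      stop("region ", r, " has fewer than 2 observations", call. = FALSE)
  }
  pairs <- utils::combn(regions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- student_t(values[[a]], values[[b]], var_equal = var_equal)
    tibble::tibble(contrast = paste(a, "vs", b), region_a = a, region_b = b,
                   n1 = length(values[[a]]), n2 = length(values[[b]]),
                   statistic = tt$statistic, p_value = tt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_value < alpha
  out
}

#' Compare signal between two groups for one (region, week) cell
#'
#' Two-sided two-sample Student's t-test of the AUC-difference signal
#' between, e.g., the statin-treated and untreated arms.
#'
#' @param signals_a,signals_b Numeric vectors of per-animal values (each
#'   of length >= 2).
#' @param alpha Significance level.
#' @param var_equal `TRUE` for pooled variance (default), `FALSE` for
#'   Welch.
#' @param contrast Optional label describing the comparison.
#' @return A one-row [tibble::tibble()] with `contrast`, `n1`, `n2`,
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_groups <- function(signals_a, signals_b, alpha = 0.05,
                           var_equal = TRUE, contrast = "a vs b") {
  tt <- student_t(signals_a, signals_b, var_equal = var_equal)
  tibble::tibble(contrast = contrast, n1 = length(signals_a),
                 n2 = length(signals_b), statistic = tt$statistic,
                 p_value = tt$p_value, significant = tt$p_value < alpha)
}

#' Correlate MR signal change with a histological biomarker
#'
#' Pearson product-moment correlation (Spearman available) with a
#' two-sided p-value, for the relationship between per-animal-region
#' AUC-difference values and biomarker expression. R4 rows must be
#' excluded upstream.
#'
#' @param delta_auc_values,biomarker_values Numeric vectors of equal
#'   length >= 3 with non-zero variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param x_name,y_name Labels for the report row.
#' @return A one-row [tibble::tibble()] with `x_name`, `y_name`, `r`,
#'   `p_value`, `n`.
#' @export
correlate_signal_biomarkers <- function(delta_auc_values, biomarker_values,
                                        method = c("pearson", "spearman"),
                                        x_name = "delta_auc",
                                        y_name = "biomarker") {
  method <- match.arg(method)
  x <- delta_auc_values; y <- biomarker_values
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(x_name = x_name, y_name = y_name,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
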