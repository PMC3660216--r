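#' Bonferroni adjustment of raw p-values
#'
#' `p_adj = min(1, m * p_raw)` with `m` the number of tests; the classical
#' family-wise error rate controlling adjustment.  Delegates to
#' [stats::p.adjust()].
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length.
#' @export
bonferroni_adjust <- function(p_raw) {
  if (!is.numeric(p_raw) || any(!is.finite(p_raw)) ||
      any(p_raw < 0 | p_raw > 1)) {
    stop("`p_raw` must be numeric in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "bonferroni")
}

#' Call differentially expressed genes at a significance level
#'
#' A gene is declared differentially expressed when its adjusted p-value is
#' strictly less than `alpha`.
#'
#' @param p_adj Numeric vector of adjusted p-values.
#' @param alpha Significance level in `[0, 1)`; `alpha = 0` rejects
#'   nothing.
#' @return Logical vector, `TRUE` = rejected.
#' @export
call_degs <- function(p_adj, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 ||
      alpha >= 1) {
    stop("`alpha` must lie in [0, 1).", call. = FALSE)
  }
  p_adj < alpha
}

#' Adjust a per-gene test table and make rejection calls
#'
#' Adds `p_adj` and `rejected` columns to a per-gene test tibble (the
#' output of [t_test_genes()] and friends).  Bonferroni is the default,
#' family-wise-error-controlling choice; Benjamini-Hochberg false
#' discovery rate control is available as an alternative.
#'
#' @param test_table Tibble with a `p_raw` column.
#' @param method `"bonferroni"` or `"BH"`.
#' @param alpha Significance level for the rejection call; strict
#'   inequality `p_adj < alpha`.
#' @return The input tibble with `p_adj` and `rejected` columns appended
#'   and `alpha`/`adjust_method` recorded as attributes.
#' @export
adjust_gene_pvalues <- function(test_table,
                                method = c("bonferroni", "BH"),
                                alpha = 0.05) {
  stopifnot(is.data.frame(test_table), "p_raw" %in% names(test_table))
  method <- match.arg(method)
  p_adj <- if (method == "bonferroni") {
    bonferroni_adjust(test_table$p_raw)
  } else {
    stats::p.adjust(test_table$p_raw, method = "BH")
  }
  out <- dplyr::mutate(test_table, p_adj = p_adj,
                       rejected = call_degs(p_adj, alpha))
  attr(out, "alpha") <- alpha
  attr(out, "adjust_method") <- method
  out
}

#' Confusion counts against ground truth
#'
#' Tabulates rejection calls against the truth classes: a true positive is
#' a rejected UP or DOWN gene, a false positive a rejected NDEG gene.
#'
#' @param rejected Logical vector of rejection calls.
#' @param truth Character vector of `"UP"`/`"DOWN"`/`"NDEG"` classes, same
#'   length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`; the four
#'   counts sum to the number of genes.
#' @export
confusion_counts <- function(rejected, truth) {
  if (length(rejected) != length(truth)) {
    stop("`rejected` and `truth` must have equal length.", call. = FALSE)
  }
  is_deg <- truth %in% c("UP", "DOWN")
  tibble::tibble(
    tp = sum(rejected & is_deg),
    fp = sum(rejected & !is_deg),
    tn = sum(!rejected & !is_deg),
    fn = sum(!rejected & is_deg)
  )
}
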