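#' Write an expression dataset to TSV files
#'
#' Writes three tab-separated files: `<prefix>_expr.tsv` (first column
#' `gene_id`, one column per array), `<prefix>_design.tsv` (`array_id`,
#' `group`) and `<prefix>_truth.tsv` (`gene_id`, `class`).
#'
#' @param dataset An [expr_dataset()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_expr_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "expr_dataset"))
  expr <- tibble::as_tibble(dataset$values, .name_repair = "minimal")
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(dataset$values)), expr)
  readr::write_tsv(expr, paste0(prefix, "_expr.tsv"))
  readr::write_tsv(tibble::tibble(array_id = colnames(dataset$values),
                                  group = dataset$group),
                   paste0(prefix, "_design.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = rownames(dataset$values),
                                  class = dataset$truth),
                   paste0(prefix, "_truth.tsv"))
  invisible(prefix)
}

#' Read an expression dataset from TSV files
#'
#' Counterpart of [write_expr_dataset()].  The truth file is optional for
#' user-supplied data: absent, all genes are labeled `"NDEG"` (no ground
#' truth).
#'
#' @param prefix Path prefix used when writing (or of user-supplied files
#'   following the same layout).
#' @param method Normalization label to record on the dataset.
#' @return An [expr_dataset()].
#' @export
read_expr_dataset <- function(prefix, method = "NONE") {
  expr <- readr::read_tsv(paste0(prefix, "_expr.tsv"),
                          show_col_types = FALSE)
  design <- readr::read_tsv(paste0(prefix, "_design.tsv"),
                            show_col_types = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$gene_id
  values <- values[, design$array_id, drop = FALSE]
  truth_path <- paste0(prefix, "_truth.tsv")
  truth <- if (file.exists(truth_path)) {
    tr <- readr::read_tsv(truth_path, show_col_types = FALSE)
    tr$class[match(expr$gene_id, tr$gene_id)]
  } else {
    rep("NDEG", nrow(values))
  }
  expr_dataset(values, design$group, truth, method = method)
}
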