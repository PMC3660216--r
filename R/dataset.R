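#' Expression dataset container
#'
#' An `expr_dataset` holds a genes-by-arrays matrix of (log2) expression
#' values together with the group label of each array (A or B), the
#' ground-truth differential-expression class of each gene (`"UP"`,
#' `"DOWN"`, `"NDEG"`), and the normalization method that produced the
#' values (`"NONE"`, `"QUANT"` or `"RANK"`).
#'
#' Rows are named `g0001, g0002, ...` and columns `A01, ..., B01, ...` so
#' that datasets round-trip through the TSV writer/reader unchanged.
#'
#' @param values Numeric matrix, genes in rows, arrays in columns.
#' @param group Character or factor vector of `"A"`/`"B"` labels, one per
#'   column of `values`; both groups must have the same size.
#' @param truth Character or factor vector of `"UP"`/`"DOWN"`/`"NDEG"`
#'   labels, one per row of `values`.
#' @param method Normalization label, one of `"NONE"`, `"QUANT"`, `"RANK"`.
#'
#' @return An object of class `expr_dataset`: a list with elements
#'   `values`, `group`, `truth` and `method`.
#' @seealso [simulate_simu()], [quantile_normalize()], [tidy.expr_dataset()]
#' @export
expr_dataset <- function(values, group, truth, method = "NONE") {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix.", call. = FALSE)
  }
  group <- as.character(group)
  truth <- as.character(truth)
  if (length(group) != ncol(values)) {
    stop("`group` must have one label per array (column).", call. = FALSE)
  }
  if (length(truth) != nrow(values)) {
    stop("`truth` must have one label per gene (row).", call. = FALSE)
  }
  if (!all(group %in% c("A", "B"))) {
    stop("group labels must be \"A\" or \"B\".", call. = FALSE)
  }
  if (sum(group == "A") != sum(group == "B")) {
    stop("the design must be balanced: equal numbers of A and B arrays.",
         call. = FALSE)
  }
  if (!all(truth %in% c("UP", "DOWN", "NDEG"))) {
    stop("truth labels must be \"UP\", \"DOWN\" or \"NDEG\".", call. = FALSE)
  }
  method <- match.arg(method, c("NONE", "QUANT", "RANK"))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(group, stats::ave(seq_along(group), group,
                                                 FUN = function(i) {
                                                   sprintf("%02d",
                                                           seq_along(i))
                                                 }))
  }
  structure(list(values = values, group = group, truth = truth,
                 method = method),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d arrays (%d per group)\n",
              nrow(x$values), ncol(x$values), sum(x$group == "A")))
  tab <- table(factor(x$truth, levels = c("UP", "DOWN", "NDEG")))
  cat(sprintf("  truth:  %d UP, %d DOWN, %d NDEG\n",
              tab[["UP"]], tab[["DOWN"]], tab[["NDEG"]]))
  cat(sprintf("  method: %s\n", x$method))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Tidy an expression dataset into a long tibble
#'
#' One row per (gene, array) measurement, carrying the group label of the
#' array, the truth class of the gene, and the normalization method.
#'
#' @param x An [expr_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `array_id`, `group`, `truth`,
#'   `method`, `value`.
#' @method tidy expr_dataset
#' @export
tidy.expr_dataset <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    array_id = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(x$group, each = nrow(x$values)),
    truth = rep(x$truth, times = ncol(x$values)),
    method = x$method,
    value = as.vector(x$values)
  )
}

#' Summarize an expression dataset in one row
#'
#' @param x An [expr_dataset()].
#' @param ... Unused.
#' @return A one-row tibble with gene/array counts, truth-class counts and
#'   the normalization method.
#' @method glance expr_dataset
#' @export
glance.expr_dataset <- function(x, ...) {
  tab <- table(factor(x$truth, levels = c("UP", "DOWN", "NDEG")))
  tibble::tibble(
    m = nrow(x$values), n_arrays = ncol(x$values),
    n_per_group = sum(x$group == "A"),
    m1_up = tab[["UP"]], m1_down = tab[["DOWN"]], m0 = tab[["NDEG"]],
    method = x$method
  )
}

# Column indices of each group.
group_cols <- function(dataset, group) which(dataset$group == group)
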