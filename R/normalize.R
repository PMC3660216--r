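#' Reference array of empirical quantiles
#'
#' Computes the reference array used by quantile normalization: the r-th
#' entry is the mean of the r-th smallest value across all arrays, both
#' phenotype groups pooled.
#'
#' @param dataset An [expr_dataset()] with at least one array.
#' @return Numeric vector of length `m`, non-decreasing.
#' @examples
#' ds <- expr_dataset(cbind(c(1, 2, 3), c(4, 5, 6)),
#'                    group = c("A", "B"), truth = rep("NDEG", 3))
#' compute_reference_quantiles(ds)  # 2.5 3.5 4.5
#' @export
compute_reference_quantiles <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (ncol(dataset$values) < 1 || nrow(dataset$values) < 1) {
    stop("dataset must contain at least one gene and one array.",
         call. = FALSE)
  }
  s <- apply(dataset$values, 2, sort)
  rowMeans(matrix(s, nrow = nrow(dataset$values)))
}

#' Quantile normalization
#'
#' Replaces each expression value by the reference-quantile entry with the
#' same within-array rank, so that every array ends up with exactly the
#' same empirical distribution (the reference array, see
#' [compute_reference_quantiles()]).  Simulated continuous data are
#' tie-free; should ties occur, the tied entries all receive the mean of
#' the reference entries spanning the tied rank range.
#'
#' @param dataset An [expr_dataset()].
#' @return An [expr_dataset()] with `method = "QUANT"`; each column sorted
#'   equals the reference array.
#' @export
quantile_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  q <- compute_reference_quantiles(dataset)
  cq <- c(0, cumsum(q))
  values <- apply(dataset$values, 2, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    # mean of q[lo..hi]; collapses to q[rank] when tie-free
    (cq[hi + 1] - cq[lo]) / (hi - lo + 1)
  })
  values <- matrix(values, nrow = nrow(dataset$values))
  dimnames(values) <- dimnames(dataset$values)
  expr_dataset(values, dataset$group, dataset$truth, method = "QUANT")
}

#' Rank normalization
#'
#' Replaces each expression value by its fractional rank within the array:
#' rank counted from the smallest value, divided by the number of genes.
#' Every tie-free column becomes a permutation of `1/m, 2/m, ..., 1`; ties
#' receive average ranks.
#'
#' @param dataset An [expr_dataset()].
#' @return An [expr_dataset()] with `method = "RANK"` and values in
#'   `(0, 1]`.
#' @export
rank_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  m <- nrow(dataset$values)
  values <- apply(dataset$values, 2, function(x) {
    rank(x, ties.method = "average") / m
  })
  values <- matrix(values, nrow = m)
  dimnames(values) <- dimnames(dataset$values)
  expr_dataset(values, dataset$group, dataset$truth, method = "RANK")
}

#' Identity (no-op) normalization
#'
#' Pass-through comparator: values are unchanged and the method label is
#' set to `"NONE"`, so raw-data analyses flow through the same pipeline as
#' normalized ones.
#'
#' @param dataset An [expr_dataset()].
#' @return The same dataset with `method = "NONE"`.
#' @export
identity_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  expr_dataset(dataset$values, dataset$group, dataset$truth,
               method = "NONE")
}

#' Apply a normalization method by label
#'
#' @param dataset An [expr_dataset()].
#' @param method One of `"none"`, `"quant"`, `"rank"` (case-insensitive).
#' @return The normalized [expr_dataset()].
#' @export
normalize_expression <- function(dataset,
                                 method = c("none", "quant", "rank")) {
  method <- match.arg(tolower(method[1]), c("none", "quant", "rank"))
  switch(method,
         none = identity_normalize(dataset),
         quant = quantile_normalize(dataset),
         rank = rank_normalize(dataset))
}
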