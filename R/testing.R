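#' Per-gene pooled two-sample t-test
#'
#' For each gene computes the equal-variance two-sample t-statistic
#' \deqn{t_i = \sqrt{n/2}\,(\bar y_i^A - \bar y_i^B)/\hat\sigma_i,}
#' where \eqn{\hat\sigma_i = \sqrt{(\hat\sigma_{iA}^2 +
#' \hat\sigma_{iB}^2)/2}} is the pooled sample standard deviation (sample
#' variances with divisor `n - 1`), and a two-sided p-value from the
#' central t distribution with `2n - 2` degrees of freedom.
#'
#' Degenerate genes (zero pooled SD) get `statistic = 0, p = 1` when the
#' mean difference is also zero, and `statistic = +/-Inf, p = 0` (flagged
#' in the `degenerate` column) otherwise.
#'
#' @param dataset An [expr_dataset()] with `n >= 2` arrays per group.
#' @return A tibble with one row per gene: `gene_id`, `truth`, `statistic`,
#'   `mean_diff`, `pooled_sd`, `p_raw`, `degenerate`.
#' @examples
#' ds <- expr_dataset(rbind(c(2, 4, 0, 2)), group = c("A", "A", "B", "B"),
#'                    truth = "UP")
#' t_test_genes(ds)  # t = sqrt(2), df = 2
#' @export
t_test_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  a <- dataset$values[, group_cols(dataset, "A"), drop = FALSE]
  b <- dataset$values[, group_cols(dataset, "B"), drop = FALSE]
  n <- ncol(a)
  if (n < 2) stop("need at least 2 arrays per group.", call. = FALSE)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (n - 1)
  vb <- rowSums((b - mb)^2) / (n - 1)
  mean_diff <- ma - mb
  pooled_sd <- sqrt((va + vb) / 2)
  stat <- ifelse(pooled_sd > 0,
                 sqrt(n / 2) * mean_diff / pooled_sd,
                 ifelse(mean_diff == 0, 0, sign(mean_diff) * Inf))
  p <- ifelse(is.finite(stat),
              2 * stats::pt(-abs(stat), df = 2 * n - 2), 0)
  p[pooled_sd == 0 & mean_diff == 0] <- 1
  tibble::tibble(
    gene_id = rownames(dataset$values),
    truth = dataset$truth,
    statistic = unname(stat),
    mean_diff = unname(mean_diff),
    pooled_sd = unname(pooled_sd),
    p_raw = unname(p),
    degenerate = unname(pooled_sd == 0 & mean_diff != 0)
  )
}

#' Per-gene Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test for each gene, exact for `n <= 10` per group in
#' the absence of ties and a normal approximation otherwise.  The reported
#' statistic is the rank sum of group A; `mean_diff` and `pooled_sd` are
#' carried along as descriptive quantities.
#'
#' @inheritParams t_test_genes
#' @return A tibble with one row per gene: `gene_id`, `truth`, `statistic`
#'   (group-A rank sum), `mean_diff`, `pooled_sd`, `p_raw`, `ties`.
#' @export
wilcoxon_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  ia <- group_cols(dataset, "A")
  ib <- group_cols(dataset, "B")
  n <- length(ia)
  if (n < 2) stop("need at least 2 arrays per group.", call. = FALSE)
  exact <- n <= 10
  res <- apply(dataset$values, 1, function(x) {
    a <- x[ia]
    b <- x[ib]
    has_ties <- anyDuplicated(x) > 0
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact && !has_ties, correct = TRUE)
    )
    ranksum_a <- sum(rank(x)[seq_len(n)])
    c(stat = ranksum_a, p = wt$p.value, ties = as.numeric(has_ties))
  })
  a <- dataset$values[, ia, drop = FALSE]
  b <- dataset$values[, ib, drop = FALSE]
  tibble::tibble(
    gene_id = rownames(dataset$values),
    truth = dataset$truth,
    statistic = unname(res["stat", ]),
    mean_diff = unname(rowMeans(a) - rowMeans(b)),
    pooled_sd = unname(sqrt((rowSums((a - rowMeans(a))^2) +
                               rowSums((b - rowMeans(b))^2)) /
                              (2 * (n - 1)))),
    p_raw = unname(res["p", ]),
    ties = unname(res["ties", ] > 0)
  )
}

# Energy statistic for labels u (logical, group A) given the pairwise
# absolute-difference matrix d of all 2n values:
#   2 mean|a - b| - mean|a - a'| - mean|b - b'|
# with means over all ordered pairs (V-statistic form).
energy_stat <- function(d, u) {
  n <- sum(u)
  2 * mean(d[u, !u]) - mean(d[u, u]) - mean(d[!u, !u])
}

#' Per-gene permutation energy (N-) test
#'
#' Nonparametric two-sample test based on the inter-point-distance energy
#' statistic \eqn{2\,\overline{|a-b|} - \overline{|a-a'|} -
#' \overline{|b-b'|}} (means over all ordered value pairs).  Significance
#' is assessed by random relabeling of the arrays; the same `n_perm`
#' permutations are applied to every gene, and the p-value is
#' `(1 + #permutations with statistic >= observed) / (1 + n_perm)`.
#'
#' @inheritParams t_test_genes
#' @param n_perm Number of random permutations; at least 100.  The smallest
#'   achievable p-value is `1 / (1 + n_perm)`; a warning is issued if that
#'   exceeds `min_level`.
#' @param min_level Significance level the permutation resolution is
#'   checked against (default `0.05`).
#' @return A tibble with one row per gene: `gene_id`, `truth`, `statistic`,
#'   `mean_diff`, `pooled_sd`, `p_raw`.
#' @export
n_test_genes <- function(dataset, n_perm = 1000, min_level = 0.05) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (n_perm < 100) stop("`n_perm` must be at least 100.", call. = FALSE)
  ia <- group_cols(dataset, "A")
  n <- length(ia)
  if (n < 2) stop("need at least 2 arrays per group.", call. = FALSE)
  n_tot <- ncol(dataset$values)
  if (1 / (1 + n_perm) > min_level) {
    warning(sprintf(
      "n_perm = %d cannot resolve p-values below %.3g (min level %g).",
      n_perm, 1 / (1 + n_perm), min_level))
  }
  obs_lab <- seq_len(n_tot) %in% ia
  # 0/1 indicator matrix of group-A membership, one column per permutation
  perm_u <- vapply(seq_len(n_perm),
                   function(i) as.numeric(seq_len(n_tot) %in%
                                            sample.int(n_tot, n)),
                   numeric(n_tot))
  stats_out <- numeric(nrow(dataset$values))
  p_out <- numeric(nrow(dataset$values))
  for (g in seq_len(nrow(dataset$values))) {
    x <- dataset$values[g, ]
    d <- abs(outer(x, x, "-"))
    obs <- energy_stat(d, obs_lab)
    # u' d u, 1' d u and the total sum give all three pair sums at once
    du <- d %*% perm_u
    s_aa <- colSums(du * perm_u)
    s_1du <- colSums(du)
    s_ab <- s_1du - s_aa
    s_bb <- sum(d) - 2 * s_1du + s_aa
    perm <- (2 * s_ab - s_aa - s_bb) / n^2
    stats_out[g] <- obs
    p_out[g] <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  }
  a <- dataset$values[, ia, drop = FALSE]
  b <- dataset$values[, -ia, drop = FALSE]
  tibble::tibble(
    gene_id = rownames(dataset$values),
    truth = dataset$truth,
    statistic = stats_out,
    mean_diff = unname(rowMeans(a) - rowMeans(b)),
    pooled_sd = unname(sqrt((rowSums((a - rowMeans(a))^2) +
                               rowSums((b - rowMeans(b))^2)) /
                              (2 * (n - 1)))),
    p_raw = p_out
  )
}

#' Run a per-gene test by label
#'
#' @param dataset An [expr_dataset()].
#' @param test One of `"t"`, `"wilcoxon"`, `"ntest"`.
#' @param n_perm Permutations for the energy test (ignored otherwise).
#' @return The per-gene test tibble of the chosen method.
#' @export
test_genes <- function(dataset, test = c("t", "wilcoxon", "ntest"),
                       n_perm = 1000) {
  test <- match.arg(test)
  switch(test,
         t = t_test_genes(dataset),
         wilcoxon = wilcoxon_genes(dataset),
         ntest = n_test_genes(dataset, n_perm = n_perm))
}
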