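#' Run one simulate-normalize-test-adjust replicate
#'
#' Composes the whole per-replicate pipeline: draw a dataset from the
#' design, normalize it, run a per-gene test, Bonferroni-adjust, call
#' differentially expressed genes at `alpha`, and tabulate confusion
#' counts against the simulation truth.
#'
#' @param design A [simu_design()]; its `seed` (if any) makes the
#'   replicate reproducible.
#' @param method Normalization label: `"none"`, `"quant"` or `"rank"`.
#' @param test Test label: `"t"`, `"wilcoxon"` or `"ntest"`.
#' @param alpha Family-wise significance level.
#' @param n_perm Permutations for the energy test.
#' @return A list with elements `counts` (one-row tibble `tp`, `fp`, `tn`,
#'   `fn`) and `tests` (the adjusted per-gene tibble).
#' @export
run_replicate <- function(design, method = "none", test = "t",
                          alpha = 0.05, n_perm = 1000) {
  dataset <- simulate_simu(design)
  norm <- normalize_expression(dataset, method)
  tests <- test_genes(norm, test, n_perm = n_perm)
  tests <- adjust_gene_pvalues(tests, "bonferroni", alpha)
  counts <- confusion_counts(tests$rejected, tests$truth)
  list(counts = counts, tests = tests)
}

# Seed for replicate r of condition k (1-based), derived from the root
# seed; NULL root seed leaves the RNG stream untouched.
replicate_seed <- function(root, cond, rep, n_replicates) {
  if (is.null(root)) return(NULL)
  root + (cond - 1L) * n_replicates + rep
}

#' True-positive power curves over an effect-size grid
#'
#' For every effect size in `e_grid` generates `n_replicates` datasets
#' (with `e_up = e`, `e_down = -e`), applies every requested normalization
#' and test to the *same* data, and summarizes true- and false-positive
#' counts across replicates.  This reproduces the replicated power
#' experiment behind the plateau phenomenon: raw-data power climbs to 100%
#' as `e` grows, while quantile- and rank-normalized power levels off
#' strictly below it.
#'
#' @param design Base [simu_design()]; `e_up`/`e_down` are overridden by
#'   the grid.  `design$seed` is the root seed; replicate `r` of effect
#'   size `k` runs with seed `seed + (k - 1) * n_replicates + r`.
#' @param e_grid Numeric vector of non-negative effect sizes.
#' @param methods Normalization labels to compare.
#' @param tests Test labels to compare.
#' @param n_replicates Replicates per effect size (at least 2).
#' @param alpha Family-wise significance level.
#' @param n_perm Permutations for the energy test.
#' @return A `power_summary` tibble: one row per (`e`, `method`, `test`)
#'   with `tp_mean`, `tp_sd`, `fp_mean`, `fp_sd`, `n_replicates`, `m1`,
#'   `m0`.
#' @export
power_curve <- function(design, e_grid = seq(0.2, 3.6, by = 0.2),
                        methods = c("none", "quant", "rank"),
                        tests = "t", n_replicates = 20, alpha = 0.05,
                        n_perm = 1000) {
  stopifnot(inherits(design, "simu_design"), n_replicates >= 2,
            all(e_grid >= 0))
  m1 <- design$m1_up + design$m1_down
  m0 <- design$m - m1
  rows <- list()
  for (k in seq_along(e_grid)) {
    d_e <- design_with_effect(design, e_grid[k])
    counts <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      d_r <- design_with_seed(d_e, replicate_seed(design$seed, k, r,
                                                  n_replicates))
      if (is.null(design$seed)) d_r$seed <- NULL
      dataset <- simulate_simu(d_r)
      counts[[r]] <- purrr::map_dfr(methods, function(mth) {
        norm <- normalize_expression(dataset, mth)
        purrr::map_dfr(tests, function(tst) {
          tab <- adjust_gene_pvalues(test_genes(norm, tst,
                                                n_perm = n_perm),
                                     "bonferroni", alpha)
          dplyr::mutate(confusion_counts(tab$rejected, tab$truth),
                        method = mth, test = tst)
        })
      })
    }
    rows[[k]] <- dplyr::bind_rows(counts) |>
      dplyr::group_by(.data$method, .data$test) |>
      dplyr::summarise(tp_mean = mean(.data$tp),
                       tp_sd = stats::sd(.data$tp),
                       fp_mean = mean(.data$fp),
                       fp_sd = stats::sd(.data$fp),
                       .groups = "drop") |>
      dplyr::mutate(e = e_grid[k], .before = 1)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(n_replicates = n_replicates, m1 = m1, m0 = m0)
  class(out) <- c("power_summary", class(out))
  out
}

# Pool |t| statistics of true DEGs over replicates for one (e, method).
pooled_deg_abs_t <- function(design, methods, n_replicates, k_offset = 0) {
  out <- stats::setNames(vector("list", length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    d_r <- design_with_seed(design,
                            replicate_seed(design$seed, k_offset + 1, r,
                                           n_replicates))
    if (is.null(design$seed)) d_r$seed <- NULL
    dataset <- simulate_simu(d_r)
    for (mth in methods) {
      tab <- t_test_genes(normalize_expression(dataset, mth))
      out[[mth]][[r]] <- tab$statistic[tab$truth != "NDEG"]
    }
  }
  lapply(out, unlist)
}

#' Median absolute t-statistic as a function of effect size
#'
#' For each effect size, pools the t-statistics of all true DEGs across
#' replicates and reports the median of their absolute values, separately
#' per normalization method.  On raw data the median grows linearly in
#' `e`; after quantile normalization it is bounded, the signature of the
#' power plateau.
#'
#' @inheritParams power_curve
#' @param n_replicates Replicates per effect size (default 200).
#' @return A `median_t_curve` tibble: one row per (`e`, `method`) with
#'   `median_abs_t` and `n_replicates`.
#' @export
median_abs_t_curve <- function(design, e_grid = seq(0, 3.6, by = 0.2),
                               methods = c("none", "quant"),
                               n_replicates = 200) {
  stopifnot(inherits(design, "simu_design"), all(e_grid >= 0))
  rows <- list()
  for (k in seq_along(e_grid)) {
    d_e <- design_with_effect(design, e_grid[k])
    pooled <- pooled_deg_abs_t(d_e, methods, n_replicates,
                               k_offset = k - 1)
    rows[[k]] <- tibble::tibble(
      e = e_grid[k],
      method = methods,
      median_abs_t = vapply(pooled,
                            function(t) stats::median(abs(t)), 0),
      n_replicates = n_replicates
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("median_t_curve", class(out))
  out
}

#' Kernel density estimates of DEG t-statistics
#'
#' Pools the t-statistics of all true DEGs across replicates and returns a
#' Gaussian-kernel density estimate (Silverman's rule-of-thumb bandwidth)
#' per normalization method and effect size.  After quantile normalization
#' at large `e` the density is multimodal: interior modes near zero from
#' the doubly noncentral t component, outer modes from the noncentral
#' component.
#'
#' @inheritParams power_curve
#' @param e_values Effect sizes at which to estimate densities.
#' @param n_replicates Replicates pooled per estimate (at least 50).
#' @param n_grid Number of grid points of the density estimate.
#' @return A `t_density` tibble: one row per grid point with columns `e`,
#'   `method`, `x`, `density`, `n_replicates`.
#' @export
t_density_estimate <- function(design, e_values = c(0, 2, 4),
                               methods = c("none", "quant"),
                               n_replicates = 200, n_grid = 512) {
  stopifnot(inherits(design, "simu_design"), n_replicates >= 50)
  rows <- list()
  for (k in seq_along(e_values)) {
    d_e <- design_with_effect(design, e_values[k])
    pooled <- pooled_deg_abs_t(d_e, methods, n_replicates,
                               k_offset = k - 1)
    rows[[k]] <- purrr::map_dfr(methods, function(mth) {
      dens <- stats::density(pooled[[mth]], bw = "nrd0", n = n_grid)
      tibble::tibble(e = e_values[k], method = mth, x = dens$x,
                     density = dens$y, n_replicates = n_replicates)
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("t_density", class(out))
  out
}

#' Locate the modes of a density estimate
#'
#' Finds local maxima of a gridded density whose height exceeds
#' `min_height` times the global maximum; used to characterize the mixture
#' structure of normalized t-statistics (interior vs outer modes).
#'
#' @param density_tbl Tibble with `x` and `density` columns (one
#'   (`e`, `method`) cell of [t_density_estimate()]).
#' @param min_height Minimum relative height of a reported mode.
#' @return Tibble with columns `x` (mode location) and `density`.
#' @export
density_modes <- function(density_tbl, min_height = 0.05) {
  stopifnot(all(c("x", "density") %in% names(density_tbl)))
  y <- density_tbl$density
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  keep <- is_peak & y >= min_height * max(y)
  tibble::tibble(x = density_tbl$x[keep], density = y[keep])
}

#' Empirical family-wise error rate under the global null
#'
#' Simulates `n_replicates` null datasets (no gene is shifted), runs the
#' normalize-test-adjust pipeline on each, and reports the fraction of
#' replicates with at least one (necessarily false) rejection, together
#' with its binomial standard error.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of null replicates.
#' @return A one-row tibble: `fwer`, `se`, `n_replicates`, `alpha`,
#'   `method`, `test`.
#' @export
estimate_fwer <- function(design, n_replicates = 200, method = "none",
                          test = "t", alpha = 0.05, n_perm = 1000) {
  stopifnot(inherits(design, "simu_design"))
  if (design$e_up != 0 || design$e_down != 0) {
    stop("`estimate_fwer` requires a null design (e_up = e_down = 0).",
         call. = FALSE)
  }
  any_rej <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    d_r <- design_with_seed(design, replicate_seed(design$seed, 1, r,
                                                   n_replicates))
    if (is.null(design$seed)) d_r$seed <- NULL
    res <- run_replicate(d_r, method = method, test = test,
                         alpha = alpha, n_perm = n_perm)
    any_rej[r] <- (res$counts$tp + res$counts$fp) > 0
  }
  fwer <- mean(any_rej)
  tibble::tibble(fwer = fwer,
                 se = sqrt(fwer * (1 - fwer) / n_replicates),
                 n_replicates = n_replicates, alpha = alpha,
                 method = method, test = test)
}
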