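#' Draw equicorrelated normal noise
#'
#' Generates an `m x n_total` matrix in which every entry is marginally
#' `Normal(0, sigma^2)` and, within each column (array), every pair of
#' distinct rows (genes) has population correlation `rho`.  Columns are
#' mutually independent.  The construction is the exact single-factor
#' representation of an equicorrelation matrix: per column `j` a shared
#' standard-normal factor `Z_j` is drawn along with independent gene noise
#' `eps_ij`, and the entry is `sigma * (sqrt(rho) * Z_j +
#' sqrt(1 - rho) * eps_ij)`.
#'
#' Uses the current R random number generator; call `set.seed()` (or supply
#' a seed through [simu_design()]) for reproducibility.
#'
#' @param m Number of genes (rows); `>= 1`.
#' @param n_total Number of arrays (columns); `>= 1`.
#' @param sigma Marginal standard deviation; `> 0`.
#' @param rho Common within-array gene-gene correlation, in `[0, 1)`.
#'
#' @return An `m x n_total` numeric matrix.
#' @examples
#' set.seed(1)
#' x <- equicorrelated_noise(5, 4, sigma = 0.35, rho = 0.9)
#' @export
equicorrelated_noise <- function(m, n_total, sigma, rho) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 ||
      !is.numeric(n_total) || length(n_total) != 1 || n_total < 1) {
    stop("`m` and `n_total` must be positive integers.", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be positive.", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1).", call. = FALSE)
  }
  m <- as.integer(m)
  n_total <- as.integer(n_total)
  z <- stats::rnorm(n_total)                    # shared factor per array
  eps <- matrix(stats::rnorm(m * n_total), nrow = m)
  sigma * (sqrt(rho) * matrix(z, nrow = m, ncol = n_total, byrow = TRUE) +
             sqrt(1 - rho) * eps)
}

# Truth labels implied by a design: first m1_up genes UP, next m1_down
# DOWN, remainder NDEG.
design_truth <- function(m, m1_up, m1_down) {
  rep(c("UP", "DOWN", "NDEG"), c(m1_up, m1_down, m - m1_up - m1_down))
}

#' Simulate an equicorrelated two-group expression dataset
#'
#' Generates the synthetic design used throughout the power experiments:
#' `m` genes on `2n` arrays, equicorrelated Gaussian noise with standard
#' deviation `sigma` and pairwise correlation `rho`, plus a constant mean
#' shift in group A for the differentially expressed genes (`+e_up` for the
#' first `m1_up` genes, `e_down` for the next `m1_down`).  Group B means
#' are zero for all genes; every downstream test is shift-invariant, so
#' this loses no generality.
#'
#' @param design A [simu_design()].  If `design$seed` is non-`NULL` the RNG
#'   is seeded before drawing, making the dataset reproducible.
#'
#' @return An [expr_dataset()] with `method = "NONE"`, group-A columns
#'   first, and truth labels in UP/DOWN/NDEG block order.
#' @examples
#' ds <- simulate_simu(simu_design(m = 100, m1_up = 6, m1_down = 4, n = 5,
#'                                 e_up = 2, e_down = -2, seed = 1))
#' @export
simulate_simu <- function(design) {
  stopifnot(inherits(design, "simu_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  values <- equicorrelated_noise(design$m, 2L * design$n,
                                 design$sigma, design$rho)
  truth <- design_truth(design$m, design$m1_up, design$m1_down)
  group <- rep(c("A", "B"), each = design$n)
  shift <- c(rep(design$e_up, design$m1_up),
             rep(design$e_down, design$m1_down),
             rep(0, design$m - design$m1_up - design$m1_down))
  values[, group == "A"] <- values[, group == "A"] + shift
  expr_dataset(values, group, truth, method = "NONE")
}

#' Simulate a dataset with heterogeneous per-gene effect sizes
#'
#' A stand-in for resampling-based designs in which each differentially
#' expressed gene carries its own recorded effect size rather than a shared
#' constant.  The group-A mean shift of gene `i` is
#' `gene_effects[i] + sign(gene_effects[i]) * extra_effect`; truth labels
#' follow the sign of `gene_effects` (positive = UP, negative = DOWN,
#' zero = NDEG).  Noise is the same equicorrelated Gaussian model as
#' [simulate_simu()].
#'
#' @param design A [simu_design()]; its `m1_up`, `m1_down`, `e_up`,
#'   `e_down` fields are ignored (the effect profile defines them).
#' @param gene_effects Numeric vector of length `design$m` of per-gene
#'   effect sizes.
#' @param extra_effect Non-negative scalar added on top of each DEG's
#'   effect, in the direction of its regulation.
#'
#' @return An [expr_dataset()] with `method = "NONE"`.
#' @seealso [random_gene_effects()] for a convenience effect profile.
#' @export
simulate_bio_like <- function(design, gene_effects, extra_effect = 0) {
  stopifnot(inherits(design, "simu_design"))
  if (!is.numeric(gene_effects) || length(gene_effects) != design$m) {
    stop("`gene_effects` must be numeric of length `design$m`.",
         call. = FALSE)
  }
  if (!is.numeric(extra_effect) || length(extra_effect) != 1 ||
      extra_effect < 0) {
    stop("`extra_effect` must be a non-negative scalar.", call. = FALSE)
  }
  if (!is.null(design$seed)) set.seed(design$seed)
  values <- equicorrelated_noise(design$m, 2L * design$n,
                                 design$sigma, design$rho)
  truth <- c("DOWN", "NDEG", "UP")[sign(gene_effects) + 2]
  group <- rep(c("A", "B"), each = design$n)
  shift <- gene_effects + sign(gene_effects) * extra_effect
  values[, group == "A"] <- values[, group == "A"] + shift
  expr_dataset(values, group, truth, method = "NONE")
}

#' Draw a random heterogeneous effect-size profile
#'
#' Convenience generator for [simulate_bio_like()]: `m1_up` positive and
#' `m1_down` negative effects with magnitudes `|Normal(mean, sd)|`, placed
#' in block order (UP genes first, then DOWN, then zeros).
#'
#' @param m Total gene count.
#' @param m1_up,m1_down Numbers of up- and down-regulated genes.
#' @param mean,sd Location and spread of the normal law whose absolute
#'   value supplies effect magnitudes.
#' @return Numeric vector of length `m`.
#' @export
random_gene_effects <- function(m, m1_up, m1_down, mean = 0.5, sd = 0.25) {
  stopifnot(m1_up + m1_down <= m)
  mags <- abs(stats::rnorm(m1_up + m1_down, mean = mean, sd = sd))
  c(mags[seq_len(m1_up)],
    -mags[m1_up + seq_len(m1_down)],
    rep(0, m - m1_up - m1_down))
}
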