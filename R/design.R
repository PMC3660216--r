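#' Describe a simulated two-group expression experiment
#'
#' A `simu_design` collects every tuning parameter of a simulated
#' microarray-style experiment: `m` genes are measured on `n` arrays per
#' phenotype group (A = condition of interest, B = reference), log2
#' expressions are equicorrelated normals with per-gene standard deviation
#' `sigma` and common pairwise correlation `rho`, and the first
#' `m1_up + m1_down` genes carry constant mean shifts in group A (`e_up` for
#' up-regulated genes, `e_down` for down-regulated ones).  Setting
#' `e_up = e_down = 0` encodes the global null.
#'
#' @param m Total number of genes.
#' @param m1_up Number of up-regulated genes.
#' @param m1_down Number of down-regulated genes.
#' @param n Arrays per group (the design is balanced).
#' @param sigma Per-gene standard deviation on the log2 scale; must be
#'   positive.
#' @param rho Common pairwise gene-gene correlation, in `[0, 1)`.
#' @param e_up Effect size (expected A - B mean difference) of up-regulated
#'   genes; must be `>= 0`.
#' @param e_down Effect size of down-regulated genes; must be `<= 0`.
#' @param seed Integer seed for the random number generator, or `NULL` to
#'   use the current RNG state.
#'
#' @return An object of class `simu_design` (a named list of the validated
#'   parameters).
#' @examples
#' simu_design(m = 1000, m1_up = 60, m1_down = 40, n = 10,
#'             e_up = 2, e_down = -2, seed = 1)
#' @export
simu_design <- function(m = 1000, m1_up = 60, m1_down = 40, n = 10,
                        sigma = 0.35, rho = 0.9,
                        e_up = 0, e_down = 0, seed = NULL) {
  stopifnot(
    is.numeric(m), length(m) == 1, m >= 1, m == as.integer(m),
    is.numeric(m1_up), length(m1_up) == 1, m1_up >= 0,
    m1_up == as.integer(m1_up),
    is.numeric(m1_down), length(m1_down) == 1, m1_down >= 0,
    m1_down == as.integer(m1_down),
    is.numeric(n), length(n) == 1, n >= 2, n == as.integer(n)
  )
  if (m1_up + m1_down > m) {
    stop("`m1_up + m1_down` cannot exceed `m`.", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a positive scalar.", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1).", call. = FALSE)
  }
  if (!is.numeric(e_up) || length(e_up) != 1 || e_up < 0) {
    stop("`e_up` must be a non-negative scalar.", call. = FALSE)
  }
  if (!is.numeric(e_down) || length(e_down) != 1 || e_down > 0) {
    stop("`e_down` must be a non-positive scalar.", call. = FALSE)
  }
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, seed == as.integer(seed))
    seed <- as.integer(seed)
  }
  structure(
    list(m = as.integer(m), m1_up = as.integer(m1_up),
         m1_down = as.integer(m1_down), n = as.integer(n),
         sigma = sigma, rho = rho, e_up = e_up, e_down = e_down,
         seed = seed),
    class = "simu_design"
  )
}

#' @export
print.simu_design <- function(x, ...) {
  cat("Simulated expression design\n")
  cat(sprintf("  genes:        m = %d (%d up, %d down, %d null)\n",
              x$m, x$m1_up, x$m1_down, x$m - x$m1_up - x$m1_down))
  cat(sprintf("  arrays:       n = %d per group (A, B)\n", x$n))
  cat(sprintf("  noise:        sigma = %g, rho = %g\n", x$sigma, x$rho))
  cat(sprintf("  effect sizes: e_up = %g, e_down = %g\n", x$e_up, x$e_down))
  cat(sprintf("  seed:         %s\n",
              if (is.null(x$seed)) "<current RNG>" else x$seed))
  invisible(x)
}

# Replace the seed of a design (used to derive per-replicate streams).
design_with_seed <- function(design, seed) {
  design$seed <- if (is.null(seed)) NULL else as.integer(seed)
  design
}

# Replace the effect sizes symmetrically: e_up = e, e_down = -e.
design_with_effect <- function(design, e) {
  stopifnot(e >= 0)
  design$e_up <- e
  design$e_down <- -e
  design
}
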