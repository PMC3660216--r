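#' Central, noncentral and doubly noncentral t densities
#'
#' `t_density_central()` and `t_density_noncentral()` are thin wrappers
#' around [stats::dt()].  `t_density_doubly_noncentral()` evaluates the
#' density of \deqn{T = (Z + \gamma) / \sqrt{\chi^2_\nu(\lambda)/\nu},}
#' with standard-normal `Z` independent of the noncentral chi-square
#' denominator, by one-dimensional numerical integration of the
#' conditional normal density against the noncentral chi-square density.
#' This is the law governing normalized DEG t-statistics at large effect
#' sizes, where the mean shift leaks into the denominator as the
#' noncentrality `lambda`.
#'
#' @param x Numeric vector of evaluation points.
#' @param nu Degrees of freedom, `>= 1`.
#' @param gamma Numerator noncentrality parameter.
#' @param lambda Denominator (chi-square) noncentrality, `>= 0`.
#' @param abs_tol Absolute tolerance of the numerical integration.
#' @return Numeric vector of density values.
#' @examples
#' t_density_central(0, nu = 1)                      # 1/pi
#' t_density_doubly_noncentral(0, nu = 18, gamma = 5, lambda = 40)
#' @export
t_density_central <- function(x, nu) {
  if (!is.numeric(nu) || length(nu) != 1 || nu < 1) {
    stop("`nu` must be >= 1.", call. = FALSE)
  }
  stats::dt(x, df = nu)
}

#' @rdname t_density_central
#' @export
t_density_noncentral <- function(x, nu, gamma) {
  if (!is.numeric(nu) || length(nu) != 1 || nu < 1) {
    stop("`nu` must be >= 1.", call. = FALSE)
  }
  stats::dt(x, df = nu, ncp = gamma)
}

#' @rdname t_density_central
#' @export
t_density_doubly_noncentral <- function(x, nu, gamma, lambda,
                                        abs_tol = 1e-8) {
  if (!is.numeric(nu) || length(nu) != 1 || nu < 1) {
    stop("`nu` must be >= 1.", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("`lambda` must be >= 0.", call. = FALSE)
  }
  if (lambda == 0) return(stats::dt(x, df = nu, ncp = gamma))
  # f(t) = E_W[ dnorm(t; gamma*s(W), s(W)) ], s(w) = sqrt(nu/w), with the
  # expectation over the noncentral chi-square denominator.  Trapezoid
  # quadrature on the log-w scale over the interval holding all but 1e-14
  # of the chi-square mass per tail: there the integrand is smooth and
  # decays exponentially at both ends, so the rule converges fast for any
  # lambda (adaptive quadrature on the raw w scale loses the concentrated
  # chi-square bulk when lambda is large).  Node counts are doubled until
  # successive estimates agree within `abs_tol`.
  # endpoint quantiles need only locate the integration window, not full
  # precision, so the qnchisq precision warning is irrelevant here
  v_lo <- log(suppressWarnings(
    stats::qchisq(1e-14, df = nu, ncp = lambda)))
  v_hi <- log(suppressWarnings(
    stats::qchisq(1e-14, df = nu, ncp = lambda, lower.tail = FALSE)))
  estimate <- function(n_nodes) {
    v <- seq(v_lo, v_hi, length.out = n_nodes)   # v = log(w)
    w <- exp(v)
    s <- sqrt(nu / w)
    wt <- stats::dchisq(w, df = nu, ncp = lambda) * w * (v[2] - v[1])
    wt[c(1, n_nodes)] <- wt[c(1, n_nodes)] / 2   # trapezoid ends
    vapply(x, function(t) sum(stats::dnorm(t, mean = gamma * s,
                                           sd = s) * wt), 0)
  }
  n_nodes <- 2048L
  f <- estimate(n_nodes)
  repeat {
    n_nodes <- 2L * n_nodes
    f_new <- estimate(n_nodes)
    if (max(abs(f_new - f)) <= abs_tol) return(f_new)
    if (n_nodes >= 65536L) {
      stop(sprintf(
        "doubly noncentral t quadrature did not converge to %g (nu = %g, gamma = %g, lambda = %g, max change %g at %d nodes)",
        abs_tol, nu, gamma, lambda, max(abs(f_new - f)), n_nodes),
        call. = FALSE)
    }
    f <- f_new
  }
}

#' Mixture weights of normalized DEG t-statistics
#'
#' After quantile normalization, the t-statistic of a differentially
#' expressed gene follows a three-part mixture whose weights are the
#' probabilities that all `n` group-B ranks of the gene fall in the top
#' block (up-regulated ranks), the middle/opposite blocks, or are mixed.
#' For an up-regulated gene: central weight `(m1_up/m)^n`, noncentral
#' weight `(m0/m)^n + (m1_down/m)^n`, doubly noncentral weight the
#' remainder; mirrored for a down-regulated gene.
#'
#' @param m Total gene count.
#' @param m1_up,m1_down Up- and down-regulated gene counts.
#' @param n Arrays per group.
#' @param direction `"UP"` or `"DOWN"`: which DEG class the weights are
#'   for.
#' @return A one-row tibble with columns `w_central`, `w_noncentral`,
#'   `w_doubly` summing to 1.
#' @export
mixture_weights <- function(m, m1_up, m1_down, n,
                            direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  if (m1_up + m1_down > m || m < 1 || m1_up < 0 || m1_down < 0 || n < 1) {
    stop("inconsistent gene counts.", call. = FALSE)
  }
  m0 <- m - m1_up - m1_down
  own <- if (direction == "UP") m1_up else m1_down
  other <- if (direction == "UP") m1_down else m1_up
  w_central <- (own / m)^n
  w_noncentral <- (m0 / m)^n + (other / m)^n
  w_doubly <- 1 - w_central - w_noncentral
  tibble::tibble(w_central = w_central, w_noncentral = w_noncentral,
                 w_doubly = w_doubly)
}

#' Parameters of the mixture t distribution
#'
#' Bundles degrees of freedom, the numerator noncentrality `gamma`, the
#' denominator noncentrality `lambda` and the three mixture weights into a
#' `mixture_t_params` object for use with [mixture_density()].
#'
#' @param nu Degrees of freedom (`2n - 2` for a two-group design).
#' @param gamma Numerator noncentrality.
#' @param lambda Denominator noncentrality, `>= 0`.
#' @param weights Numeric vector or one-row tibble
#'   (`w_central`, `w_noncentral`, `w_doubly`), non-negative, summing
#'   to 1.
#' @param direction `"UP"` or `"DOWN"`.
#' @return An object of class `mixture_t_params`.
#' @export
mixture_t_params <- function(nu, gamma, lambda, weights,
                             direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  w <- unlist(weights, use.names = FALSE)
  if (length(w) != 3 || any(w < -1e-12) || abs(sum(w) - 1) > 1e-12) {
    stop("`weights` must be 3 non-negative values summing to 1.",
         call. = FALSE)
  }
  if (nu < 1) stop("`nu` must be >= 1.", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0.", call. = FALSE)
  structure(list(nu = nu, gamma = gamma, lambda = lambda,
                 weights = pmax(w, 0), direction = direction),
            class = "mixture_t_params")
}

#' @export
print.mixture_t_params <- function(x, ...) {
  cat(sprintf("Mixture t parameters (%s genes)\n", x$direction))
  cat(sprintf("  nu = %g, gamma = %g, lambda = %g\n",
              x$nu, x$gamma, x$lambda))
  cat(sprintf("  weights: central %.3g, noncentral %.3g, doubly %.3g\n",
              x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}

#' Tidy mixture t parameters
#'
#' @param x A [mixture_t_params()] object.
#' @param ... Unused.
#' @return A one-row tibble of the parameters and weights.
#' @method tidy mixture_t_params
#' @export
tidy.mixture_t_params <- function(x, ...) {
  tibble::tibble(direction = x$direction, nu = x$nu, gamma = x$gamma,
                 lambda = x$lambda, w_central = x$weights[1],
                 w_noncentral = x$weights[2], w_doubly = x$weights[3])
}

#' Density of the mixture t distribution
#'
#' Weighted sum of the central, noncentral and doubly noncentral t
#' densities with common degrees of freedom: the predicted law of
#' quantile-normalized DEG t-statistics.
#'
#' @param x Numeric vector of evaluation points.
#' @param params A [mixture_t_params()] object.
#' @return Numeric vector of density values.
#' @export
mixture_density <- function(x, params) {
  stopifnot(inherits(params, "mixture_t_params"))
  w <- params$weights
  out <- w[1] * t_density_central(x, params$nu) +
    w[2] * t_density_noncentral(x, params$nu, params$gamma)
  if (w[3] > 0) {
    out <- out + w[3] * t_density_doubly_noncentral(x, params$nu,
                                                    params$gamma,
                                                    params$lambda)
  }
  out
}

#' Calibrate mixture noncentralities from simulation
#'
#' The theory fixes `gamma` and `lambda` only up to proportionality in the
#' effect size, so for density overlays they are calibrated empirically:
#' the function simulates `n_replicates` quantile-normalized datasets,
#' classifies each DEG-replicate pair by where its group-B within-array
#' ranks fall (all in the gene's own block = central case; all in the
#' middle or the opposite block = noncentral; mixed = doubly noncentral),
#' and estimates
#' * the baseline per-observation standard deviation `sigma0` from the
#'   pooled sample variances of the noncentral cases (whose variance does
#'   not depend on the effect size under the rank-occupancy assumption),
#' * `gamma` as `sqrt(n/2)` times the mean normalized group difference of
#'   the noncentral cases divided by `sigma0`,
#' * `lambda` from the variance inflation of the mixed-rank ("doubly")
#'   cases: `(2n - 2) * (mean pooled variance / sigma0^2 - 1)`, truncated
#'   at zero.
#'
#' Weights are taken from the exact formula ([mixture_weights()]).
#'
#' @param design A [simu_design()] with non-zero effect sizes.
#' @param n_replicates Number of simulated replicates to pool.
#' @param direction Which DEG class to calibrate for.
#' @return A [mixture_t_params()] object.
#' @export
calibrate_mixture_params <- function(design, n_replicates = 200,
                                     direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  stopifnot(inherits(design, "simu_design"))
  n <- design$n
  m <- design$m
  genes <- if (direction == "UP") {
    seq_len(design$m1_up)
  } else {
    design$m1_up + seq_len(design$m1_down)
  }
  if (length(genes) == 0) {
    stop("the design has no genes in the requested direction.",
         call. = FALSE)
  }
  diffs_nc <- c()
  pooledvar_nc <- c()
  pooledvar_dbl <- c()
  for (r in seq_len(n_replicates)) {
    d_r <- design_with_seed(design, replicate_seed(design$seed, 1, r,
                                                   n_replicates))
    dataset <- simulate_simu(d_r)
    ib <- group_cols(dataset, "B")
    ia <- group_cols(dataset, "A")
    rank_b <- apply(dataset$values[, ib, drop = FALSE], 2, rank)
    norm <- quantile_normalize(dataset)
    va <- norm$values[genes, ia, drop = FALSE]
    vb <- norm$values[genes, ib, drop = FALSE]
    diff <- rowMeans(va) - rowMeans(vb)
    pooled_var <- (apply(va, 1, stats::var) +
                     apply(vb, 1, stats::var)) / 2
    rb <- rank_b[genes, , drop = FALSE]
    in_top <- rb > m - design$m1_up
    in_bottom <- rb <= design$m1_down
    in_middle <- !in_top & !in_bottom
    own <- if (direction == "UP") in_top else in_bottom
    all_own <- rowSums(own) == n
    all_mid <- rowSums(in_middle) == n
    all_opp <- rowSums(if (direction == "UP") in_bottom else in_top) == n
    noncentral <- all_mid | all_opp
    doubly <- !(all_own | noncentral)
    diffs_nc <- c(diffs_nc, diff[noncentral])
    pooledvar_nc <- c(pooledvar_nc, pooled_var[noncentral])
    pooledvar_dbl <- c(pooledvar_dbl, pooled_var[doubly])
  }
  if (length(diffs_nc) == 0 || length(pooledvar_nc) == 0) {
    stop("no noncentral-class cases observed; increase `n_replicates` ",
         "or the effect size.", call. = FALSE)
  }
  sigma0 <- sqrt(mean(pooledvar_nc))
  gamma <- sqrt(n / 2) * mean(diffs_nc) / sigma0
  lambda <- if (length(pooledvar_dbl) > 0) {
    max(0, (2 * n - 2) * (mean(pooledvar_dbl) / sigma0^2 - 1))
  } else {
    0
  }
  w <- mixture_weights(m, design$m1_up, design$m1_down, n, direction)
  mixture_t_params(nu = 2 * n - 2, gamma = gamma, lambda = lambda,
                   weights = w, direction = direction)
}

#' Expected rank-normalized group difference at large effect size
#'
#' In the large-effect limit, up-regulated genes occupy the top `m1_up`
#' ranks in every group-A array while their group-B ranks stay uniform, so
#' the expected A - B difference of fractional ranks converges to
#' `1/2 - m1_up/(2m)` (mirrored for down-regulated genes).
#'
#' @inheritParams mixture_weights
#' @return Scalar expected difference.
#' @examples
#' rank_expected_difference(1000, 60, 40, "UP")    # 0.47
#' rank_expected_difference(1000, 60, 40, "DOWN")  # -0.48
#' @export
rank_expected_difference <- function(m, m1_up, m1_down,
                                     direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  stopifnot(m >= 1, m1_up >= 0, m1_down >= 0, m1_up + m1_down <= m)
  if (direction == "UP") 1 / 2 - m1_up / (2 * m) else
    m1_down / (2 * m) - 1 / 2
}

#' Limiting support of rank-normalized expressions
#'
#' In the large-effect limit the fractional ranks of each gene class are
#' approximately uniform on a sub-interval of `[0, 1]`: group-B values on
#' the whole interval, group-A up-regulated genes on the top `m1_up/m`
#' fraction, down-regulated genes on the bottom `m1_down/m` fraction, and
#' null genes in between.
#'
#' @param gene_class `"UP"`, `"DOWN"` or `"NDEG"`.
#' @param group `"A"` or `"B"`.
#' @inheritParams mixture_weights
#' @return A one-row tibble with columns `gene_class`, `group`, `lower`,
#'   `upper`.
#' @export
rank_asymptotic_support <- function(gene_class = c("UP", "DOWN", "NDEG"),
                                    group = c("A", "B"),
                                    m, m1_up, m1_down) {
  gene_class <- match.arg(gene_class)
  group <- match.arg(group)
  stopifnot(m >= 1, m1_up >= 0, m1_down >= 0, m1_up + m1_down <= m)
  if (group == "B") {
    lims <- c(0, 1)
  } else {
    lims <- switch(gene_class,
                   UP = c(1 - m1_up / m, 1),
                   DOWN = c(0, m1_down / m),
                   NDEG = c(m1_down / m, 1 - m1_up / m))
  }
  tibble::tibble(gene_class = gene_class, group = group,
                 lower = lims[1], upper = lims[2])
}
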