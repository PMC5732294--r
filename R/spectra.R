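# Binned energy spectra (log-spaced wavenumber levels), repertoire
# distributions normalized by the baseline maximum, and energy probability
# distributions with the characteristic energy E*.

#' Quantize the harmonic spectrum into log-spaced wavenumber levels
#'
#' Bin edges are `10^linspace(log10(1), log10(m), n_levels + 1)`; harmonic
#' `k` falls in the unique half-open bin `[edge_i, edge_{i+1})`, the last
#' bin closed. Per-bin energy is the sum (default) or mean of the member
#' harmonics' time-averaged energies.
#'
#' @param energy an `energy_tensor`.
#' @param n_levels number of levels (default 15).
#' @param mode `"sum"` (conserves the spectrum total) or `"mean"`.
#' @return object of class `binned_spectrum`: `edges`, `bin_of_k`,
#'   `values` (length `n_levels`), `counts`, `mode`.
#' @export
quantize_spectrum <- function(energy, n_levels = 15, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (n_levels < 2) chd_input_error("n_levels must be >= 2")
  m <- length(energy$lambda)
  if (m < n_levels) chd_input_error("need at least as many harmonics (%d) as levels (%d)",
                                    m, n_levels)
  edges <- 10^seq(0, log10(m), length.out = n_levels + 1)
  bin_of_k <- findInterval(seq_len(m), edges, rightmost.closed = TRUE)
  per_k <- energy$mean_k
  values <- vapply(seq_len(n_levels), function(b) {
    v <- per_k[bin_of_k == b]
    if (length(v) == 0) 0 else if (mode == "sum") sum(v) else mean(v)
  }, numeric(1))
  structure(list(edges = edges, bin_of_k = bin_of_k, values = values,
                 counts = tabulate(bin_of_k, n_levels), mode = mode),
            class = "binned_spectrum")
}

#' @keywords internal
fit_gaussian_histogram <- function(mids, density) {
  if (all(density == 0)) chd_input_error("degenerate histogram: no mass")
  p <- density / sum(density)
  mu0 <- sum(mids * p)
  s0 <- sqrt(sum((mids - mu0)^2 * p))
  if (!is.finite(s0) || s0 <= 0) chd_input_error("degenerate histogram: zero width")
  a0 <- max(density)
  obj <- function(par) {
    a <- par[1]; mu <- par[2]; s <- exp(par[3])
    sum((density - a * exp(-(mids - mu)^2 / (2 * s^2)))^2)
  }
  fit <- stats::optim(c(a0, mu0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(height = fit$par[1], mu = fit$par[2], sigma = exp(fit$par[3]),
       sse = fit$value)
}

#' Repertoire distribution of baseline-normalized projection values
#'
#' Every coefficient `alpha_k(t)` is divided by the maximum of `|alpha_k|`
#' over all baseline-condition scans (pooled); harmonics whose baseline
#' maximum is zero are excluded with a count. The pooled normalized values
#' of each condition are histogrammed (common breaks across conditions) and
#' a Gaussian density is least-squares fitted, giving the height `mu-height`
#' at the peak and the width `sigma` — the repertoire breadth.
#'
#' @param coeffs_by_condition named list; each element a `spectral_coeffs`,
#'   an alpha matrix, or a list of either (multiple scans).
#' @param baseline name of the baseline (e.g. placebo) condition.
#' @param n_bins histogram bins (default 100).
#' @return named list of fits, one per condition; each of class
#'   `distribution_fit` with `breaks`, `mids`, `prob`, `density`, `mu`,
#'   `sigma`, `height`, `n_values`, `n_excluded`.
#' @export
repertoire_distribution <- function(coeffs_by_condition, baseline,
                                    n_bins = 100) {
  if (!baseline %in% names(coeffs_by_condition))
    chd_input_error("baseline condition '%s' not present", baseline)
  as_alpha_list <- function(x) {
    if (inherits(x, "spectral_coeffs")) list(x$alpha)
    else if (is.matrix(x)) list(x)
    else lapply(x, function(s) if (inherits(s, "spectral_coeffs")) s$alpha else as.matrix(s))
  }
  cond <- lapply(coeffs_by_condition, as_alpha_list)
  base_max <- do.call(pmax, lapply(cond[[baseline]], function(a) apply(abs(a), 1, max)))
  keep <- base_max > 0
  n_excluded <- sum(!keep)
  if (!any(keep)) chd_input_error("all harmonics have zero baseline maximum")
  pooled <- lapply(cond, function(scans)
    unlist(lapply(scans, function(a) a[keep, , drop = FALSE] / base_max[keep]),
           use.names = FALSE))
  rng <- range(unlist(pooled))
  if (diff(rng) == 0) chd_input_error("degenerate coefficients: zero range")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  lapply(pooled, function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    prob <- h$counts / sum(h$counts)
    g <- fit_gaussian_histogram(h$mids, h$density)
    structure(list(breaks = breaks, mids = h$mids, prob = prob,
                   density = h$density, mu = g$mu, sigma = g$sigma,
                   height = g$height, n_values = length(v),
                   n_excluded = n_excluded),
              class = "distribution_fit")
  })
}

#' Probability distribution of total energy and characteristic energy E*
#'
#' Normalized histogram of pooled `E_total(t)` values; `E*` is the center of
#' the maximum-probability bin and `Pr(E*)` its probability.
#'
#' @param e_total numeric vector of total-energy values (or an
#'   `energy_tensor`, whose `total_t` is used).
#' @param n_bins histogram bins (default 100).
#' @return a `distribution_fit`-like list with `mids`, `prob`, `e_star`,
#'   `p_star`.
#' @export
energy_distribution <- function(e_total, n_bins = 100) {
  if (inherits(e_total, "energy_tensor")) e_total <- e_total$total_t
  e_total <- as.numeric(e_total)
  if (length(e_total) < 30) chd_input_error("need at least 30 samples")
  if (length(e_total) < n_bins)
    chd_input_error("fewer samples (%d) than bins (%d)", length(e_total), n_bins)
  if (diff(range(e_total)) == 0) {
    return(structure(list(mids = e_total[1], prob = 1,
                          e_star = e_total[1], p_star = 1),
                     class = "distribution_fit"))
  }
  h <- graphics::hist(e_total, breaks = seq(min(e_total), max(e_total),
                                            length.out = n_bins + 1),
                      plot = FALSE)
  prob <- h$counts / sum(h$counts)
  i <- which.max(prob)
  structure(list(mids = h$mids, prob = prob,
                 e_star = h$mids[i], p_star = prob[i]),
            class = "distribution_fit")
}

#' Per-bin energy contrast between two conditions
#'
#' Subject-level binned energies of a paired two-condition design are
#' compared bin by bin with the paired permutation test
#' ([permutation_test()]) and Bonferroni correction across bins.
#'
#' @param binned_a,binned_b numeric subjects x bins matrices (same subjects,
#'   same row order).
#' @param n_perm permutations per bin.
#' @param seed RNG seed.
#' @param alpha significance level after correction (default 0.01).
#' @return data.frame with columns `bin`, `delta` (mean b - a), `p`,
#'   `p_adj`, `significant`.
#' @export
condition_energy_contrast <- function(binned_a, binned_b, n_perm = 10000,
                                      seed = 1, alpha = 0.01) {
  binned_a <- as.matrix(binned_a); binned_b <- as.matrix(binned_b)
  if (!all(dim(binned_a) == dim(binned_b)))
    chd_input_error("condition tables must be subject-paired with equal shape")
  L <- ncol(binned_a)
  seeds <- derive_seeds(seed, L)
  res <- lapply(seq_len(L), function(b) {
    pt <- permutation_test(binned_b[, b], binned_a[, b],
                           n_perm = n_perm, seed = seeds[b])
    c(delta = pt$statistic, p = pt$p)
  })
  delta <- vapply(res, `[[`, numeric(1), "delta")
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- bonferroni(p, L)
  data.frame(bin = seq_len(L), delta = delta, p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}
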