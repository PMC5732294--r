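# Statistical machinery shared by the analysis modules: two-sample t and KS
# tests, paired-design permutation testing (exhaustive when feasible, else
# Monte-Carlo with the add-one rule), Bonferroni correction, Cohen's d,
# energy-rating Pearson correlation, and multiple correlation (direct and
# harmonic-mediated indirect variants).

#' Two-sample t-test (equal variances)
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list of class `condition_comparison`: `statistic` (t), `p`
#'   (two-sided), `df`, `n` (group sizes).
#' @export
ttest2 <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) chd_input_error("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(statistic = 0, p = 1, df = length(a) + length(b) - 2,
                            n = c(length(a), length(b)), degenerate = TRUE),
                       class = "condition_comparison"))
    return(structure(list(statistic = Inf * sign(mean(a) - mean(b)), p = 0,
                          df = length(a) + length(b) - 2,
                          n = c(length(a), length(b)), degenerate = TRUE),
                     class = "condition_comparison"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(statistic = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), n = c(length(a), length(b))),
            class = "condition_comparison")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b numeric vectors, each of length >= 5.
#' @return `condition_comparison` with `statistic` (D, sup of the ECDF
#'   difference) and asymptotic two-sided `p`.
#' @export
kstest2 <- function(a, b) {
  if (length(a) < 5 || length(b) < 5) chd_input_error("each group needs >= 5 values")
  ks <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(ks$statistic), p = ks$p.value,
                 n = c(length(a), length(b))),
            class = "condition_comparison")
}

#' Paired permutation test on the mean difference
#'
#' The null is built by flipping condition labels within subject. When all
#' `2^n` sign patterns number no more than `n_perm` the test enumerates them
#' exhaustively (exact p); otherwise `n_perm` random flips are drawn and the
#' add-one rule `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)` applies, so p
#' never falls below `1/(n_perm + 1)`.
#'
#' @param a,b paired numeric vectors (same subjects, same order).
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param seed RNG seed (only used on the Monte-Carlo path).
#' @return `condition_comparison` with `statistic` (mean of a - b), `p`,
#'   `n`, `method` ("exhaustive" or "monte-carlo"), `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = 1) {
  if (n_perm < 100) chd_input_error("n_perm must be >= 100")
  if (length(a) != length(b)) chd_input_error("paired groups must have equal length")
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  tol <- 1e-12 * max(1, abs(obs))
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- abs(as.numeric(signs %*% d) / n)
    p <- sum(null >= abs(obs) - tol) / nrow(signs)
    method <- "exhaustive"; used <- nrow(signs)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null <- abs(as.numeric(signs %*% d) / n)
    p <- (1 + sum(null >= abs(obs) - tol)) / (n_perm + 1)
    method <- "monte-carlo"; used <- n_perm
  }
  structure(list(statistic = obs, p = p, n = n, method = method,
                 n_perm = used),
            class = "condition_comparison")
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values.
#' @param k number of simultaneous tests (>= length(p)).
#' @return adjusted p-values, `min(1, p * k)`.
#' @export
bonferroni <- function(p, k = length(p)) {
  if (k < length(p)) chd_input_error("k must be at least the number of tests")
  pmin(1, p * k)
}

#' Cohen's d effect size
#'
#' `(mean(a) - mean(b)) / s_pooled` with the (n - 1)-weighted pooled
#' standard deviation.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return numeric d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) chd_input_error("each group needs >= 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) chd_input_error("zero pooled standard deviation: effect size undefined")
  (mean(a) - mean(b)) / sp
}

#' Correlation of per-scan energy changes with subjective ratings
#'
#' Pearson correlation between a vector of per subject-scan energy changes
#' (e.g. `delta Ebar` or `delta sigma(E)` over a wavenumber range) and a
#' rating column, with a two-sided p-value.
#'
#' @param energy_changes numeric vector, one value per subject-scan.
#' @param ratings numeric vector of the same length.
#' @return `condition_comparison` with `statistic` (r) and `p`.
#' @export
energy_rating_correlation <- function(energy_changes, ratings) {
  if (length(energy_changes) != length(ratings))
    chd_input_error("energy changes and ratings must be matched")
  if (length(ratings) < 4) chd_input_error("need at least 4 pairs")
  ct <- stats::cor.test(energy_changes, ratings, method = "pearson")
  structure(list(statistic = unname(ct$estimate), p = ct$p.value,
                 n = length(ratings)),
            class = "condition_comparison")
}

#' Multiple correlation coefficient
#'
#' `R = sqrt(c' Rxx^{-1} c)` with `c` the simple correlations of each
#' predictor with the response and `Rxx` the predictor intercorrelation
#' matrix; identical to the square root of the OLS R^2. Significance from
#' the F statistic for R^2 with `(q, n - q - 1)` degrees of freedom.
#'
#' @param predictors numeric n x q matrix (observations x predictors).
#' @param response numeric length-n vector.
#' @return list of class `condition_comparison`: `statistic` (R), `R2`,
#'   `p`, `F`, `df`.
#' @export
multiple_correlation <- function(predictors, response) {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  n <- nrow(X); q <- ncol(X)
  if (length(y) != n) chd_input_error("response length must match predictor rows")
  if (n <= q + 1) chd_input_error("need more observations (%d) than predictors + 1 (%d)",
                                  n, q + 1)
  Rxx <- stats::cor(X)
  cvec <- as.numeric(stats::cor(X, y))
  sol <- tryCatch(solve(Rxx, cvec),
                  error = function(e) chd_input_error(
                    "singular predictor correlation matrix (collinearity)"))
  R2 <- sum(cvec * sol)
  R2 <- min(max(R2, 0), 1)
  Fst <- if (R2 >= 1) Inf else (R2 / q) / ((1 - R2) / (n - q - 1))
  p <- stats::pf(Fst, q, n - q - 1, lower.tail = FALSE)
  structure(list(statistic = sqrt(R2), R2 = R2, F = Fst, p = p,
                 df = c(q, n - q - 1), n = n),
            class = "condition_comparison")
}

#' Indirect (harmonic-mediated) multiple correlation
#'
#' Each observation-space vector (a network connectivity-change vector and
#' the rating vector, one value per subject-scan) is first re-represented as
#' its vector of Pearson correlations with the per-harmonic energy-change
#' vectors; the multiple correlation is then computed over these
#' harmonic-correlate representations, whose dimension (`n_harmonics`) plays
#' the role of the sample dimension. A warning is attached: harmonic
#' correlates are not independent samples, so the p-value is the procedure's
#' nominal value, not a calibrated error rate.
#'
#' @param rsn_changes numeric n_obs x q matrix, one column per network.
#' @param ratings numeric length-n_obs vector.
#' @param energy_changes numeric n_obs x n_harmonics matrix of per-harmonic
#'   energy-change vectors.
#' @param n_harmonics how many harmonic columns to use (default all).
#' @return `condition_comparison` as in [multiple_correlation()], with the
#'   `warning` field set.
#' @export
indirect_multiple_correlation <- function(rsn_changes, ratings,
                                          energy_changes,
                                          n_harmonics = ncol(energy_changes)) {
  X <- as.matrix(rsn_changes)
  y <- as.numeric(ratings)
  E <- as.matrix(energy_changes)
  if (nrow(X) != length(y) || nrow(E) != length(y))
    chd_input_error("all observation vectors must be aligned")
  if (n_harmonics > ncol(E)) chd_input_error("n_harmonics exceeds available harmonics")
  if (n_harmonics < ncol(X) + 2)
    chd_input_error("n_harmonics must be at least the number of networks + 2")
  E <- E[, seq_len(n_harmonics), drop = FALSE]
  rep_of <- function(v) as.numeric(stats::cor(E, v))
  Xr <- apply(X, 2, rep_of)
  yr <- rep_of(y)
  out <- multiple_correlation(Xr, yr)
  out$warning <- "harmonic correlates are not independent observations; p-value is nominal"
  out
}
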