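# Criticality diagnostics: power summaries (max / mean / sd of |alpha_k(t)|
# over time) as functions of wavenumber k, smoothed by 100-bin logarithmic
# binning, then fitted with an ordinary least-squares line in log10-log10
# space. The slope is the critical exponent beta; the RMSE of the residuals
# (epsilon) measures proximity to a pure power law.

#' Per-harmonic time summaries of power
#'
#' @param P a `power_tensor` (or `spectral_coeffs`, whose power is taken).
#' @return data.frame with columns `k`, `max`, `mean`, `sd`.
#' @export
power_summaries <- function(P) {
  if (inherits(P, "spectral_coeffs")) P <- harmonic_power(P)
  if (ncol(P$P) < 2) chd_input_error("need at least 2 time points for the sd summary")
  data.frame(k = seq_along(P$mean_k), max = P$max_k, mean = P$mean_k,
             sd = P$sd_k)
}

#' Logarithmic binning of a spectral curve
#'
#' Bin edges are log-spaced over `[min(x), max(x)]`; each occupied bin
#' reports the geometric means of its `x` and `y` values (arithmetic means
#' in log space, so points of an exact power law stay exactly on the line
#' after binning). Points with `y = 0` are excluded first (count in
#' attribute `n_zero_excluded`); empty bins are dropped.
#'
#' @param x wavenumbers (>= 1).
#' @param y positive series of the same length.
#' @param n_bins number of bins (default 100).
#' @return data.frame with columns `x`, `y` (geometric means), `n`.
#' @export
log_bin <- function(x, y, n_bins = 100) {
  if (length(x) != length(y)) chd_input_error("x and y lengths differ")
  if (any(x < 1)) chd_input_error("wavenumbers must be >= 1")
  if (any(y < 0)) chd_input_error("series values must be non-negative")
  n_zero <- sum(y == 0)
  keep <- y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) chd_input_error("no positive values to bin")
  edges <- 10^seq(log10(min(x)), log10(max(x)), length.out = n_bins + 1)
  if (diff(range(x)) == 0) edges <- c(min(x) * 0.999, max(x) * 1.001)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  gx <- tapply(log10(x), bin, mean)
  gy <- tapply(log10(y), bin, mean)
  cnt <- tapply(y, bin, length)
  out <- data.frame(x = 10^as.numeric(gx), y = 10^as.numeric(gy),
                    n = as.integer(cnt))
  out <- out[order(out$x), ]
  rownames(out) <- NULL
  if (nrow(out) < 3) chd_input_error("fewer than 3 non-empty bins")
  attr(out, "n_zero_excluded") <- n_zero
  out
}

#' Fit a power law as a line in log10-log10 space
#'
#' Unweighted OLS of `log10(y)` on `log10(x)`; `beta` is the slope
#' (reported literally — negative for decaying spectra), `epsilon` the RMSE
#' of the residuals in log10 units.
#'
#' @param binned data.frame from [log_bin()] (columns `x`, `y`), or a
#'   numeric `x` vector if `y` is given.
#' @param y optional y values when `binned` is a plain vector.
#' @return object of class `power_law_fit`: `beta`, `intercept`, `epsilon`,
#'   `n_points`.
#' @export
fit_power_law <- function(binned, y = NULL) {
  if (is.data.frame(binned)) { x <- binned$x; yy <- binned$y }
  else { x <- as.numeric(binned); yy <- as.numeric(y) }
  if (length(x) < 3) chd_input_error("need at least 3 points")
  if (any(x <= 0) || any(yy <= 0))
    chd_input_error("non-positive values cannot be log-transformed")
  lx <- log10(x); ly <- log10(yy)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(list(beta = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 epsilon = sqrt(mean(fit$residuals^2)),
                 n_points = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: beta = %.4f, epsilon = %.4f (%d points)\n",
              x$beta, x$epsilon, x$n_points))
  invisible(x)
}

#' All three power-law fits for one scan
#'
#' Convenience wrapper: max / mean / sd power summaries, log-binned and
#' line-fitted.
#'
#' @param coeffs a `spectral_coeffs` or `power_tensor`.
#' @param n_bins log-binning resolution (default 100).
#' @return data.frame with one row per summary kind: `kind`, `beta`,
#'   `intercept`, `epsilon`, `n_bins_used`.
#' @export
power_law_fits <- function(coeffs, n_bins = 100) {
  s <- power_summaries(coeffs)
  do.call(rbind, lapply(c("max", "mean", "sd"), function(kind) {
    b <- log_bin(s$k, s[[kind]], n_bins)
    f <- fit_power_law(b)
    data.frame(kind = kind, beta = f$beta, intercept = f$intercept,
               epsilon = f$epsilon, n_bins_used = f$n_points)
  }))
}

#' Compare power-law fits between conditions
#'
#' Two-sample t-tests on the per-subject distributions of `beta` and
#' `epsilon` between two conditions, per summary kind.
#'
#' @param fits data.frame with columns `subject`, `condition`, `kind`,
#'   `beta`, `epsilon` (one row per subject x condition x kind).
#' @param condition_pair character vector of the two condition labels.
#' @return data.frame: `kind`, `metric`, `delta` (mean second minus first),
#'   `t`, `p`.
#' @export
compare_fits <- function(fits, condition_pair) {
  stopifnot(all(c("subject", "condition", "kind", "beta", "epsilon") %in% names(fits)))
  a <- fits[fits$condition == condition_pair[1], ]
  b <- fits[fits$condition == condition_pair[2], ]
  out <- list()
  for (kind in unique(fits$kind)) {
    for (metric in c("beta", "epsilon")) {
      va <- a[a$kind == kind, metric]; vb <- b[b$kind == kind, metric]
      if (length(va) < 2 || length(vb) < 2)
        chd_input_error("fewer than 2 fits for condition '%s', kind '%s'",
                        condition_pair[which.min(c(length(va), length(vb)))], kind)
      tt <- ttest2(vb, va)
      out[[length(out) + 1]] <- data.frame(
        kind = kind, metric = metric, delta = mean(vb) - mean(va),
        t = tt$statistic, p = tt$p)
    }
  }
  do.call(rbind, out)
}
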