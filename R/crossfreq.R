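# Cross-frequency co-activation: Pearson correlations between the absolute
# coefficient time courses of every pair of harmonic brain states,
#   r(psi_i, psi_j) = r(|alpha_i(t)|, |alpha_j(t)|),
# band summaries over fractional spectrum ranges, and p x p partition means.
# "Frequency" here is spatial wavenumber, not temporal Hz.

#' Cross-frequency correlation matrix
#'
#' @param coeffs a `spectral_coeffs` or m x T alpha matrix.
#' @return m x m symmetric correlation matrix of class `crossfreq_matrix`;
#'   zero-variance rows give `NA` entries, their count is in attribute
#'   `n_missing_rows`.
#' @export
crossfreq_matrix <- function(coeffs) {
  a <- if (inherits(coeffs, "spectral_coeffs")) coeffs$alpha else as.matrix(coeffs)
  Tn <- ncol(a)
  if (Tn < 3) chd_input_error("need at least 3 time points")
  P <- t(abs(a))                       # T x m
  sds <- apply(P, 2, stats::sd)
  zero <- sds == 0
  Z <- scale(P)                        # zero-variance cols become NaN
  Z[, zero] <- 0
  r <- crossprod(Z) / (Tn - 1)
  r[zero, ] <- NA_real_
  r[, zero] <- NA_real_
  diag(r)[!zero] <- 1
  r <- pmin(pmax(r, -1), 1)
  structure(r, class = c("crossfreq_matrix", class(r)),
            n_missing_rows = sum(zero))
}

#' @keywords internal
band_indices <- function(band, m) {
  if (length(band) != 2 || band[1] < 0 || band[2] > 1 || band[1] >= band[2])
    chd_input_error("band must be fractions (lo, hi) with 0 <= lo < hi <= 1")
  idx <- seq.int(ceiling(band[1] * m) + 1L, floor(band[2] * m))
  if (length(idx) == 0 || idx[1] > m) chd_input_error("band selects no harmonics")
  idx
}

#' Correlation values within or between spectral bands
#'
#' Bands are fractional ranges of the spectrum: band `(lo, hi)` selects
#' wavenumbers `ceiling(lo * m) + 1 ... floor(hi * m)`. Within one band the
#' off-diagonal upper-triangle values are returned; with a second band, all
#' cross-block values.
#'
#' @param mat a `crossfreq_matrix`.
#' @param band length-2 fractional range.
#' @param band2 optional second band for between-band values.
#' @return numeric vector of correlation values (NAs dropped, count in
#'   attribute `n_missing`).
#' @export
band_values <- function(mat, band, band2 = NULL) {
  m <- nrow(mat)
  i1 <- band_indices(band, m)
  vals <- if (is.null(band2)) {
    sub <- mat[i1, i1, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    as.numeric(mat[i1, band_indices(band2, m), drop = FALSE])
  }
  out <- vals[!is.na(vals)]
  attr(out, "n_missing") <- sum(is.na(vals))
  out
}

#' Block means over a p x p partition of the spectrum
#'
#' The spectrum is split into `p` contiguous blocks of equal harmonic count
#' (remainder to the last block); each cell is the mean of the correlation
#' entries of the block pair, excluding the self-correlation diagonal for
#' diagonal blocks. NAs are excluded with a count.
#'
#' @param mat a `crossfreq_matrix`.
#' @param p number of partitions (default 10).
#' @return p x p numeric matrix; attribute `block_sizes` gives the block
#'   harmonic counts.
#' @export
partition_means <- function(mat, p = 10) {
  m <- nrow(mat)
  if (m < p) chd_input_error("need at least p = %d harmonics, have %d", p, m)
  size <- m %/% p
  starts <- (seq_len(p) - 1) * size + 1
  ends <- c(starts[-1] - 1, m)
  out <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) for (b in seq_len(a)) {
    blk <- mat[starts[a]:ends[a], starts[b]:ends[b], drop = FALSE]
    if (a == b) blk <- blk[row(blk) != col(blk)]
    out[a, b] <- out[b, a] <- mean(blk, na.rm = TRUE)
  }
  attr(out, "block_sizes") <- ends - starts + 1
  out
}

#' Band-wise condition contrast of cross-frequency correlations
#'
#' Pools the band values of each condition's matrices and reports Cohen's d
#' (condition b minus condition a) with a significance flag at the
#' configured |d| threshold.
#'
#' @param mats_a,mats_b a `crossfreq_matrix` or list of them per condition.
#' @param band fractional spectrum range.
#' @param d_threshold flag threshold on |d| (default 0.2).
#' @return list with `d`, `significant`, `n_a`, `n_b`.
#' @export
band_contrast <- function(mats_a, mats_b, band, d_threshold = 0.2) {
  pool <- function(x) {
    if (!is.list(x)) x <- list(x)
    unlist(lapply(x, band_values, band = band), use.names = FALSE)
  }
  va <- pool(mats_a); vb <- pool(mats_b)
  if (length(va) == 0 || length(vb) == 0)
    chd_input_error("empty band-value distribution")
  d <- cohens_d(vb, va)
  list(d = d, significant = abs(d) > d_threshold,
       n_a = length(va), n_b = length(vb))
}
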