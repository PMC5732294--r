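# Projection of vertex-mapped functional series onto the harmonic basis
#   alpha_k(t) = <F_t, psi_k>
# and the derived power P = |alpha| and energy E = |alpha|^2 lambda^2
# tensors. The inner product is the plain Euclidean dot product over
# vertices; no area or degree weighting.

#' Construct a functional series object
#'
#' @param data numeric vertex x time matrix `F(v, t)` (BOLD, arbitrary
#'   units).
#' @param TR repetition time in seconds (metadata).
#' @param subject_id,condition,scan_order optional metadata.
#' @return object of class `functional_series`.
#' @export
functional_series <- function(data, TR = NA_real_, subject_id = NA,
                              condition = NA, scan_order = NA) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) chd_input_error("non-finite values in functional data")
  structure(list(data = data, TR = TR, subject_id = subject_id,
                 condition = condition, scan_order = scan_order),
            class = "functional_series")
}

#' @export
print.functional_series <- function(x, ...) {
  cat(sprintf("functional_series: %d vertices x %d time points (TR=%s, subject=%s, condition=%s)\n",
              nrow(x$data), ncol(x$data), format(x$TR), format(x$subject_id),
              format(x$condition)))
  invisible(x)
}

#' @keywords internal
as_series_matrix <- function(series) {
  if (inherits(series, "functional_series")) series$data else as.matrix(series)
}

#' Project a functional series onto connectome harmonics
#'
#' `alpha_k(t) = <F_t, psi_k>` for every mode `k` and time point `t`.
#'
#' @param series a `functional_series` or vertex x time matrix.
#' @param basis a `harmonic_basis` with matching vertex dimension.
#' @param zscored provenance flag recorded on the result (set by
#'   [zscore_vertices()]; not acted upon here).
#' @return object of class `spectral_coeffs`: `alpha` (m x T),
#'   `basis_fingerprint`, `lambda`, `zscored`.
#' @export
decompose <- function(series, basis, zscored = FALSE) {
  F <- as_series_matrix(series)
  if (!inherits(basis, "harmonic_basis")) chd_input_error("basis must be a harmonic_basis")
  if (nrow(F) != basis$n)
    chd_input_error("vertex dimension mismatch: series has %d, basis expects %d",
                    nrow(F), basis$n)
  if (inherits(series, "functional_series") && isTRUE(attr(series, "zscored")))
    zscored <- TRUE
  structure(list(alpha = crossprod(basis$evectors, F),
                 basis_fingerprint = basis$fingerprint,
                 lambda = basis$evalues, zscored = zscored),
            class = "spectral_coeffs")
}

#' @export
print.spectral_coeffs <- function(x, ...) {
  cat(sprintf("spectral_coeffs: %d harmonics x %d time points\n",
              nrow(x$alpha), ncol(x$alpha)))
  invisible(x)
}

#' Reconstruct vertex-space activity from spectral coefficients
#'
#' `F_hat_t = sum_k alpha_k(t) psi_k`; exact when the basis is complete
#' (m = n), a least-squares truncation otherwise.
#'
#' @param coeffs a `spectral_coeffs`.
#' @param basis the `harmonic_basis` the coefficients were computed with.
#' @return a `functional_series`.
#' @export
reconstruct <- function(coeffs, basis) {
  if (!inherits(coeffs, "spectral_coeffs")) chd_input_error("not spectral_coeffs")
  if (!identical(coeffs$basis_fingerprint, basis$fingerprint))
    chd_integrity_error("coefficients were computed with a different basis")
  if (nrow(coeffs$alpha) > basis$m)
    chd_input_error("more coefficients than basis modes")
  m <- nrow(coeffs$alpha)
  functional_series(basis$evectors[, seq_len(m), drop = FALSE] %*% coeffs$alpha)
}

#' Power of harmonic brain states
#'
#' `P(psi_k, t) = |alpha_k(t)|`: the strength of activation of harmonic `k`
#' at time `t`.
#'
#' @param coeffs a `spectral_coeffs`.
#' @return object of class `power_tensor`: `P` (m x T) plus per-harmonic
#'   time summaries `max_k`, `mean_k`, `sd_k` and `total` (sum over k and t).
#' @export
harmonic_power <- function(coeffs) {
  P <- abs(coeffs$alpha)
  structure(list(P = P,
                 max_k = apply(P, 1, max),
                 mean_k = rowMeans(P),
                 sd_k = apply(P, 1, stats::sd),
                 total = sum(P)),
            class = "power_tensor")
}

#' Energy of harmonic brain states
#'
#' `E(psi_k, t) = |alpha_k(t)|^2 lambda_k^2`: activation strength weighted
#' by the harmonic's intrinsic (eigenvalue-squared) energy. The total over
#' modes equals the squared Laplacian norm of the activity pattern,
#' `E_total(t) = ||Delta_G F_t||^2`, when the basis is complete.
#'
#' @param coeffs a `spectral_coeffs`.
#' @param basis optional `harmonic_basis`; defaults to the eigenvalues
#'   stored with the coefficients.
#' @return object of class `energy_tensor`: `E` (m x T), `lambda`,
#'   `total_t` (per time point), `mean_k` and `sd_k` (per-harmonic time mean
#'   and sd), `total` (scan total).
#' @export
harmonic_energy <- function(coeffs, basis = NULL) {
  lambda <- if (!is.null(basis)) {
    if (!identical(coeffs$basis_fingerprint, basis$fingerprint))
      chd_integrity_error("coefficients were computed with a different basis")
    basis$evalues
  } else coeffs$lambda
  if (is.null(lambda)) chd_input_error("no eigenvalues available")
  if (length(lambda) != nrow(coeffs$alpha))
    chd_input_error("eigenvalue count does not match coefficient rows")
  E <- (coeffs$alpha^2) * lambda^2
  structure(list(E = E, lambda = lambda,
                 total_t = colSums(E),
                 mean_k = rowMeans(E),
                 sd_k = apply(E, 1, stats::sd),
                 total = sum(E)),
            class = "energy_tensor")
}

#' Per-vertex temporal z-scoring
#'
#' Optional preprocessing: each vertex time course is standardized to mean 0
#' and sd 1; constant vertices are set to zero and counted in attribute
#' `n_constant`.
#'
#' @param series a `functional_series` or matrix.
#' @return a `functional_series` with attribute `zscored = TRUE`.
#' @export
zscore_vertices <- function(series) {
  F <- as_series_matrix(series)
  if (ncol(F) < 2) chd_input_error("z-scoring needs at least 2 time points")
  mu <- rowMeans(F)
  sd <- apply(F, 1, stats::sd)
  const <- sd == 0
  sd[const] <- 1
  Z <- (F - mu) / sd
  Z[const, ] <- 0
  out <- if (inherits(series, "functional_series")) {
    series$data <- Z; series
  } else functional_series(Z)
  attr(out, "zscored") <- TRUE
  attr(out, "n_constant") <- sum(const)
  out
}

# --- persistent formats ------------------------------------------------------

#' Read / write a functional series as TSV
#'
#' Vertices as rows, time points as columns, with a comment header
#' `# n=<vertices> T=<timepoints> TR=<seconds>`.
#'
#' @param series a `functional_series`.
#' @param path file path.
#' @return `read_series_tsv` returns a `functional_series`.
#' @export
write_series_tsv <- function(series, path) {
  F <- as_series_matrix(series)
  TR <- if (inherits(series, "functional_series")) series$TR else NA_real_
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# n=%d T=%d TR=%s", nrow(F), ncol(F), format(TR)), con)
  utils::write.table(format(F, digits = 17, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^#\\s*n=\\d+\\s+T=\\d+", hdr))
    chd_format_error("missing '# n=.. T=.. TR=..' header in %s", path)
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", hdr))
  Tn <- as.integer(sub(".*T=(\\d+).*", "\\1", hdr))
  TR <- suppressWarnings(as.numeric(sub(".*TR=([^ ]+).*", "\\1", hdr)))
  F <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(F) <- NULL
  if (nrow(F) != n || ncol(F) != Tn)
    chd_format_error("data shape %dx%d does not match header %dx%d in %s",
                     nrow(F), ncol(F), n, Tn, path)
  functional_series(F, TR = TR)
}
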