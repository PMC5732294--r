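# Connectome harmonics: the symmetric graph Laplacian
#   Delta_G = D^{-1/2} (D - A) D^{-1/2}
# and its eigenmodes psi_k with eigenvalues lambda_k in [0, 2], sorted
# ascending (wavenumber k = 1-based rank of lambda).

#' Symmetric graph Laplacian
#'
#' `Delta_G = D^{-1/2} (D - A) D^{-1/2}` with `D` the (weighted) degree
#' matrix. Defined only when every vertex has positive degree; prune
#' isolated vertices first (see [prune_isolated()]).
#'
#' @param graph a `connectome_graph`, or a square symmetric (sparse) matrix.
#' @return sparse symmetric `Matrix` with unit diagonal (unweighted case) and
#'   `-A(i,j)/sqrt(d_i d_j)` off the diagonal.
#' @export
graph_laplacian <- function(graph) {
  A <- if (inherits(graph, "connectome_graph")) graph$A else
    methods::as(methods::as(graph, "CsparseMatrix"), "generalMatrix")
  deg <- Matrix::rowSums(A)
  zero <- which(deg == 0)
  if (length(zero) > 0)
    chd_input_error("zero-degree vertex (first: %d); prune isolated vertices first",
                    zero[1])
  n <- nrow(A)
  S <- Matrix::Diagonal(n, 1 / sqrt(deg))
  Matrix::Diagonal(n) - methods::as(S %*% A %*% S, "CsparseMatrix")
}

#' Compute connectome harmonics
#'
#' Solves `Delta_G psi_k = lambda_k psi_k` for the `m` smallest eigenpairs.
#' Dense `eigen()` is used for `n <= dense_threshold` or `m = "all"`; for
#' larger graphs a partial ARPACK solve is run on the spectrally flipped
#' operator `2I - Delta_G` (eigenvalues of the symmetric Laplacian lie in
#' `[0, 2]`, so its smallest eigenpairs are the flip's largest — no
#' shift-invert factorization needed).
#'
#' A deterministic sign convention is applied: the entry of largest absolute
#' value of each eigenvector is made positive (ties broken by lowest vertex
#' index). Within a degenerate eigenspace individual vectors are
#' solver-dependent; only the spanned subspace is meaningful.
#'
#' @param graph a `connectome_graph` or a Laplacian matrix as returned by
#'   [graph_laplacian()] (detected by its unit diagonal).
#' @param m number of modes, or `"all"`.
#' @param dense_threshold use dense `eigen()` when `n` is at most this.
#' @param tol ARPACK tolerance.
#' @param maxiter ARPACK iteration cap.
#' @return object of class `harmonic_basis`: `evalues` (ascending),
#'   `evectors` (n x m, orthonormal columns), `m`, `n`, `fingerprint`,
#'   `solver`.
#' @export
compute_harmonics <- function(graph, m = "all", dense_threshold = 2000,
                              tol = 1e-10, maxiter = 10000) {
  if (inherits(graph, "connectome_graph")) {
    lap <- graph_laplacian(graph)
    fp <- graph_fingerprint(graph$A)
  } else {
    lap <- methods::as(graph, "CsparseMatrix")
    fp <- graph_fingerprint(lap)
  }
  n <- nrow(lap)
  all_modes <- identical(m, "all")
  if (all_modes) m <- n
  m <- as.integer(m)
  if (m < 1 || m > n) chd_input_error("m must be in [1, %d]", n)
  if (n <= dense_threshold || m == n) {
    ed <- eigen(as.matrix(Matrix::symmpart(lap)), symmetric = TRUE)
    ord <- order(ed$values)[seq_len(m)]
    vals <- ed$values[ord]
    vecs <- ed$vectors[, ord, drop = FALSE]
    solver <- "dense"
  } else {
    flip <- 2 * Matrix::Diagonal(n) - lap
    res <- igraph::arpack(
      function(x, extra = NULL) as.numeric(flip %*% x),
      options = list(n = n, nev = m, ncv = min(n, max(2 * m + 1, 20)),
                     which = "LA", maxiter = maxiter, tol = tol),
      sym = TRUE)
    vals <- 2 - res$values
    vecs <- res$vectors
    if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = 1)
    ord <- order(vals)
    vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
    solver <- "arpack-flip"
  }
  vals[abs(vals) < 1e-12] <- abs(vals[abs(vals) < 1e-12])  # clamp -0 noise
  # sign convention: largest-|entry| positive, ties -> lowest vertex index
  for (k in seq_len(ncol(vecs))) {
    v <- vecs[, k]
    i <- which(abs(v) == max(abs(v)))[1]
    if (v[i] < 0) vecs[, k] <- -v
  }
  res_norms <- sqrt(colSums(as.matrix(lap %*% vecs - vecs %*% diag(vals, m))^2))
  if (any(res_norms > 1e-6))
    warning(sprintf("eigen-residual above 1e-6 for %d mode(s); max %.2e",
                    sum(res_norms > 1e-6), max(res_norms)))
  structure(list(evalues = vals, evectors = vecs, m = m, n = n,
                 fingerprint = fp, solver = solver, tol = tol),
            class = "harmonic_basis")
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat(sprintf("harmonic_basis: %d modes on %d vertices (%s), lambda in [%.3g, %.3g]\n",
              x$m, x$n, x$solver, min(x$evalues), max(x$evalues)))
  invisible(x)
}

#' Persist / restore a harmonic basis
#'
#' The container stores eigenvalues, eigenvectors, the source-graph
#' fingerprint and solver metadata; the round trip is bit-exact. On load the
#' fingerprint can be verified against a supplied graph.
#'
#' @param basis a `harmonic_basis`.
#' @param path file path.
#' @param graph optional `connectome_graph` (or adjacency) whose fingerprint
#'   must match the stored one.
#' @return `load_basis` returns the `harmonic_basis`.
#' @export
save_basis <- function(basis, path) {
  if (!inherits(basis, "harmonic_basis")) chd_input_error("not a harmonic_basis")
  payload <- unclass(basis)
  payload$.container <- "connharm-basis-v1"
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path, graph = NULL) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) chd_format_error("unreadable basis file %s: %s",
                                                           path, conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$.container, "connharm-basis-v1"))
    chd_format_error("%s is not a connharm basis container", path)
  payload$.container <- NULL
  basis <- structure(payload, class = "harmonic_basis")
  if (!is.null(graph)) {
    fp <- if (inherits(graph, "connectome_graph")) graph_fingerprint(graph$A)
          else graph_fingerprint(graph)
    if (!identical(fp, basis$fingerprint))
      chd_integrity_error("basis fingerprint %s does not match graph %s",
                          basis$fingerprint, fp)
  }
  basis
}
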