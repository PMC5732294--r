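# Shared fixtures, memoised per test run: the order-2 two-hemisphere graph
# and its full harmonic basis are reused across files, and a fake identity
# basis supports large-m coefficient-level tests without an eigensolve.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_graph <- function() {
  cached("graph_o2", synth_connectome(order = 2, n_long_edges = 200,
                                      distance_decay = 30, seed = 42))
}

fixture_basis <- function() {
  cached("basis_o2", compute_harmonics(fixture_graph(), m = "all"))
}

# orthonormal "basis" with trivial eigenvectors (identity): decompose() is
# then the identity map, so coefficient-level analyses can be exercised at
# large m without an eigensolve. Eigenvalues are a plausible ascending ramp.
identity_basis <- function(m, lambda = seq(0, 1.8, length.out = m)) {
  structure(list(evalues = lambda, evectors = diag(m), m = m, n = m,
                 fingerprint = sprintf("identity-%d", m),
                 solver = "fixture", tol = 0),
            class = "harmonic_basis")
}

# adjacency of simple named graphs as connectome_graph objects
cycle_graph <- function(n) {
  e <- cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  connectome_graph(Matrix::sparseMatrix(i = c(e[, 1], e[, 2]),
                                        j = c(e[, 2], e[, 1]),
                                        x = 1, dims = c(n, n)))
}

path_graph <- function(n) {
  e <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  connectome_graph(Matrix::sparseMatrix(i = c(e[, 1], e[, 2]),
                                        j = c(e[, 2], e[, 1]),
                                        x = 1, dims = c(n, n)))
}

# seeded Erdos-Renyi graph without isolated vertices
random_graph <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  iso <- rowSums(A) == 0
  for (i in which(iso)) {          # connect isolates to a random partner
    j <- sample(setdiff(seq_len(n), i), 1)
    A[i, j] <- A[j, i] <- 1
  }
  connectome_graph(methods::as(A, "CsparseMatrix"))
}

# principal angles between the column spaces of two matrices
principal_angle_max <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  acos(pmin(pmax(min(s), -1), 1))
}
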