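# harmonics: symmetric graph Laplacian, eigensolvers (dense and partial
# ARPACK), closed-form oracles, spectral bounds, and basis persistence.

test_that("Laplacian of K2 and P3 match hand computation", {
  k2 <- connectome_graph(Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1))
  expect_equal(as.matrix(graph_laplacian(k2)),
               matrix(c(1, -1, -1, 1), 2), tolerance = 1e-14)
  ev <- compute_harmonics(path_graph(3))$evalues
  expect_equal(ev, c(0, 1, 2), tolerance = 1e-10)
  # zero-degree vertex refused, naming the vertex
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_error(graph_laplacian(connectome_graph(methods::as(A, "CsparseMatrix"))),
               "vertex \\(first: 3\\)")
})

test_that("cycle eigenvalues match the circulant closed form", {
  for (n in c(5, 8, 12, 50)) {
    ev <- compute_harmonics(cycle_graph(n))$evalues
    expect_equal(ev, sort(1 - cos(2 * pi * (0:(n - 1)) / n)), tolerance = 1e-8)
  }
})

test_that("C8 eigenvectors span the Fourier cosine/sine subspaces", {
  n <- 8
  b <- compute_harmonics(cycle_graph(n))
  for (mm in 1:3) {   # eigenvalue 1 - cos(2 pi m / n), multiplicity 2
    lam <- 1 - cos(2 * pi * mm / n)
    idx <- which(abs(b$evalues - lam) < 1e-9)
    expect_length(idx, 2)
    theta <- 2 * pi * mm * (0:(n - 1)) / n
    expect_lt(principal_angle_max(b$evectors[, idx], cbind(cos(theta), sin(theta))),
              1e-6)
  }
})

test_that("null space: lambda_1 = 0 with psi_1 proportional to D^{1/2} 1", {
  g <- fixture_graph()
  b <- fixture_basis()
  expect_lt(abs(b$evalues[1]), 1e-10)
  d <- Matrix::rowSums(g$A)
  v <- sqrt(d) / sqrt(sum(d))
  expect_lt(min(sum((b$evectors[, 1] - v)^2), sum((b$evectors[, 1] + v)^2)), 1e-16)
})

test_that("disconnected hemispheres give exactly two zero eigenvalues", {
  g <- synth_connectome(order = 1, n_long_edges = 0, seed = 1)
  ev <- compute_harmonics(g)$evalues
  expect_equal(sum(abs(ev) < 1e-10), 2)
})

test_that("orthonormality, residuals and the lambda <= 2 bound hold", {
  b <- fixture_basis()
  expect_lt(max(abs(crossprod(b$evectors) - diag(b$n))), 1e-8)
  lap <- graph_laplacian(fixture_graph())
  res <- sqrt(colSums(as.matrix(lap %*% b$evectors -
                                  b$evectors %*% diag(b$evalues))^2))
  expect_lt(max(res), 1e-6)
  expect_lte(max(b$evalues), 2 + 1e-10)
  # bipartite K2 attains the bound exactly
  k2 <- connectome_graph(Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1))
  expect_equal(max(compute_harmonics(k2)$evalues), 2, tolerance = 1e-12)
})

test_that("partial ARPACK solver agrees with the dense solver", {
  for (seed in 1:3) {
    g <- random_graph(150, p = 0.06, seed = seed)
    dense <- compute_harmonics(g, m = "all")
    part <- compute_harmonics(g, m = 15, dense_threshold = 10)
    expect_identical(part$solver, "arpack-flip")
    expect_equal(part$evalues, dense$evalues[1:15], tolerance = 1e-8)
    # subspace comparison groups degenerate eigenvalues
    groups <- split(1:15, round(dense$evalues[1:15], 8))
    for (idx in groups)
      expect_lt(principal_angle_max(part$evectors[, idx, drop = FALSE],
                                    dense$evectors[, idx, drop = FALSE]), 1e-6)
  }
})

test_that("weighted (group-average) graphs use weighted degrees", {
  gs <- lapply(1:4, function(s) random_graph(40, p = 0.15, seed = s))
  avg <- average_graphs(gs)
  lap <- graph_laplacian(avg)
  A <- as.matrix(avg$A); d <- rowSums(A)
  oracle <- diag(40) - A / sqrt(outer(d, d))
  expect_equal(as.matrix(lap), oracle, tolerance = 1e-12)
  expect_lte(max(compute_harmonics(avg)$evalues), 2 + 1e-10)
})

test_that("adding one edge obeys Weyl's eigenvalue perturbation bound", {
  for (seed in 4:6) {
    g <- random_graph(40, p = 0.15, seed = seed)
    A2 <- as.matrix(g$A)
    free <- which(A2 == 0 & upper.tri(A2), arr.ind = TRUE)
    set.seed(seed); pick <- free[sample(nrow(free), 1), ]
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
    g2 <- connectome_graph(methods::as(A2, "CsparseMatrix"))
    l1 <- graph_laplacian(g); l2 <- graph_laplacian(g2)
    gap <- max(abs(eigen(as.matrix(l2 - l1), symmetric = TRUE)$values))
    dl <- abs(compute_harmonics(g2)$evalues - compute_harmonics(g)$evalues)
    expect_lte(max(dl), gap + 1e-10)
  }
})

test_that("sign convention is deterministic across repeated solves", {
  b1 <- compute_harmonics(fixture_graph(), m = "all")
  b2 <- compute_harmonics(fixture_graph(), m = "all")
  expect_identical(b1$evectors, b2$evectors)
  peaks <- apply(b1$evectors, 2, function(v) v[which.max(abs(v))])
  expect_true(all(peaks > 0))
})

test_that("basis save/load round-trips and verifies integrity", {
  b <- fixture_basis()
  f <- tempfile(fileext = ".rds")
  save_basis(b, f)
  b2 <- load_basis(f, graph = fixture_graph())
  expect_identical(b2$evalues, b$evalues)
  expect_identical(b2$evectors, b$evectors)
  expect_identical(b2$fingerprint, b$fingerprint)

  expect_error(load_basis(f, graph = cycle_graph(10)), "fingerprint")

  # truncated file: format error, no partial basis
  raw <- readBin(f, "raw", file.info(f)$size)
  f2 <- tempfile(fileext = ".rds")
  writeBin(raw[seq_len(length(raw) %/% 2)], f2)
  expect_error(load_basis(f2), "unreadable|container")

  f3 <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), f3)
  expect_error(load_basis(f3), "container")
})
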