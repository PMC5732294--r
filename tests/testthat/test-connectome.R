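# connectome_builder: adjacency construction, averaging, pruning, icosphere
# meshes, the synthetic two-hemisphere generator, and file formats.

test_that("build_adjacency combines mesh edges and long-range pairs", {
  tri <- surface_mesh(vertices = diag(3), triangles = matrix(1:3, 1))
  g <- build_adjacency(tri)
  expect_equal(Matrix::nnzero(g$A) / 2, 3)           # one triangle, 3 edges
  expect_true(Matrix::isSymmetric(g$A))
  expect_equal(Matrix::diag(g$A), rep(0, 3))

  expect_error(build_adjacency(tri, matrix(c(1, 1), 1)), "self-pair")
  expect_error(build_adjacency(tri, matrix(c(1, 9), 1)), "out of range")

  # a long pair duplicating a mesh edge is counted once, flagged local
  g2 <- build_adjacency(tri, matrix(c(1, 2), 1))
  expect_equal(Matrix::nnzero(g2$A) / 2, 3)
  expect_equal(nrow(g2$long_edges), 0)
})

test_that("icosphere + seeded long pairs matches brute-force edge union", {
  mesh <- make_icosphere(2)
  n <- nrow(mesh$vertices)
  set.seed(11)
  pairs <- cbind(sample(n, 50, TRUE), sample(n, 50, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  g <- build_adjacency(mesh, pairs)

  # oracle: dense union over an explicit loop of triangle edges + pairs
  D <- matrix(0, n, n)
  for (r in seq_len(nrow(mesh$triangles))) {
    t3 <- mesh$triangles[r, ]
    for (e in list(t3[c(1, 2)], t3[c(2, 3)], t3[c(1, 3)]))
      D[e[1], e[2]] <- D[e[2], e[1]] <- 1
  }
  mesh_edge_count <- sum(D) / 2
  for (r in seq_len(nrow(pairs)))
    D[pairs[r, 1], pairs[r, 2]] <- D[pairs[r, 2], pairs[r, 1]] <- 1
  expect_equal(unname(as.matrix(g$A)), D)
  novel <- sum(D) / 2 - mesh_edge_count
  expect_equal(nrow(g$long_edges), novel)
  expect_equal(Matrix::nnzero(g$A) / 2, mesh_edge_count + novel)
})

test_that("average_graphs is the elementwise mean", {
  tri <- surface_mesh(diag(4)[, 1:3], matrix(1:3, 1))
  g1 <- build_adjacency(tri, matrix(c(1, 4), 1))
  expect_equal(as.matrix(average_graphs(list(g1))$A), as.matrix(g1$A))

  g2 <- build_adjacency(tri, matrix(c(2, 4), 1))
  avg <- average_graphs(list(g1, g2))
  M <- as.matrix(avg$A)
  expect_equal(M[1, 4], 0.5)
  expect_equal(M[2, 4], 0.5)
  expect_equal(M[1, 2], 1)   # shared triangle edge in both

  gs <- lapply(1:5, function(s) {
    set.seed(s)
    A <- matrix(0, 10, 10)
    A[upper.tri(A)] <- rbinom(45, 1, 0.3)
    connectome_graph(methods::as(A + t(A), "CsparseMatrix"))
  })
  oracle <- Reduce(`+`, lapply(gs, function(g) as.matrix(g$A))) / 5
  expect_equal(as.matrix(average_graphs(gs)$A), oracle, tolerance = 1e-12)
  expect_true(all(as.matrix(average_graphs(gs)$A) >= 0 &
                  as.matrix(average_graphs(gs)$A) <= 1))
  expect_error(average_graphs(list(g1, cycle_graph(7))), "mismatched")
})

test_that("prune_isolated keeps exactly the positive-degree vertices", {
  g <- cycle_graph(6)
  expect_identical(prune_isolated(g)$vertex_map, 1:6)
  expect_equal(attr(prune_isolated(g), "n_removed"), 0L)

  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  g4 <- connectome_graph(methods::as(A, "CsparseMatrix"))
  p <- prune_isolated(g4)
  expect_equal(p$n, 3)
  expect_identical(p$vertex_map, 1:3)

  set.seed(3)
  A <- matrix(0, 30, 30)
  A[upper.tri(A)] <- rbinom(435, 1, 0.05)
  A <- A + t(A)
  iso <- sample(30, 6); A[iso, ] <- 0; A[, iso] <- 0
  gr <- connectome_graph(methods::as(A, "CsparseMatrix"))
  p <- prune_isolated(gr)
  expect_identical(p$vertex_map, which(rowSums(A) > 0))   # degree-scan oracle
  expect_true(all(Matrix::rowSums(p$A) > 0))
  expect_error(prune_isolated(connectome_graph(Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(3, 3)))),
    "all vertices")
})

test_that("icosphere anchors: counts, Euler characteristic, errors", {
  m0 <- make_icosphere(0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$triangles), 20)
  for (ord in 0:3) {
    m <- make_icosphere(ord)
    V <- nrow(m$vertices); F <- nrow(m$triangles); E <- nrow(mesh_edges(m))
    expect_equal(V, 10 * 4^ord + 2)
    expect_equal(V - E + F, 2)
    expect_equal(3 * F, 2 * E)                 # closed triangulated surface
  }
  expect_error(make_icosphere(-1), "non-negative")
  expect_error(make_icosphere(7), "maximum")
})

test_that("synth_connectome: determinism, disconnection, decay model", {
  g1 <- synth_connectome(order = 1, n_long_edges = 40, seed = 9)
  g2 <- synth_connectome(order = 1, n_long_edges = 40, seed = 9)
  expect_identical(as.matrix(g1$A), as.matrix(g2$A))

  g0 <- synth_connectome(order = 1, n_long_edges = 0, seed = 1)
  nh <- nrow(make_icosphere(1)$vertices)
  expect_equal(sum(as.matrix(g0$A)[seq_len(nh), nh + seq_len(nh)]), 0)

  # long-edge distances follow the exp(-d/decay) sampling model: compare to
  # an independent weighted resample of the same candidate pairs
  decay <- 30
  g <- synth_connectome(order = 2, n_long_edges = 200, distance_decay = decay,
                        seed = 7, frac_interhemi = 0)
  obs <- attr(g, "long_edge_lengths")
  mesh <- attr(g, "mesh")
  n <- nrow(mesh$vertices)
  local <- mesh_edges(mesh)
  pairs <- t(utils::combn(n, 2L))
  key <- pairs[, 1] * (n + 1) + pairs[, 2]
  pairs <- pairs[!(key %in% (local[, 1] * (n + 1) + local[, 2])), ]
  d <- sqrt(rowSums((mesh$vertices[pairs[, 1], ] - mesh$vertices[pairs[, 2], ])^2))
  intra <- mesh$hemisphere[pairs[, 1]] == mesh$hemisphere[pairs[, 2]]
  set.seed(123)
  ref <- unlist(lapply(1:20, function(i)
    d[intra][sample(sum(intra), 200, prob = exp(-d[intra] / decay))]))
  expect_gt(suppressWarnings(stats::ks.test(obs, ref))$p.value, 1e-3)

  expect_error(synth_connectome(order = 0, n_long_edges = 1e6, seed = 1),
               "exceeds")
})

test_that("mesh and graph file formats round-trip", {
  mesh <- make_icosphere(1)
  off <- tempfile(fileext = ".off"); ply <- tempfile(fileext = ".ply")
  write_off(mesh, off); write_ply(mesh, ply)
  for (m2 in list(read_off(off), read_ply(ply))) {
    expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-9)
    expect_identical(m2$triangles, mesh$triangles)
  }
  expect_error(read_off(ply), "not an OFF")

  g <- fixture_graph()
  mtx <- tempfile(fileext = ".mtx")
  write_graph_mtx(g, mtx)
  expect_equal(as.matrix(read_graph_mtx(mtx)$A), as.matrix(g$A))

  tsv <- tempfile(fileext = ".tsv")
  write_long_edges(g$long_edges, g$n, tsv)
  le <- read_long_edges(tsv)
  expect_identical(le$pairs, g$long_edges)
  expect_equal(le$n_vertices, g$n)
})

test_that("edge provenance masks partition the edge set", {
  g <- fixture_graph()
  all_edges <- rbind(g$local_edges, g$long_edges)
  n <- g$n
  key <- all_edges[, 1] * (n + 1) + all_edges[, 2]
  expect_equal(length(unique(key)), nrow(all_edges))       # no double counting
  expect_equal(nrow(all_edges), Matrix::nnzero(g$A) / 2)   # covers all edges
})
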