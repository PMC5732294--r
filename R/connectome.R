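# Vertex-level connectome graphs: local (mesh) edges plus long-range
# (tract-endpoint) edges, group averaging, isolated-vertex pruning, and the
# synthetic two-hemisphere generator.

#' Construct a connectome graph object
#'
#' @param A sparse symmetric non-negative matrix, zero diagonal.
#' @param local_edges,long_edges integer 2-column matrices of 1-based vertex
#'   pairs recording edge provenance; a long-range pair duplicating a mesh
#'   edge is counted once and flagged local.
#' @param vertex_map integer vector mapping retained graph index -> original
#'   vertex id (identity unless pruning occurred).
#' @return object of class `connectome_graph` with elements `n`, `A`,
#'   `local_edges`, `long_edges`, `vertex_map`.
#' @export
connectome_graph <- function(A, local_edges = NULL, long_edges = NULL,
                             vertex_map = NULL) {
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  n <- nrow(A)
  if (n != ncol(A)) chd_input_error("adjacency must be square")
  if (any(Matrix::diag(A) != 0)) chd_input_error("adjacency must have zero diagonal")
  if (!isTRUE(Matrix::isSymmetric(A, tol = 0))) chd_input_error("adjacency must be symmetric")
  if (any(A@x < 0)) chd_input_error("adjacency weights must be non-negative")
  structure(list(
    n = n, A = A,
    local_edges = local_edges %||% matrix(integer(0), ncol = 2),
    long_edges = long_edges %||% matrix(integer(0), ncol = 2),
    vertex_map = vertex_map %||% seq_len(n)
  ), class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf(
    "connectome_graph: %d vertices, %d edges (%d local, %d long-range)\n",
    x$n, Matrix::nnzero(x$A) / 2, nrow(x$local_edges), nrow(x$long_edges)))
  invisible(x)
}

#' @keywords internal
edges_to_sparse <- function(edges, n, weight = 1) {
  if (nrow(edges) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = weight, dims = c(n, n), use.last.ij = TRUE)
}

#' Build a binary adjacency from a mesh and long-range endpoint pairs
#'
#' The graph's edge set is the union of the mesh's triangle edges ("local"
#' connections) and the supplied long-range endpoint pairs (tractography
#' derived or synthetic); `A(i,j) = 1` iff the pair is connected by either
#' route. Undirected, unweighted, zero diagonal.
#'
#' @param mesh a `surface_mesh`.
#' @param long_edges integer k x 2 matrix of 1-based vertex pairs (or NULL).
#' @return a `connectome_graph`.
#' @export
build_adjacency <- function(mesh, long_edges = NULL) {
  if (!inherits(mesh, "surface_mesh")) chd_input_error("mesh must be a surface_mesh")
  n <- nrow(mesh$vertices)
  if (n == 0) chd_input_error("empty mesh")
  local <- mesh_edges(mesh)
  long <- matrix(integer(0), ncol = 2)
  if (!is.null(long_edges) && nrow(long_edges) > 0) {
    long <- matrix(as.integer(as.matrix(long_edges)), ncol = 2)
    if (min(long) < 1 || max(long) > n)
      chd_input_error("long-range edge index out of range [1, %d]", n)
    if (any(long[, 1] == long[, 2]))
      chd_input_error("long-range self-pair is not allowed")
    long <- unique(cbind(pmin(long[, 1], long[, 2]), pmax(long[, 1], long[, 2])))
    # pairs that duplicate a mesh edge are counted once, flagged local
    key <- function(e) e[, 1] * (n + 1) + e[, 2]
    long <- long[!(key(long) %in% key(local)), , drop = FALSE]
  }
  A <- edges_to_sparse(rbind(local, long), n)
  connectome_graph(A, local_edges = local, long_edges = long)
}

#' Entrywise mean of subject adjacency matrices
#'
#' Group-average structural connectivity: binary per-subject graphs average
#' to fractional weights in `[0, 1]`.
#'
#' @param graphs list of `connectome_graph` objects sharing `n` and ordering.
#' @return a `connectome_graph` with fractional weights.
#' @export
average_graphs <- function(graphs) {
  if (length(graphs) == 0) chd_input_error("no graphs to average")
  ns <- vapply(graphs, function(g) g$n, integer(1))
  if (length(unique(ns)) != 1)
    chd_input_error("graphs have mismatched vertex counts: %s",
                    paste(unique(ns), collapse = ", "))
  Abar <- Reduce(`+`, lapply(graphs, function(g) g$A)) / length(graphs)
  connectome_graph(Abar,
                   local_edges = unique(do.call(rbind, lapply(graphs, `[[`, "local_edges"))),
                   long_edges = unique(do.call(rbind, lapply(graphs, `[[`, "long_edges"))))
}

#' Remove zero-degree vertices
#'
#' The symmetric Laplacian involves `D^{-1/2}` and is undefined at isolated
#' vertices; they are dropped before the eigenproblem, with the original ->
#' retained index map recorded in `vertex_map`.
#'
#' @param graph a `connectome_graph`.
#' @return a `connectome_graph`; attribute `n_removed` counts dropped vertices.
#' @export
prune_isolated <- function(graph) {
  deg <- Matrix::rowSums(graph$A)
  keep <- which(deg > 0)
  if (length(keep) == 0) chd_input_error("all vertices are isolated")
  if (length(keep) == graph$n) {
    attr(graph, "n_removed") <- 0L
    return(graph)
  }
  remap <- rep(NA_integer_, graph$n)
  remap[keep] <- seq_along(keep)
  remap_edges <- function(e) {
    e <- matrix(remap[e], ncol = 2)
    e[stats::complete.cases(e), , drop = FALSE]
  }
  out <- connectome_graph(graph$A[keep, keep, drop = FALSE],
                          local_edges = remap_edges(graph$local_edges),
                          long_edges = remap_edges(graph$long_edges),
                          vertex_map = graph$vertex_map[keep])
  attr(out, "n_removed") <- graph$n - length(keep)
  out
}

#' Synthetic two-hemisphere connectome
#'
#' Two icosphere meshes (disjoint left/right vertex blocks, left first)
#' provide the local edges; `n_long_edges` long-range pairs are sampled
#' without replacement with probability proportional to
#' `exp(-distance / distance_decay)`, a fixed fraction of them constrained to
#' be inter-hemispheric. Deterministic under a fixed seed.
#'
#' @param order icosphere subdivision order per hemisphere.
#' @param n_long_edges number of long-range pairs to sample.
#' @param distance_decay exponential decay length (mm) of the sampling
#'   weights.
#' @param seed integer RNG seed.
#' @param frac_interhemi fraction of long-range pairs forced to connect the
#'   two hemispheres (rounded down).
#' @param radius hemisphere sphere radius (mm).
#' @param gap distance between hemisphere surfaces (mm).
#' @return a `connectome_graph`; the generating mesh is attached as
#'   attribute `mesh`, long-edge Euclidean lengths as attribute
#'   `long_edge_lengths`.
#' @export
synth_connectome <- function(order = 2, n_long_edges = 200,
                             distance_decay = 30, seed = 1,
                             frac_interhemi = 0.1,
                             radius = 70, gap = 10) {
  if (n_long_edges < 0) chd_input_error("n_long_edges must be >= 0")
  if (distance_decay <= 0) chd_input_error("distance_decay must be positive")
  off <- radius + gap / 2
  mesh <- combine_hemispheres(
    make_icosphere(order, radius = radius, center = c(-off, 0, 0)),
    make_icosphere(order, radius = radius, center = c(off, 0, 0)))
  n <- nrow(mesh$vertices)
  local <- mesh_edges(mesh)
  long <- matrix(integer(0), ncol = 2)
  lengths <- numeric(0)
  if (n_long_edges > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    hemi <- mesh$hemisphere
    key <- function(e) e[, 1] * (n + 1) + e[, 2]
    n_inter_target <- floor(n_long_edges * frac_interhemi)
    if (choose(n, 2) <= 3e6) {
      pairs <- t(utils::combn(n, 2L))
      pairs <- pairs[!(key(pairs) %in% key(local)), , drop = FALSE]
      d <- sqrt(rowSums((mesh$vertices[pairs[, 1], , drop = FALSE] -
                         mesh$vertices[pairs[, 2], , drop = FALSE])^2))
      inter <- hemi[pairs[, 1]] != hemi[pairs[, 2]]
      w <- exp(-d / distance_decay)
      n_inter <- min(n_inter_target, sum(inter))
      n_intra <- n_long_edges - n_inter
      if (n_intra > sum(!inter))
        chd_input_error("n_long_edges exceeds the number of available pairs")
      pick_intra <- sample(which(!inter), n_intra, prob = w[!inter])
      pick_inter <- if (n_inter > 0) sample(which(inter), n_inter, prob = w[inter]) else integer(0)
      pick <- c(pick_intra, pick_inter)
      long <- pairs[pick, , drop = FALSE]
      lengths <- d[pick]
    } else {
      # large graphs: rejection sampling with a uniform pair proposal and
      # acceptance exp(-d/decay) targets the same distribution without
      # enumerating choose(n, 2) pairs
      n_inter <- n_inter_target
      n_intra <- n_long_edges - n_inter
      seen <- key(local)
      acc <- matrix(integer(0), ncol = 2); accd <- numeric(0); acci <- logical(0)
      tries <- 0L
      while ((sum(!acci) < n_intra || sum(acci) < n_inter) && tries < 5000L) {
        tries <- tries + 1L
        i <- sample.int(n, 4096L, replace = TRUE)
        j <- sample.int(n, 4096L, replace = TRUE)
        ok <- i != j
        e <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
        e <- e[!(key(e) %in% seen), , drop = FALSE]
        if (nrow(e) == 0) next
        d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                           mesh$vertices[e[, 2], , drop = FALSE])^2))
        keep <- stats::runif(length(d)) < exp(-d / distance_decay)
        e <- e[keep, , drop = FALSE]; d <- d[keep]
        if (nrow(e) == 0) next
        seen <- c(seen, key(e))
        acc <- rbind(acc, e); accd <- c(accd, d)
        acci <- c(acci, hemi[e[, 1]] != hemi[e[, 2]])
      }
      if (sum(!acci) < n_intra || sum(acci) < n_inter)
        chd_input_error("n_long_edges exceeds the number of reachable pairs")
      pick <- c(which(!acci)[seq_len(n_intra)], which(acci)[seq_len(n_inter)])
      long <- acc[pick, , drop = FALSE]
      lengths <- accd[pick]
    }
  }
  g <- connectome_graph(edges_to_sparse(rbind(local, long), n),
                        local_edges = local, long_edges = long)
  attr(g, "mesh") <- mesh
  attr(g, "long_edge_lengths") <- lengths
  g
}

# --- persistent formats ------------------------------------------------------

#' Read / write an adjacency matrix in Matrix Market coordinate format
#'
#' @param graph a `connectome_graph` (for writing).
#' @param path file path (.mtx).
#' @return `read_graph_mtx` returns a `connectome_graph` (edge provenance is
#'   not stored in the format; all edges are reported as local).
#' @export
write_graph_mtx <- function(graph, path) {
  Matrix::writeMM(methods::as(graph$A, "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_graph_mtx
#' @export
read_graph_mtx <- function(path) {
  A <- methods::as(methods::as(Matrix::readMM(path), "dMatrix"), "CsparseMatrix")
  T3 <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  up <- T3@i < T3@j
  connectome_graph(A, local_edges = cbind(T3@i[up] + 1L, T3@j[up] + 1L))
}

#' Read / write long-range endpoint pairs as 2-column TSV
#'
#' On disk the indices are 0-based with a `# n_vertices=<n>` header; in
#' memory they are 1-based.
#'
#' @param pairs integer k x 2 matrix (1-based, for writing).
#' @param n_vertices vertex count recorded in the header.
#' @param path file path.
#' @return `read_long_edges` returns a list with `pairs` (1-based matrix) and
#'   `n_vertices`.
#' @export
write_long_edges <- function(pairs, n_vertices, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# n_vertices=%d", n_vertices), con)
  utils::write.table(pairs - 1L, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_long_edges
#' @export
read_long_edges <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^#\\s*n_vertices=", hdr))
    chd_format_error("missing '# n_vertices=' header in %s", path)
  n <- as.integer(sub("^#\\s*n_vertices=", "", hdr))
  tab <- utils::read.table(path, sep = "\t", comment.char = "#")
  pairs <- unname(as.matrix(tab[, 1:2])) + 1L
  if (nrow(pairs) > 0 && (min(pairs) < 1 || max(pairs) > n))
    chd_format_error("edge index out of range in %s", path)
  list(pairs = pairs, n_vertices = n)
}
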