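# Triangle surface meshes: construction (icosphere), edge extraction, and
# plain-ASCII OFF / PLY input-output. Vertex indices are 1-based in memory;
# the on-disk formats are 0-based as usual.

#' Construct a surface mesh object
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param hemisphere optional character vector of per-vertex tags
#'   (`"left"`/`"right"`).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, hemisphere = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) chd_input_error("vertices must be n x 3")
  if (nrow(vertices) == 0) chd_input_error("empty mesh")
  if (nrow(triangles) > 0) {
    if (min(triangles) < 1 || max(triangles) > nrow(vertices))
      chd_input_error("triangle index out of range")
    if (any(triangles[, 1] == triangles[, 2] |
            triangles[, 1] == triangles[, 3] |
            triangles[, 2] == triangles[, 3]))
      chd_input_error("degenerate triangle (repeated vertex index)")
  }
  if (!is.null(hemisphere) && length(hemisphere) != nrow(vertices))
    chd_input_error("hemisphere tags must match vertex count")
  structure(list(vertices = vertices, triangles = triangles,
                 hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Undirected edge set of a triangle mesh
#'
#' Edges are unordered vertex pairs appearing in at least one triangle;
#' duplicates collapsed.
#'
#' @param mesh a `surface_mesh`.
#' @return integer k x 2 matrix, each row `i < j`, rows sorted.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(matrix(integer(0), ncol = 2))
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Recursively subdivided icosahedron projected onto a sphere
#'
#' Subdivision order 0 is the icosahedron (12 vertices, 20 faces); each
#' subdivision splits every triangle in four, giving `10 * 4^order + 2`
#' vertices. Order 5 yields 10,242 vertices, the per-hemisphere resolution of
#' a standard FreeSurfer-style cortical surface graph.
#'
#' @param order non-negative integer subdivision order.
#' @param radius sphere radius (mm).
#' @param center length-3 numeric center.
#' @param max_order guard on recursion depth (default 6).
#' @return a `surface_mesh`.
#' @export
make_icosphere <- function(order, radius = 1, center = c(0, 0, 0),
                           max_order = 6L) {
  if (length(order) != 1 || is.na(order) || order < 0 || order != floor(order))
    chd_input_error("subdivision order must be a non-negative integer")
  if (order > max_order)
    chd_input_error("subdivision order %d exceeds maximum %d", order, max_order)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(order)) {
    nv <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
    key <- edges[, 1] * (nv + 1) + edges[, 2]
    mid_index <- stats::setNames(nv + seq_len(nrow(edges)), key)
    mids <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    m12 <- mid_index[as.character(ekey(f[, 1], f[, 2]))]
    m23 <- mid_index[as.character(ekey(f[, 2], f[, 3]))]
    m13 <- mid_index[as.character(ekey(f[, 1], f[, 3]))]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23),
               cbind(m12, m23, m13))
  }
  v <- sweep(v * radius, 2, center, `+`)
  surface_mesh(v, f)
}

#' Concatenate two hemisphere meshes into one two-block mesh
#'
#' Left-hemisphere vertices come first, then right; triangle indices of the
#' right mesh are offset accordingly.
#'
#' @param left,right `surface_mesh` objects.
#' @return a `surface_mesh` with `hemisphere` tags filled in.
#' @export
combine_hemispheres <- function(left, right) {
  nl <- nrow(left$vertices)
  surface_mesh(rbind(left$vertices, right$vertices),
               rbind(left$triangles, right$triangles + nl),
               hemisphere = c(rep("left", nl), rep("right", nrow(right$vertices))))
}

#' Read / write ASCII OFF meshes
#'
#' @param path file path.
#' @return `read_off` returns a `surface_mesh`.
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (toupper(trimws(ln[1])) != "OFF") chd_format_error("not an OFF file: %s", path)
  hdr <- scan(text = ln[2], quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  if (length(ln) < 2 + nv + nf) chd_format_error("truncated OFF file: %s", path)
  v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  f <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3)) chd_format_error("only triangle faces supported")
  surface_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' @rdname read_off
#' @param mesh a `surface_mesh`.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  invisible(path)
}

#' Read / write ASCII PLY triangle meshes
#'
#' Minimal ascii-1.0 reader: x/y/z vertex properties and triangular faces.
#'
#' @param path file path.
#' @return `read_ply` returns a `surface_mesh`.
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  if (trimws(ln[1]) != "ply") chd_format_error("not a PLY file: %s", path)
  end <- match("end_header", trimws(ln))
  if (is.na(end)) chd_format_error("PLY header not terminated")
  hdr <- ln[seq_len(end)]
  if (!any(grepl("^format\\s+ascii", hdr))) chd_format_error("only ascii PLY supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "", grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "", grep("element\\s+face", hdr, value = TRUE)[1]))
  body <- ln[-seq_len(end)]
  if (length(body) < nv + nf) chd_format_error("truncated PLY file: %s", path)
  v <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  f <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE), nrow = nf, byrow = TRUE)
  if (any(f[, 1] != 3)) chd_format_error("only triangle faces supported")
  surface_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' @rdname read_ply
#' @param mesh a `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  invisible(path)
}
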