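#' @keywords internal
chd_input_error <- function(msg, ...) {
  stop(structure(class = c("chd_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @keywords internal
chd_integrity_error <- function(msg, ...) {
  stop(structure(class = c("chd_integrity_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @keywords internal
chd_format_error <- function(msg, ...) {
  stop(structure(class = c("chd_format_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# md5 of a canonical text rendering; no digest package in the stack, so go
# through a temp file and tools::md5sum.
#' @keywords internal
md5_of_text <- function(lines) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(lines, f, sep = "\n")
  unname(tools::md5sum(f))
}

#' Fingerprint of a sparse adjacency matrix
#'
#' md5 over the canonical triplet form (sorted by column, then row) plus the
#' dimension; invariant to the storage class of the matrix. Used to tie a
#' harmonic basis to the graph it was computed from.
#'
#' @param A square sparse (or dense) matrix.
#' @return character md5 string.
#' @export
graph_fingerprint <- function(A) {
  if (inherits(A, "connectome_graph")) A <- A$A
  T3 <- as(as(as(A, "dMatrix"), "generalMatrix"), "TsparseMatrix")
  ord <- order(T3@j, T3@i)
  keep <- T3@x[ord] != 0
  md5_of_text(c(
    sprintf("n=%d", nrow(A)),
    sprintf("%d %d %.17g", T3@i[ord][keep], T3@j[ord][keep], T3@x[ord][keep])
  ))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# seeds derived from one master seed; kept below 2^31
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
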