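#' Binary fingerprint matrix
#'
#' Container for molecule substructure fingerprints: a binary 0/1 matrix with
#' one row per molecule (row names are molecule ids) plus a spec describing
#' how the fingerprints were produced, carried for provenance in every
#' downstream result.
#'
#' @param mat binary matrix (molecules x bits); row names are molecule ids.
#' @param spec named list describing the fingerprint (e.g. `type`, `n_bits`).
#' @return an object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(mat, spec = list()) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    stop("fingerprint matrix must carry molecule ids as row names", call. = FALSE)
  }
  if (!all(mat %in% c(0L, 1L))) {
    stop("fingerprint entries must be 0/1", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  spec$n_bits <- spec$n_bits %||% ncol(mat)
  structure(list(matrix = mat, spec = spec), class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_matrix> %d molecules x %d bits (%s)\n",
    nrow(x$matrix), ncol(x$matrix), x$spec$type %||% "unspecified"
  ))
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$matrix)

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) x$matrix

#' Subset a fingerprint matrix by molecule id or index
#'
#' @param x a `fingerprint_matrix`.
#' @param i molecule ids or row indices.
#' @param ... unused.
#' @export
`[.fingerprint_matrix` <- function(x, i, ...) {
  fingerprint_matrix(x$matrix[i, , drop = FALSE], x$spec)
}

fp_ids <- function(fp) rownames(fp$matrix)
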