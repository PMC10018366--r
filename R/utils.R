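#' Build splice-junction keys
#'
#' A junction is identified by its intronic interval: the first and last
#' intronic bases, 1-based inclusive, on a named chromosome. Keys are the
#' strings \code{"chrom:start:end"} used as row names of junction count
#' matrices.
#'
#' @param chrom Chromosome names.
#' @param start First intronic base (1-based, inclusive).
#' @param end Last intronic base (1-based, inclusive).
#' @return Character vector of junction keys.
#' @export
sj_key <- function(chrom, start, end) {
  stopifnot(all(nzchar(chrom)), all(start <= end))
  paste(chrom, start, end, sep = ":")
}

#' Parse splice-junction keys
#'
#' @param keys Character vector of \code{"chrom:start:end"} keys.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
parse_sj_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed junction key: ", keys[bad][1])
  }
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

# split a semicolon-joined junction-set column into a list of key vectors
split_sj_set <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(k) k[nzchar(k)])
}

join_sj_set <- function(keys) paste(keys, collapse = ";")

#' Write a dense count or value matrix as TSV
#'
#' Row identifiers go into a leading \code{id} column; values keep full
#' precision. The companion reader [read_matrix_tsv()] restores the matrix
#' element-wise identically for integer-valued input.
#'
#' @param mat Matrix with row and column names.
#' @param path Output file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(nrow(mat) == 0 || !is.null(rownames(mat)),
            !is.null(colnames(mat)))
  ids <- if (nrow(mat) == 0) character(0) else rownames(mat)
  df <- data.frame(id = ids, as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with an \code{id} column.
#' @return Numeric matrix with row names from \code{id}.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write a sparse count matrix as MatrixMarket triplets
#'
#' Emits the droplet-convention trio \code{matrix.mtx}, \code{barcodes.tsv}
#' (columns/cells) and \code{features.tsv} (rows) into a directory.
#'
#' @param mat A matrix or \code{Matrix::sparseMatrix} with dimnames.
#' @param dir Output directory (created if absent).
#' @export
write_sparse_mtx <- function(mat, dir) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as(as(mat, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket triplet directory
#'
#' @param dir Directory containing \code{matrix.mtx}, \code{barcodes.tsv},
#'   \code{features.tsv}.
#' @return A \code{dgCMatrix} with features as rows and barcodes as columns.
#' @export
read_sparse_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

# log2(x + 1): the one transformation used for all fold-change and
# "mean log2 expression" computations
log2p1 <- function(x) log2(x + 1)

# Benjamini-Hochberg via stats::p.adjust; NA-safe passthrough
bh_adjust <- function(p) p.adjust(p, method = "BH")
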