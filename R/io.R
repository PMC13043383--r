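#' Write a UMI count matrix in MatrixMarket triplet layout
#'
#' Writes `matrix.mtx` together with `genes.tsv` and `cells.tsv` sidecars,
#' the plain-text exchange layout used for droplet count matrices. Rows of
#' the matrix are cells and columns are genes, matching the in-memory
#' orientation used throughout the package.
#'
#' @param counts cells x genes matrix (dense or `Matrix` sparse) with
#'   dimnames.
#' @param dir output directory; created if missing.
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  paths <- file.path(dir, c("matrix.mtx", "cells.tsv", "genes.tsv"))
  Matrix::writeMM(m, paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  invisible(paths)
}

#' Read a UMI count matrix written by [write_count_matrix()]
#'
#' @param dir directory holding `matrix.mtx`, `cells.tsv`, `genes.tsv`.
#' @return sparse cells x genes matrix with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "cells.tsv")),
                      readLines(file.path(dir, "genes.tsv")))
  m
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors of gene identifiers; descriptions
#'   are kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("GMT lines without members: ", paste(which(bad), collapse = ", "))
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

# plain TSV writer shared by the pipeline outputs
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# echo generator parameters + seed next to written fixtures
.write_params_yaml <- function(params, path) {
  writeLines(yaml::as.yaml(params), path)
  invisible(path)
}
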