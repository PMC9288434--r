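#' Expression bundle: sparse counts with cell annotations
#'
#' The pipeline's container: a cells x genes sparse count matrix, an optional
#' normalized layer of identical shape, and per-cell annotations (tissue,
#' population, dataset). Constructed by [read_bundle()], [generate_cohort()]
#' or directly from components.
#'
#' @param counts Non-negative integer matrix or Matrix, cells x genes.
#' @param gene_ids Unique gene symbols, length = ncol(counts).
#' @param cell_ids Unique cell identifiers, length = nrow(counts).
#' @param cell_meta data.frame with columns `cell_id`, `tissue`,
#'   `population`, `dataset`, one row per cell, in cell order.
#' @param normalized Optional normalized layer, same shape as counts.
#' @return A validated object of class `expression_bundle`.
#' @export
expression_bundle <- function(counts, gene_ids, cell_ids, cell_meta,
                              normalized = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (!is.null(normalized)) {
    normalized <- methods::as(methods::as(Matrix::Matrix(normalized, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix")
    dimnames(normalized) <- list(cell_ids, gene_ids)
  }
  b <- structure(list(counts = counts, normalized = normalized,
                      gene_ids = as.character(gene_ids),
                      cell_ids = as.character(cell_ids),
                      cell_meta = cell_meta),
                 class = "expression_bundle")
  validate_bundle(b)
  b
}

#' @export
#' @method print expression_bundle
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d cells x %d genes; normalized: %s\n",
              length(x$cell_ids), length(x$gene_ids),
              if (is.null(x$normalized)) "no" else "yes"))
  tab <- table(x$cell_meta$tissue, x$cell_meta$population)
  print(tab)
  invisible(x)
}

validate_bundle <- function(b) {
  if (anyDuplicated(b$gene_ids)) stop("duplicate gene_ids in bundle")
  if (anyDuplicated(b$cell_ids)) stop("duplicate cell_ids in bundle")
  if (nrow(b$counts) != length(b$cell_ids) ||
      ncol(b$counts) != length(b$gene_ids))
    stop("counts shape does not match gene/cell identifiers")
  if (any(b$counts@x < 0)) stop("negative entries in counts")
  need <- c("cell_id", "tissue", "population", "dataset")
  if (!all(need %in% names(b$cell_meta)))
    stop("cell_meta must have columns ", paste(need, collapse = ", "))
  if (nrow(b$cell_meta) != length(b$cell_ids) ||
      !identical(as.character(b$cell_meta$cell_id), b$cell_ids))
    stop("cell_meta must have exactly one row per cell_id, in cell order")
  if (!is.null(b$normalized)) {
    if (!identical(dim(b$normalized), dim(b$counts)))
      stop("normalized layer must match counts shape")
    if (any(b$normalized@x < 0)) stop("negative entries in normalized layer")
  }
  invisible(TRUE)
}

#' Read an expression bundle from a directory
#'
#' Expects `matrix.mtx` (Matrix Market coordinate counts), `genes.tsv`
#' (column `gene_id`), `cells.tsv` (columns `cell_id`, `tissue`,
#' `population`, `dataset`), a one-line `manifest.tsv` declaring the on-disk
#' orientation, and optionally `normalized.mtx`. In memory the orientation is
#' always cells x genes.
#'
#' @param directory Path containing the files above.
#' @return An `expression_bundle`.
#' @export
read_bundle <- function(directory) {
  need <- c("matrix.mtx", "genes.tsv", "cells.tsv")
  for (f in need) {
    if (!file.exists(file.path(directory, f)))
      stop("missing file: ", file.path(directory, f))
  }
  orientation <- "cells_x_genes"
  mf <- file.path(directory, "manifest.tsv")
  if (file.exists(mf)) {
    man <- read.delim(mf, stringsAsFactors = FALSE)
    if ("orientation" %in% names(man)) orientation <- man$orientation[1]
  }
  counts <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  genes <- read.delim(file.path(directory, "genes.tsv"),
                      stringsAsFactors = FALSE)
  cells <- read.delim(file.path(directory, "cells.tsv"),
                      stringsAsFactors = FALSE)
  if (orientation == "genes_x_cells") counts <- Matrix::t(counts)
  normalized <- NULL
  nf <- file.path(directory, "normalized.mtx")
  if (file.exists(nf)) {
    normalized <- Matrix::readMM(nf)
    if (orientation == "genes_x_cells") normalized <- Matrix::t(normalized)
  }
  expression_bundle(counts, genes$gene_id, cells$cell_id, cells,
                    normalized = normalized)
}

#' Write an expression bundle to a directory
#'
#' Inverse of [read_bundle()]: writes `matrix.mtx`, `genes.tsv`, `cells.tsv`,
#' `manifest.tsv` and, when present, `normalized.mtx`. The normalized layer
#' is written with full double precision so that a write/read round trip
#' reproduces the bundle exactly.
#'
#' @param bundle An `expression_bundle`.
#' @param directory Output directory (created if absent).
#' @export
write_bundle <- function(bundle, directory) {
  validate_bundle(bundle)
  if (length(bundle$cell_ids) == 0 || length(bundle$gene_ids) == 0)
    stop("refusing to write a degenerate bundle with 0 cells or 0 genes")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  Matrix::writeMM(bundle$counts, file.path(directory, "matrix.mtx"))
  if (!is.null(bundle$normalized))
    write_mtx_real(bundle$normalized, file.path(directory, "normalized.mtx"))
  write.table(data.frame(gene_id = bundle$gene_ids),
              file.path(directory, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$cell_meta, file.path(directory, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(orientation = "cells_x_genes", format = "mtx_1based"),
              file.path(directory, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

# Matrix::writeMM prints reals at reduced precision; emit the normalized
# layer ourselves at %.17g so round trips are exact.
write_mtx_real <- function(m, path) {
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x)), con)
  if (length(tm@x))
    writeLines(sprintf("%d %d %.17g", tm@i + 1L, tm@j + 1L, tm@x), con)
  invisible(path)
}
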