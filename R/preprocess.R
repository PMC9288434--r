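#' Filter genes by detection count
#'
#' Keeps gene g iff it is detected (count > 0) in more than `min_cells`
#' cells; a gene detected in exactly `min_cells` cells is removed. Seed-panel
#' genes are exempt: a low-frequency TF (e.g. Runx1 in a small tissue) must
#' never be silently dropped before frequency analysis, so rescued panel
#' genes are kept and logged.
#'
#' @param bundle An `expression_bundle`.
#' @param min_cells Non-negative integer threshold (default 10).
#' @param panel Optional [seed_panel()]; its genes are exempt from removal.
#' @return Filtered `expression_bundle`.
#' @export
filter_genes <- function(bundle, min_cells = 10L, panel = NULL) {
  stopifnot(min_cells >= 0)
  ncells_per_gene <- Matrix::colSums(bundle$counts > 0)
  keep <- ncells_per_gene > min_cells
  if (!is.null(panel)) {
    rescued <- bundle$gene_ids %in% panel$seed_tfs & !keep
    if (any(rescued))
      hr_log("gene filter: rescued seed-panel gene(s) %s",
             paste(bundle$gene_ids[rescued], collapse = ", "))
    keep <- keep | bundle$gene_ids %in% panel$seed_tfs
  }
  if (!any(keep)) stop("gene filter removed every gene")
  subset_bundle(bundle, genes = which(keep))
}

#' Filter cells by detected-gene count
#'
#' Keeps cell c iff its number of detected genes (count > 0) is at least
#' `min_genes`. The per-cell detected-gene counts are attached to the result
#' as attribute `genes_per_cell` so the distribution can be inspected when
#' choosing a threshold.
#'
#' @param bundle An `expression_bundle`.
#' @param min_genes Non-negative integer threshold.
#' @return Filtered `expression_bundle` with attribute `genes_per_cell`.
#' @export
filter_cells <- function(bundle, min_genes = 1L) {
  stopifnot(min_genes >= 0)
  ngenes_per_cell <- Matrix::rowSums(bundle$counts > 0)
  keep <- ngenes_per_cell >= min_genes
  if (!any(keep)) stop("cell filter removed every cell")
  out <- subset_bundle(bundle, cells = which(keep))
  attr(out, "genes_per_cell") <- ngenes_per_cell
  out
}

#' Log-normalize counts
#'
#' Global-scaling normalization: each cell's counts are divided by the
#' cell's total count, multiplied by `scale` (10,000 by default) and
#' log-transformed, normalized(c,g) = ln(1 + count(c,g)/total(c) * scale).
#' The counts layer is preserved unchanged.
#'
#' @param bundle An `expression_bundle`; every cell must have total > 0.
#' @param scale Positive scale factor.
#' @return Bundle with the `normalized` layer filled in.
#' @export
lognormalize <- function(bundle, scale = 10000) {
  stopifnot(scale > 0)
  totals <- Matrix::rowSums(bundle$counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count; run filter_cells first")
  norm <- Matrix::Diagonal(x = scale / totals) %*% bundle$counts
  norm@x <- log1p(norm@x)
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(bundle$counts)
  bundle$normalized <- norm
  bundle
}

#' Detection mask
#'
#' Boolean cells x genes matrix, TRUE where the raw count is positive.
#' "Expressed" everywhere in this pipeline means raw count > 0.
#'
#' @param bundle An `expression_bundle`.
#' @return Sparse logical matrix, cells x genes.
#' @export
detection_mask <- function(bundle) {
  m <- bundle$counts > 0
  dimnames(m) <- dimnames(bundle$counts)
  m
}

subset_bundle <- function(bundle, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_along(bundle$cell_ids)
  if (is.null(genes)) genes <- seq_along(bundle$gene_ids)
  norm <- if (is.null(bundle$normalized)) NULL else
    bundle$normalized[cells, genes, drop = FALSE]
  expression_bundle(bundle$counts[cells, genes, drop = FALSE],
                    bundle$gene_ids[genes], bundle$cell_ids[cells],
                    bundle$cell_meta[cells, , drop = FALSE],
                    normalized = norm)
}
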