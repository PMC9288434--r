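#' Seed-TF detection frequency profile
#'
#' For every (tissue, population, TF) triple: the fraction of cells with a
#' positive count for the TF, the mean normalized expression among the
#' expressing cells only (the dot-plot convention; 0 when no cell expresses
#' it), the group size, and the frequency class — "moderate" above the
#' panel's 25% threshold, "low" at or below it.
#'
#' @param bundle An `expression_bundle` with a normalized layer.
#' @param panel A [seed_panel()]; its genes must be present in the bundle.
#' @return data.frame with columns tissue, population, tf, detect_fraction,
#'   mean_expr_in_expressing, n_cells, freq_class.
#' @export
tf_frequency <- function(bundle, panel) {
  if (is.null(bundle$normalized)) stop("normalized layer required")
  missing <- setdiff(panel$seed_tfs, bundle$gene_ids)
  if (length(missing))
    stop("panel gene(s) absent from bundle: ", paste(missing, collapse = ", "))
  groups <- split(seq_along(bundle$cell_ids),
                  list(tissue = bundle$cell_meta$tissue,
                       population = bundle$cell_meta$population),
                  drop = TRUE)
  mask <- detection_mask(bundle)[, panel$seed_tfs, drop = FALSE]
  norm <- bundle$normalized[, panel$seed_tfs, drop = FALSE]
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) == 0) {
      warning("group ", g, " has 0 cells; omitted")
      return(NULL)
    }
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    det <- Matrix::colSums(mask[idx, , drop = FALSE])
    expr_sum <- Matrix::colSums(norm[idx, , drop = FALSE])
    frac <- det / length(idx)
    data.frame(tissue = key[1], population = key[2], tf = panel$seed_tfs,
               detect_fraction = as.numeric(frac),
               mean_expr_in_expressing =
                 ifelse(det > 0, as.numeric(expr_sum) / pmax(det, 1), 0),
               n_cells = length(idx),
               freq_class = ifelse(frac > panel$moderate_freq_threshold,
                                   "moderate", "low"),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-cell co-expression counts
#'
#' Number of co-expression-subset TFs detected in each cell.
#'
#' @param mask Detection mask (cells x genes) from [detection_mask()].
#' @param subset_tfs Gene ids to count (default the panel's coexpr subset).
#' @return Integer vector, one entry per cell, named by cell id.
#' @export
coexpression_counts <- function(mask, subset_tfs) {
  missing <- setdiff(subset_tfs, colnames(mask))
  if (length(missing))
    stop("subset gene(s) absent: ", paste(missing, collapse = ", "))
  k <- Matrix::rowSums(mask[, subset_tfs, drop = FALSE])
  setNames(as.integer(k), rownames(mask))
}

#' Co-expression distribution per group
#'
#' For each (tissue, population) group: the exact count of cells detecting
#' k = 0..K subset TFs simultaneously, the non-increasing tail fractions
#' P(cell detects at least k), and k* — the largest k whose tail fraction is
#' still at least 0.5, the single-number summary used to compare tissues
#' ("more than 50% of cells co-express at least k* TFs").
#'
#' @param k_values Integer per-cell counts from [coexpression_counts()].
#' @param groups data.frame with columns tissue, population aligned to
#'   `k_values`.
#' @param K Panel size (maximum possible k).
#' @return List with `distribution` (tissue, population, k, n_cells_k,
#'   frac_at_least_k) and `summary` (tissue, population, n_cells, k_star,
#'   mean_k).
#' @export
coexpression_distribution <- function(k_values, groups, K) {
  stopifnot(length(k_values) == nrow(groups), all(k_values <= K))
  idx <- split(seq_along(k_values),
               list(tissue = groups$tissue, population = groups$population),
               drop = TRUE)
  dist_rows <- list(); sum_rows <- list()
  for (g in names(idx)) {
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    kv <- k_values[idx[[g]]]
    counts <- tabulate(kv + 1L, nbins = K + 1L)  # k = 0..K
    tail_frac <- rev(cumsum(rev(counts))) / length(kv)
    k_star <- max(c(0L, which(tail_frac >= 0.5) - 1L))
    dist_rows[[g]] <- data.frame(tissue = key[1], population = key[2],
                                 k = 0:K, n_cells_k = counts,
                                 frac_at_least_k = tail_frac,
                                 row.names = NULL)
    sum_rows[[g]] <- data.frame(tissue = key[1], population = key[2],
                                n_cells = length(kv), k_star = k_star,
                                mean_k = mean(kv), row.names = NULL)
  }
  list(distribution = do.call(rbind, c(dist_rows, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(sum_rows, list(make.row.names = FALSE))))
}
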