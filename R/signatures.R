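#' Pairwise overlap of seed-TF target sets
#'
#' Counts |T_i intersect T_j| for every TF pair, the row-normalized
#' fractions |T_i intersect T_j| / |T_j| (asymmetric), and the high-overlap
#' clique: the largest TF subset in which every pair overlaps reciprocally
#' by at least `clique_frac` in both directions, found by exhaustive subset
#' search (at most 2^11 subsets for the default panel).
#'
#' @param target_sets Named list mapping TF -> character vector of targets.
#' @param clique_frac Reciprocal-overlap fraction defining "high" overlap
#'   (default 0.5, anchored on the ~50% Runx1/Fli1 target overlap scale).
#' @return An `overlap_matrix`: list with `count` (symmetric), `frac`
#'   (frac\[i, j\] = count / |T_j|), `clique_tfs`, `tfs`.
#' @export
pairwise_overlap <- function(target_sets, clique_frac = 0.5) {
  tfs <- names(target_sets)
  stopifnot(length(tfs) >= 2)
  sizes <- lengths(target_sets)
  if (all(sizes == 0)) hr_log("pairwise_overlap: all target sets empty")
  k <- length(tfs)
  count <- matrix(0L, k, k, dimnames = list(tfs, tfs))
  for (i in seq_len(k)) for (j in seq_len(k))
    count[i, j] <- length(intersect(target_sets[[i]], target_sets[[j]]))
  frac <- sweep(count, 2, pmax(sizes, 1), "/")
  frac[, sizes == 0] <- 0
  # exhaustive max clique over TFs with nonempty sets
  nonempty <- which(sizes > 0)
  reciprocal <- matrix(FALSE, k, k)
  for (i in nonempty) for (j in nonempty)
    reciprocal[i, j] <- frac[i, j] >= clique_frac && frac[j, i] >= clique_frac
  best <- integer(0)
  if (length(nonempty) >= 2) {
    for (mask in seq_len(2^length(nonempty) - 1)) {
      members <- nonempty[bitwAnd(mask, 2^(seq_along(nonempty) - 1)) > 0]
      if (length(members) < 2) next  # a clique needs at least a pair
      if (length(members) <= length(best)) next
      ok <- TRUE
      for (a in members) {
        if (!all(reciprocal[a, setdiff(members, a)])) { ok <- FALSE; break }
      }
      if (ok) best <- members
    }
  }
  structure(list(count = count, frac = frac, tfs = tfs,
                 clique_tfs = tfs[best]),
            class = "overlap_matrix")
}

#' Split endothelial cells by a TF's detection
#'
#' Labels each endothelial cell of a tissue as `tf_pos` (raw count > 0) or
#' `tf_neg`. Both groups must have at least 3 cells; a tissue without any
#' TF-positive endothelial cells (the pancreas case for Runx1) is an
#' informative error.
#'
#' @param bundle An `expression_bundle`.
#' @param tissue Tissue name.
#' @param tf Gene symbol (default "Runx1").
#' @param population Population to split (default "endothelial").
#' @return Named factor (`tf_pos`/`tf_neg`) over the group's cell ids.
#' @export
split_by_tf <- function(bundle, tissue, tf = "Runx1",
                        population = "endothelial") {
  if (!tf %in% bundle$gene_ids) stop("gene not in bundle: ", tf)
  idx <- which(bundle$cell_meta$tissue == tissue &
               bundle$cell_meta$population == population)
  if (!length(idx)) stop("no ", population, " cells in tissue ", tissue)
  pos <- as.vector(bundle$counts[idx, tf] > 0)
  if (sum(pos) == 0)
    stop(sprintf("tissue %s contains no %s+ %s cells", tissue, tf,
                 population))
  if (sum(pos) < 3 || sum(!pos) < 3)
    stop(sprintf("tissue %s: %s+/%s- groups too small (%d/%d); >= 3 needed",
                 tissue, tf, tf, sum(pos), sum(!pos)))
  setNames(factor(ifelse(pos, "tf_pos", "tf_neg"),
                  levels = c("tf_pos", "tf_neg")),
           bundle$cell_ids[idx])
}

#' Marker genes of a cell split
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of normalized expression in
#' `tf_pos` versus `tf_neg` cells plus the log fold-change (difference of
#' mean log-normalized expression). Markers are the genes with
#' Holm-adjusted p < alpha and lfc > `lfc_min` in the positive group,
#' ranked by adjusted p then lfc.
#'
#' @param bundle An `expression_bundle` with normalized layer.
#' @param labels Factor from [split_by_tf()] (named by cell id).
#' @param alpha Significance level.
#' @param lfc_min Log fold-change gate (default 0.25).
#' @return data.frame gene, lfc, p, p_adj, marker — ordered by evidence.
#' @export
marker_genes <- function(bundle, labels, alpha = 0.05, lfc_min = 0.25) {
  if (is.null(bundle$normalized)) stop("normalized layer required")
  stopifnot(all(names(labels) %in% bundle$cell_ids))
  idx <- match(names(labels), bundle$cell_ids)
  pos <- idx[labels == "tf_pos"]
  neg <- idx[labels == "tf_neg"]
  if (length(pos) < 3 || length(neg) < 3)
    stop("both groups need >= 3 cells")
  m <- as.matrix(bundle$normalized[c(pos, neg), , drop = FALSE])
  grp <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  p <- apply(m, 2, function(v) {
    if (sd(v) == 0) return(1)
    suppressWarnings(wilcox.test(v[grp], v[!grp], exact = FALSE)$p.value)
  })
  lfc <- colMeans(m[grp, , drop = FALSE]) - colMeans(m[!grp, , drop = FALSE])
  hol <- holm_adjust(p, alpha)
  out <- data.frame(gene = colnames(m), lfc = as.numeric(lfc), p = p,
                    p_adj = hol$p_adj,
                    marker = hol$p_adj < alpha & lfc > lfc_min,
                    row.names = NULL)
  out[order(out$p_adj, -out$lfc), ]
}

#' Marker recurrence across tissues
#'
#' Given per-tissue marker gene lists, tabulates for every gene the set of
#' tissues in which it is a marker and flags as recurrent the genes found in
#' at least `min_tissues` tissues.
#'
#' @param marker_lists Named list mapping tissue -> character vector.
#' @param min_tissues Recurrence threshold (default 4).
#' @return List with `gene_tissues` (data.frame gene, n_tissues, tissues)
#'   and `recurrent_genes`.
#' @export
recurrence <- function(marker_lists, min_tissues = 4L) {
  stopifnot(length(marker_lists) >= min_tissues)
  per_tissue <- lapply(marker_lists, unique)
  genes <- sort(unique(unlist(per_tissue)))
  if (!length(genes))
    return(list(gene_tissues = data.frame(gene = character(0),
                                          n_tissues = integer(0),
                                          tissues = character(0)),
                recurrent_genes = character(0)))
  tissue_sets <- lapply(genes, function(g)
    names(per_tissue)[vapply(per_tissue, function(l) g %in% l, TRUE)])
  n <- lengths(tissue_sets)
  gt <- data.frame(gene = genes, n_tissues = n,
                   tissues = vapply(tissue_sets, paste, "", collapse = ","),
                   row.names = NULL)
  gt <- gt[order(-gt$n_tissues, gt$gene), ]
  list(gene_tissues = gt,
       recurrent_genes = gt$gene[gt$n_tissues >= min_tissues])
}
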