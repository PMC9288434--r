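#' Sign of a TF -> target relationship
#'
#' Spearman correlation between TF and target expression restricted to the
#' cells in which the TF is detected (value > 0): "positive" / "negative"
#' when |rho| >= 0.1, "none" when the association is weaker or fewer than 10
#' cells express the TF. Restricting to expressing cells avoids the
#' detection mask itself driving the sign.
#'
#' @param tf_expr,target_expr Numeric vectors over the population's cells
#'   (normalized expression).
#' @return One of "positive", "negative", "none".
#' @export
edge_sign <- function(tf_expr, target_expr) {
  on <- tf_expr > 0
  if (sum(on) < 10) return("none")
  rho <- suppressWarnings(cor(tf_expr[on], target_expr[on],
                              method = "spearman"))
  if (!is.finite(rho) || abs(rho) < 0.1) return("none")
  if (rho > 0) "positive" else "negative"
}

#' Infer a seed-TF regulatory network for one population
#'
#' Three stages, deterministic given `config$rng_seed`:
#'
#' 1. *Marginal network.* For every (seed TF, candidate target) pair the
#'    distance correlation on normalized expression is tested by
#'    permutation; p-values are Holm-adjusted per TF family across its
#'    candidates and edges with adjusted p < alpha are kept. Candidates are
#'    the non-seed genes detected in at least 10% of the population's cells
#'    (distance statistics carry no information on near-all-zero vectors).
#' 2. *Indirect-edge pruning.* For each kept edge (a, t) and every other
#'    seed TF b that also has a kept edge to t, the partial distance
#'    correlation pdcor(a, t; b) is compared with the unconditional
#'    bias-corrected dependence R*(a, t) on the same U-centered scale: if
#'    conditioning removes at least `pruning_drop_fraction` of it, or kills
#'    its permutation significance, the edge is marked `pruned_by = b` and a
#'    TF-TF interaction (a, b, t) is recorded.
#' 3. *Signs.* Surviving edges get a sign from [edge_sign()].
#'
#' @param bundle An `expression_bundle` with normalized layer.
#' @param panel A [seed_panel()].
#' @param tissue,population Group to analyse (>= 30 cells required).
#' @param config A [pipeline_config()].
#' @param early_stop_k Besag-Clifford early stopping for the permutation
#'   loops (0 disables; default 30 keeps null pairs cheap without changing
#'   which edges reach small p-values).
#' @return A `grn_result`: list with `tissue`, `population`, `n_cells`,
#'   `edges` (data.frame tf, target, dcor, p, p_adj, sign, pruned_by),
#'   `target_sets` (named list over TFs, retained edges only) and
#'   `interactions` (data.frame tf_a, tf_b, target).
#' @export
infer_network <- function(bundle, panel, tissue, population, config,
                          early_stop_k = 30L) {
  if (is.null(bundle$normalized)) stop("normalized layer required")
  idx <- which(bundle$cell_meta$tissue == tissue &
               bundle$cell_meta$population == population)
  n <- length(idx)
  if (n < 30)
    stop(sprintf("population %s/%s has %d cells; >= 30 required",
                 tissue, population, n))
  norm <- as.matrix(bundle$normalized[idx, , drop = FALSE])
  counts_det <- Matrix::colSums(bundle$counts[idx, , drop = FALSE] > 0)
  candidates <- setdiff(bundle$gene_ids[counts_det >= 0.10 * n],
                        panel$seed_tfs)
  empty <- grn_result(tissue, population, n, empty_edges(), panel)
  if (length(candidates) == 0) return(empty)

  perms <- make_perms(n, config$n_permutations, config$rng_seed)
  Ycand <- norm[, candidates, drop = FALSE]
  rows <- list()
  for (tf in panel$seed_tfs) {
    fam <- cpp_dcor_perm_family(norm[, tf], Ycand, perms,
                                as.integer(early_stop_k))
    p <- ifelse(fam$degenerate, 1.0, fam$p)
    hol <- holm_adjust(p, config$alpha)
    rows[[tf]] <- data.frame(
      tf = tf, target = candidates, dcor = fam$dcor,
      p = p, p_adj = hol$p_adj, row.names = NULL)
  }
  edges <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  edges <- edges[edges$p_adj < config$alpha, , drop = FALSE]
  edges$pruned_by <- rep(NA_character_, nrow(edges))
  edges$sign <- rep(NA_character_, nrow(edges))
  if (nrow(edges) == 0) return(empty)

  interactions <- list()
  targets_multi <- unique(edges$target[duplicated(edges$target)])
  for (t in targets_multi) {
    tfs_t <- edges$tf[edges$target == t]
    # unconditional bias-corrected dependence R*(a, t), same U-scale as pdcor
    marg <- vapply(tfs_t, function(a)
      cpp_pdcor(norm[, a], norm[, t], norm[, t])$Rxy, 0)
    for (bi in seq_along(tfs_t)) {
      b <- tfs_t[bi]
      # conditional-null permutations: shuffle the target within quantile
      # strata of the conditioning TF, preserving its target relationship
      perms_b <- make_stratified_perms(
        norm[, b], config$n_permutations_conditional,
        config$rng_seed + 131L * match(t, bundle$gene_ids) + bi)
      fam <- cpp_pdcor_prune_family(norm[, t], norm[, tfs_t, drop = FALSE],
                                    perms_b, as.integer(early_stop_k))
      if (isTRUE(fam$degenerate)) next
      for (ai in seq_along(tfs_t)) {
        if (ai == bi) next
        a <- tfs_t[ai]
        i <- which(edges$tf == a & edges$target == t)
        if (!is.na(edges$pruned_by[i])) next
        if (fam$pdcor[ai, bi] < config$pruning_drop_fraction * marg[ai] ||
            fam$p[ai, bi] > config$alpha) {
          edges$pruned_by[i] <- b
          interactions[[length(interactions) + 1L]] <-
            data.frame(tf_a = a, tf_b = b, target = t)
        }
      }
    }
  }
  retained <- is.na(edges$pruned_by)
  edges$sign[retained] <- vapply(which(retained), function(i)
    edge_sign(norm[, edges$tf[i]], norm[, edges$target[i]]), "")
  grn_result(tissue, population, n, edges, panel,
             interactions = if (length(interactions))
               do.call(rbind, interactions) else NULL)
}

empty_edges <- function() {
  data.frame(tf = character(0), target = character(0), dcor = numeric(0),
             p = numeric(0), p_adj = numeric(0),
             pruned_by = character(0), sign = character(0))
}

grn_result <- function(tissue, population, n_cells, edges, panel,
                       interactions = NULL) {
  retained <- edges[is.na(edges$pruned_by), , drop = FALSE]
  target_sets <- lapply(setNames(panel$seed_tfs, panel$seed_tfs),
                        function(tf) retained$target[retained$tf == tf])
  structure(list(tissue = tissue, population = population,
                 n_cells = n_cells, edges = edges,
                 target_sets = target_sets,
                 interactions = interactions %||%
                   data.frame(tf_a = character(0), tf_b = character(0),
                              target = character(0))),
            class = "grn_result")
}

#' @export
#' @method print grn_result
print.grn_result <- function(x, ...) {
  retained <- x$edges[is.na(x$edges$pruned_by), , drop = FALSE]
  cat(sprintf("<grn_result> %s/%s (%d cells): %d retained edge(s), %d pruned, %d interaction(s)\n",
              x$tissue, x$population, x$n_cells, nrow(retained),
              sum(!is.na(x$edges$pruned_by)), nrow(x$interactions)))
  invisible(x)
}
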