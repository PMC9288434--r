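#' Frequency score of a tissue
#'
#' Mean seed-TF detection fraction over the panel in the tissue's
#' endothelial population. A TF missing from the profile contributes 0
#' (logged).
#'
#' @param profile data.frame from [tf_frequency()].
#' @param tissue Tissue name.
#' @param panel A [seed_panel()].
#' @return A number in \[0, 1\].
#' @export
frequency_score <- function(profile, tissue, panel) {
  sub <- profile[profile$tissue == tissue &
                 profile$population == "endothelial", ]
  if (!nrow(sub)) stop("no endothelial frequency profile for ", tissue)
  frac <- setNames(rep(0, length(panel$seed_tfs)), panel$seed_tfs)
  hit <- intersect(panel$seed_tfs, sub$tf)
  if (length(hit) < length(panel$seed_tfs))
    hr_log("frequency_score(%s): missing TF(s) treated as 0: %s", tissue,
           paste(setdiff(panel$seed_tfs, hit), collapse = ", "))
  frac[hit] <- sub$detect_fraction[match(hit, sub$tf)]
  mean(frac)
}

#' Co-expression score of a tissue
#'
#' Mean per-cell number of co-detected subset TFs divided by the subset
#' size K: the average fraction of the co-expression panel a cell expresses
#' simultaneously. Under independent TFs at common frequency f the score
#' converges to f.
#'
#' @param coexpr Output of [coexpression_distribution()].
#' @param tissue Tissue name.
#' @param K Subset size.
#' @return A number in \[0, 1\].
#' @export
coexpression_score <- function(coexpr, tissue, K) {
  sub <- coexpr$summary[coexpr$summary$tissue == tissue &
                        coexpr$summary$population == "endothelial", ]
  if (!nrow(sub)) stop("no endothelial co-expression summary for ", tissue)
  sub$mean_k[1] / K
}

#' GRN score of a tissue
#'
#' Network evidence combined from the two outputs the ranking uses: the
#' fraction of seed TFs with at least one retained positive edge whose
#' target set is actually expressed by endothelial cells (assigned-cell
#' fraction > 0 in the activity analysis), and the size of the high-overlap
#' target-set clique relative to the panel; both terms weigh 1/2.
#'
#' @param grn A `grn_result` for the tissue's endothelial population.
#' @param activity_summary data.frame with columns tf, frac_assigned_endo
#'   (assigned endothelial fraction per seed TF), or NULL when no activity
#'   analysis ran (all fractions treated as 0 unless the TF has no edges).
#' @param overlap An `overlap_matrix` for the same population.
#' @param panel A [seed_panel()].
#' @return A number in \[0, 1\].
#' @export
grn_score <- function(grn, activity_summary, overlap, panel) {
  retained <- grn$edges[is.na(grn$edges$pruned_by), , drop = FALSE]
  if (!nrow(retained)) return(0)
  pos_tfs <- unique(retained$tf[retained$sign == "positive"])
  if (!is.null(activity_summary) && nrow(activity_summary)) {
    expressed <- activity_summary$tf[activity_summary$frac_assigned_endo > 0]
    pos_tfs <- intersect(pos_tfs, expressed)
  }
  n_pos <- length(pos_tfs)
  n_clique <- length(overlap$clique_tfs)
  0.5 * n_pos / length(panel$seed_tfs) +
    0.5 * n_clique / length(panel$seed_tfs)
}

#' Rank tissues by composite EHT-potential score
#'
#' Each component (frequency, co-expression, GRN) is divided by its maximum
#' across tissues; the composite is the unweighted mean of the three
#' normalized components and tissues are ranked by descending composite.
#' A component that is zero everywhere contributes 0 for all tissues and is
#' flagged. Exact composite ties are broken deterministically by raw
#' frequency score, then tissue name, and flagged.
#'
#' @param scorecards data.frame with columns tissue, freq_score,
#'   coexpr_score, grn_score (one row per tissue, >= 2 tissues).
#' @param weights Numeric length-3 aggregation weights (default equal).
#' @return data.frame with raw and normalized components, composite, rank,
#'   and a `tie` flag, ordered by rank.
#' @export
rank_tissues <- function(scorecards,
                         weights = c(freq = 1, coexpr = 1, grn = 1) / 3) {
  stopifnot(nrow(scorecards) >= 2, length(weights) == 3)
  weights <- weights / sum(weights)
  comp <- c("freq_score", "coexpr_score", "grn_score")
  normed <- sapply(comp, function(cn) {
    mx <- max(scorecards[[cn]])
    if (mx <= 0) {
      hr_log("rank_tissues: component %s is zero for all tissues", cn)
      rep(0, nrow(scorecards))
    } else scorecards[[cn]] / mx
  })
  colnames(normed) <- sub("_score", "_norm", comp)
  composite <- as.numeric(normed %*% weights)
  out <- cbind(scorecards, normed,
               data.frame(composite = composite))
  o <- order(-out$composite, -out$freq_score, out$tissue)
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(out$composite) | duplicated(out$composite,
                                                    fromLast = TRUE)
  if (any(out$tie))
    hr_log("rank_tissues: composite tie(s) broken by frequency score then tissue name")
  rownames(out) <- NULL
  out
}
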