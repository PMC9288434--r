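#' Per-cell gene rankings
#'
#' For each cell, genes are ranked from highest to lowest normalized value
#' (rank 1 = highest). Tied genes are shuffled by a seeded random draw, so
#' zeros end up randomly ordered at the bottom of the ranking. Each cell's
#' ranks are a permutation of 1..n_genes; the whole matrix is reproducible
#' given `seed`.
#'
#' @param bundle An `expression_bundle` with normalized layer.
#' @param cells Optional cell ids / indices to rank (default all).
#' @param seed Integer tie-break seed.
#' @return Integer matrix cells x genes of ranks.
#' @export
build_rankings <- function(bundle, cells = NULL, seed = 1L) {
  if (is.null(bundle$normalized)) stop("normalized layer required")
  m <- bundle$normalized
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  m <- as.matrix(m)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ranks <- t(apply(m, 1, function(v)
    rank(-v, ties.method = "random")))
  storage.mode(ranks) <- "integer"
  dimnames(ranks) <- dimnames(m)
  ranks
}

#' Recovery-curve AUC per cell
#'
#' For each cell the recovery curve steps through ranks 1..L
#' (L = floor(top_fraction * n_genes)) counting cumulative gene-set hits;
#' the AUC is the sum of the curve normalized by its maximum possible value,
#' attained when all set genes sit at the very top of the ranking. The score
#' is in \[0, 1\] and depends on the cell's expression only through ranks.
#'
#' @param rankings Matrix from [build_rankings()].
#' @param gene_set Character vector of gene ids.
#' @param top_fraction Fraction in (0,1) of the ranking to integrate over.
#' @return Named numeric vector of per-cell AUC scores.
#' @export
auc_score <- function(rankings, gene_set, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  set_in <- intersect(gene_set, colnames(rankings))
  if (length(set_in) == 0)
    stop("gene set has no genes in the ranking: ",
         paste(head(gene_set), collapse = ", "))
  n_genes <- ncol(rankings)
  L <- floor(top_fraction * n_genes)
  if (L < 1) stop("top_fraction too small: top window is empty")
  r <- rankings[, set_in, drop = FALSE]
  s <- length(set_in)
  # sum over ranks 1..L of hits(rank) = sum over set genes of (L - r + 1)+
  raw <- rowSums(pmax(L - r + 1L, 0L))
  max_raw <- sum(pmin(seq_len(L), s))
  setNames(raw / max_raw, rownames(rankings))
}

#' Threshold exploration on an AUC distribution
#'
#' Emulates picking a threshold between the two modes of a bimodal AUC
#' distribution: a two-component Gaussian mixture is fitted; when the
#' component means are separated by more than two pooled standard
#' deviations, the threshold is the equal-posterior point between the two
#' means; otherwise the distribution is flagged unimodal and the global 99th
#' percentile is used as a conservative fallback. Mixture fitting (mclust)
#' is deterministic, so the threshold is reproducible.
#'
#' @param auc_values Numeric vector of per-cell AUCs (>= 50 cells).
#' @return List with `threshold`, `bimodal` (flag) and `diagnostics`.
#' @export
explore_threshold <- function(auc_values) {
  stopifnot(length(auc_values) >= 50)
  fallback <- function(reason) {
    list(threshold = as.numeric(quantile(auc_values, 0.99)),
         bimodal = FALSE, diagnostics = reason)
  }
  if (sd(auc_values) < 1e-12) return(fallback("degenerate variance"))
  # Mclust resolves its helpers in the calling frame, so it must be called
  # from an environment whose namespace imports them (see package imports)
  fit <- tryCatch(
    Mclust(auc_values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback("mixture fit failed"))
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  pro <- fit$parameters$pro
  lo <- which.min(mu); hi <- which.max(mu)
  pooled <- sqrt(mean(sig^2))
  if (!is.finite(pooled) || pooled <= 0) return(fallback("degenerate variance"))
  if ((mu[hi] - mu[lo]) <= 2 * pooled) return(fallback("unimodal"))
  post_diff <- function(x)
    pro[hi] * dnorm(x, mu[hi], sig[hi]) - pro[lo] * dnorm(x, mu[lo], sig[lo])
  thr <- tryCatch(
    uniroot(post_diff, lower = mu[lo], upper = mu[hi])$root,
    error = function(e) (mu[lo] + mu[hi]) / 2)
  list(threshold = thr, bimodal = TRUE, diagnostics = "bimodal")
}

#' Per-cell Kruskal-Wallis significance of a gene set
#'
#' For each cell, a two-group Kruskal-Wallis test compares the rank values
#' of the gene-set genes against all remaining genes (null: equal mean
#' ranks). Because each cell's ranks are a tie-free permutation the
#' statistic has a closed form and a chi-squared (df = 1) reference
#' distribution; with two groups it is equivalent to the Wilcoxon rank-sum
#' normal approximation. P-values are Holm-corrected across cells.
#'
#' @param rankings Matrix from [build_rankings()].
#' @param gene_set Character vector (>= 2 genes after intersection; >= 2
#'   background genes).
#' @param alpha Significance level for the Holm flags.
#' @return data.frame with cell, p, p_adj, significant.
#' @export
kw_significance <- function(rankings, gene_set, alpha = 0.05) {
  set_in <- intersect(gene_set, colnames(rankings))
  N <- ncol(rankings)
  n1 <- length(set_in)
  n2 <- N - n1
  if (n1 < 2 || n2 < 2) stop("need >= 2 set genes and >= 2 background genes")
  R1 <- rowSums(rankings[, set_in, drop = FALSE]) / n1
  Rtot <- N * (N + 1) / 2
  R2 <- (Rtot - R1 * n1) / n2
  grand <- (N + 1) / 2
  H <- 12 / (N * (N + 1)) * (n1 * (R1 - grand)^2 + n2 * (R2 - grand)^2)
  p <- pchisq(H, df = 1, lower.tail = FALSE)
  hol <- holm_adjust(p, alpha)
  data.frame(cell = rownames(rankings), p = p, p_adj = hol$p_adj,
             significant = hol$significant, row.names = NULL)
}

#' Holm-Bonferroni stepwise correction
#'
#' The stepwise rule applied exactly as stated: p-values are sorted
#' smallest to largest; the i-th sorted p-value is compared with
#' alpha/(m - i + 1); the first one that is greater than or equal to its
#' threshold stops the procedure and it and all later hypotheses are
#' declared non-significant. Also returns the standard monotone
#' Holm-adjusted p-values (p_adj = cummax((m - i + 1) * p_sorted), capped at
#' 1, mapped back to input order). Flags are invariant to input order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param alpha Family-wise level.
#' @return List with `significant` (logical, input order) and `p_adj`.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  thresh <- alpha / (m - seq_len(m) + 1)
  pass <- ps < thresh
  first_fail <- match(FALSE, pass)
  sig_sorted <- if (is.na(first_fail)) rep(TRUE, m) else
    seq_len(m) < first_fail
  significant <- logical(m)
  significant[o] <- sig_sorted
  padj_sorted <- pmin(cummax((m - seq_len(m) + 1) * ps), 1)
  p_adj <- numeric(m)
  p_adj[o] <- padj_sorted
  list(significant = significant, p_adj = p_adj)
}

#' Assign cells expressing a target set
#'
#' A cell is assigned iff its AUC reaches the threshold AND its Holm-adjusted
#' Kruskal-Wallis p-value is below alpha — AUC alone says nothing about
#' significance, the rank test alone nothing about effect size.
#'
#' @param auc Named per-cell AUC vector.
#' @param threshold AUC threshold from [explore_threshold()].
#' @param p_adj Named (or aligned) per-cell adjusted p-values.
#' @param alpha Significance level.
#' @return Character vector of assigned cell ids.
#' @export
assign_cells <- function(auc, threshold, p_adj, alpha = 0.05) {
  stopifnot(length(auc) == length(p_adj))
  names(auc)[auc >= threshold & p_adj < alpha]
}

#' Target-set activity for one gene set in one tissue
#'
#' Convenience wrapper chaining rankings, AUC, threshold exploration,
#' per-cell Kruskal-Wallis significance and cell assignment, and summarizing
#' the assigned-cell fraction per population.
#'
#' @param bundle An `expression_bundle` with normalized layer.
#' @param tissue Tissue to analyse (rankings are built within it).
#' @param gene_set Target gene set (a seed TF's inferred targets).
#' @param gene_set_id Label (the seed TF).
#' @param config A [pipeline_config()].
#' @return An `activity_result`: list with `gene_set_id`, `auc`,
#'   `threshold`, `bimodal`, `p_adj`, `assigned_cells` and
#'   `population_summary` (population, n_cells, n_assigned, frac_assigned).
#' @export
target_activity <- function(bundle, tissue, gene_set, gene_set_id, config) {
  cells <- which(bundle$cell_meta$tissue == tissue)
  rk <- build_rankings(bundle, cells = cells, seed = config$rng_seed)
  auc <- auc_score(rk, gene_set, config$auc_top_fraction)
  thr <- explore_threshold(auc)
  kw <- kw_significance(rk, gene_set, config$alpha)
  assigned <- assign_cells(auc, thr$threshold, kw$p_adj, config$alpha)
  pop <- bundle$cell_meta$population[cells]
  summ <- do.call(rbind, lapply(split(seq_along(pop), pop), function(i) {
    data.frame(population = pop[i[1]], n_cells = length(i),
               n_assigned = sum(names(auc)[i] %in% assigned),
               frac_assigned = mean(names(auc)[i] %in% assigned),
               row.names = NULL)
  }))
  structure(list(gene_set_id = gene_set_id, tissue = tissue, auc = auc,
                 threshold = thr$threshold, bimodal = thr$bimodal,
                 p_adj = setNames(kw$p_adj, kw$cell),
                 assigned_cells = assigned, population_summary = summ),
            class = "activity_result")
}
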