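#' Run the full EHT-potential pipeline on a bundle
#'
#' End-to-end orchestration: gene/cell filtering and log-normalization,
#' seed-TF frequency and co-expression profiling per tissue and population,
#' regulatory-network inference for every endothelial population (and every
#' leukocyte population with enough cells — the white-blood-cell confound
#' check), per-TF target-set activity scoring and cell assignment,
#' pairwise target-set overlap analysis, Runx1-positive marker signatures
#' and their cross-tissue recurrence, and the composite max-normalized
#' tissue ranking.
#'
#' @param bundle An `expression_bundle` (raw counts; normalization is done
#'   here).
#' @param config A [pipeline_config()].
#' @param panel A [seed_panel()].
#' @return A `hemorank_result` list: `bundle` (preprocessed), `frequency`,
#'   `coexpression`, `grn` (per tissue/population), `activity`, `overlap`,
#'   `signatures` (markers + recurrence), `scorecards` (ranked).
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         panel = seed_panel()) {
  bundle <- filter_genes(bundle, config$filter_min_cells_per_gene, panel)
  bundle <- filter_cells(bundle, config$filter_min_genes_per_cell)
  bundle <- lognormalize(bundle, config$lognorm_scale)
  tissues <- unique(bundle$cell_meta$tissue)

  freq <- tf_frequency(bundle, panel)
  mask <- detection_mask(bundle)
  k8 <- coexpression_counts(mask, panel$coexpr_subset)
  coexpr <- coexpression_distribution(k8, bundle$cell_meta,
                                      K = length(panel$coexpr_subset))
  k11 <- coexpression_counts(mask, panel$seed_tfs)
  coexpr_full <- coexpression_distribution(k11, bundle$cell_meta,
                                           K = length(panel$seed_tfs))

  grns <- list(); activities <- list(); overlaps <- list()
  act_summaries <- list()
  for (ts in tissues) {
    for (pop in c("endothelial", "leukocyte")) {
      n <- sum(bundle$cell_meta$tissue == ts &
               bundle$cell_meta$population == pop)
      if (n < 30) next
      key <- paste(ts, pop, sep = "/")
      hr_log("inferring network for %s (%d cells)", key, n)
      grns[[key]] <- infer_network(bundle, panel, ts, pop, config)
      sets <- Filter(length, grns[[key]]$target_sets)
      if (length(sets) >= 2)
        overlaps[[key]] <- pairwise_overlap(sets)
    }
    grn_ec <- grns[[paste(ts, "endothelial", sep = "/")]]
    if (is.null(grn_ec)) next
    rows <- list()
    for (tf in panel$seed_tfs) {
      set <- grn_ec$target_sets[[tf]]
      if (length(set) < 2) next
      act <- target_activity(bundle, ts, set, tf, config)
      activities[[paste(ts, tf, sep = "/")]] <- act
      endo <- act$population_summary[
        act$population_summary$population == "endothelial", ]
      rows[[tf]] <- data.frame(tissue = ts, tf = tf,
                               frac_assigned_endo =
                                 if (nrow(endo)) endo$frac_assigned else 0)
    }
    act_summaries[[ts]] <- if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  }

  markers <- list()
  for (ts in tissues) {
    res <- tryCatch({
      labels <- split_by_tf(bundle, ts, tf = "Runx1")
      mk <- marker_genes(bundle, labels, config$alpha)
      setdiff(mk$gene[mk$marker], "Runx1")  # the split gene is a given
    }, error = function(e) {
      hr_log("signatures: skipping %s (%s)", ts, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) markers[[ts]] <- res
  }
  recur <- if (length(markers) >= config$recurrence_min_tissues)
    recurrence(markers, config$recurrence_min_tissues)
  else {
    hr_log("signatures: only %d tissue(s) with a Runx1 split; recurrence needs %d",
           length(markers), config$recurrence_min_tissues)
    list(gene_tissues = NULL, recurrent_genes = character(0))
  }

  cards <- do.call(rbind, lapply(tissues, function(ts) {
    key <- paste(ts, "endothelial", sep = "/")
    g <- if (!is.null(grns[[key]]))
      grn_score(grns[[key]], act_summaries[[ts]], overlaps[[key]] %||%
                  structure(list(clique_tfs = character(0)),
                            class = "overlap_matrix"), panel)
    else 0
    data.frame(tissue = ts,
               freq_score = frequency_score(freq, ts, panel),
               coexpr_score = coexpression_score(coexpr, ts,
                                                 length(panel$coexpr_subset)),
               grn_score = g)
  }))
  scorecards <- rank_tissues(cards)

  structure(list(bundle = bundle, frequency = freq,
                 coexpression = coexpr, coexpression_full_panel = coexpr_full,
                 grn = grns, activity = activities,
                 activity_summaries = act_summaries,
                 overlap = overlaps,
                 signatures = list(markers = markers, recurrence = recur),
                 scorecards = scorecards),
            class = "hemorank_result")
}

#' @export
#' @method print hemorank_result
print.hemorank_result <- function(x, ...) {
  cat("<hemorank_result>\n")
  cat(sprintf("  %d tissues, %d networks, %d activity analyses\n",
              length(unique(x$scorecards$tissue)), length(x$grn),
              length(x$activity)))
  cat("  ranking:\n")
  print(x$scorecards[, c("tissue", "freq_score", "coexpr_score",
                         "grn_score", "composite", "rank")])
  invisible(x)
}

#' Write pipeline result tables to a directory
#'
#' TSV outputs: frequency profile, co-expression distributions, edge lists
#' per network, overlap counts, marker recurrence and the scorecard.
#'
#' @param result A `hemorank_result`.
#' @param dir Output directory.
#' @export
write_result_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(result$frequency, "tf_frequency.tsv")
  wt(result$coexpression$distribution, "coexpression_distribution.tsv")
  wt(result$coexpression$summary, "coexpression_summary.tsv")
  edges <- do.call(rbind, lapply(names(result$grn), function(k) {
    e <- result$grn[[k]]$edges
    if (!nrow(e)) return(NULL)
    cbind(data.frame(tissue = result$grn[[k]]$tissue,
                     population = result$grn[[k]]$population), e)
  }))
  if (!is.null(edges)) wt(edges, "grn_edges.tsv")
  ov <- do.call(rbind, lapply(names(result$overlap), function(k) {
    m <- result$overlap[[k]]$count
    data.frame(group = k,
               tf_a = rep(rownames(m), ncol(m)),
               tf_b = rep(colnames(m), each = nrow(m)),
               count = as.vector(m),
               frac = as.vector(result$overlap[[k]]$frac))
  }))
  if (!is.null(ov)) wt(ov, "target_overlap.tsv")
  if (!is.null(result$signatures$recurrence$gene_tissues))
    wt(result$signatures$recurrence$gene_tissues, "runx1_recurrence.tsv")
  wt(result$scorecards, "tissue_scorecards.tsv")
  invisible(dir)
}
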