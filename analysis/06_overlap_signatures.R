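#!/usr/bin/env Rscript
# Target-set overlap analysis (pairwise counts, row-normalized fractions,
# exhaustively verified high-overlap cliques) for every inferred network,
# plus Runx1+ endothelial signatures: rank-sum marker genes of
# Runx1-expressing vs non-expressing endothelial cells per tissue and
# their recurrence across tissues.
#
# Usage: Rscript analysis/06_overlap_signatures.R

suppressMessages(library(hemorank))

bundle <- read_bundle("results/preprocessed")
nets <- readRDS("results/grn/networks.rds")
cfg <- cohort_config()
dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)

ov_rows <- list()
for (key in names(nets)) {
  sets <- Filter(length, nets[[key]]$target_sets)
  if (length(sets) < 2) next
  ov <- pairwise_overlap(sets)
  message(sprintf("%-24s clique: %s", key,
                  if (length(ov$clique_tfs))
                    paste(ov$clique_tfs, collapse = ",") else "none"))
  m <- ov$count
  ov_rows[[key]] <- data.frame(group = key,
                               tf_a = rep(rownames(m), ncol(m)),
                               tf_b = rep(colnames(m), each = nrow(m)),
                               count = as.vector(m),
                               frac = as.vector(ov$frac))
}
write.table(do.call(rbind, ov_rows), "results/signatures/overlap.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

markers <- list()
for (ts in unique(bundle$cell_meta$tissue)) {
  res <- tryCatch({
    labels <- split_by_tf(bundle, ts, tf = "Runx1")
    mk <- marker_genes(bundle, labels, cfg$alpha)
    setdiff(mk$gene[mk$marker], "Runx1")
  }, error = function(e) {
    message(sprintf("%s: %s", ts, conditionMessage(e)))
    NULL
  })
  if (!is.null(res)) markers[[ts]] <- res
}
rec <- recurrence(markers, cfg$recurrence_min_tissues)
write.table(rec$gene_tissues, "results/signatures/runx1_recurrence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d genes recur as Runx1+ markers in >= %d tissues: %s",
                length(rec$recurrent_genes), cfg$recurrence_min_tissues,
                paste(rec$recurrent_genes, collapse = ", ")))
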