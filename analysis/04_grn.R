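#!/usr/bin/env Rscript
# Seed-TF regulatory network inference per tissue: distance correlation
# against every candidate target with permutation significance (Holm per
# TF family), partial-distance-correlation pruning of edges explained by a
# co-seed, and Spearman-based signs. Endothelial populations always; the
# leukocyte population too where present (the white-blood-cell confound
# check).
#
# Usage: Rscript analysis/04_grn.R [seed]

suppressMessages(library(hemorank))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

bundle <- read_bundle("results/preprocessed")
cfg <- cohort_config(rng_seed = seed)
panel <- seed_panel()
dir.create("results/grn", showWarnings = FALSE, recursive = TRUE)

nets <- list()
for (ts in unique(bundle$cell_meta$tissue)) {
  for (pop in c("endothelial", "leukocyte")) {
    n <- sum(bundle$cell_meta$tissue == ts & bundle$cell_meta$population == pop)
    if (n < 30) next
    net <- infer_network(bundle, panel, ts, pop, cfg)
    nets[[paste(ts, pop, sep = "/")]] <- net
    retained <- net$edges[is.na(net$edges$pruned_by), ]
    message(sprintf("%-24s %3d retained edges, %2d pruned, %2d interactions",
                    paste(ts, pop, sep = "/"), nrow(retained),
                    sum(!is.na(net$edges$pruned_by)), nrow(net$interactions)))
    if (nrow(net$edges))
      write.table(cbind(tissue = ts, population = pop, net$edges),
                  sprintf("results/grn/edges_%s_%s.tsv", ts, pop),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
saveRDS(nets, "results/grn/networks.rds")  # scratch for downstream steps
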