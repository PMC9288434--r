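#!/usr/bin/env Rscript
# Quality filtering and log-normalization of the simulated cohort:
# genes must be detected in more than 10 cells (seed-panel genes exempt),
# cells must detect at least one gene, and counts are LogNormalized with
# the standard 10,000 scale factor.
#
# Usage: Rscript analysis/02_preprocess.R

suppressMessages(library(hemorank))

bundle <- read_bundle("results/bundle")
cfg <- cohort_config()
panel <- seed_panel()

n0 <- c(length(bundle$cell_ids), length(bundle$gene_ids))
bundle <- filter_genes(bundle, cfg$filter_min_cells_per_gene, panel)
bundle <- filter_cells(bundle, cfg$filter_min_genes_per_cell)
bundle <- lognormalize(bundle, cfg$lognorm_scale)

dir.create("results/preprocessed", showWarnings = FALSE, recursive = TRUE)
write_bundle(bundle, "results/preprocessed")
message(sprintf("filtered %d x %d -> %d cells x %d genes; normalized layer added",
                n0[1], n0[2], length(bundle$cell_ids),
                length(bundle$gene_ids)))
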