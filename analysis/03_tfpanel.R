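#!/usr/bin/env Rscript
# Seed-TF expression frequency and single-cell co-expression profiling per
# tissue and population: detection fractions with the moderate/low class at
# the 25% threshold, and the distribution of how many of the 8
# co-expression-subset TFs (and, separately, of the full 11-TF panel) each
# cell detects simultaneously.
#
# Usage: Rscript analysis/03_tfpanel.R

suppressMessages(library(hemorank))

bundle <- read_bundle("results/preprocessed")
panel <- seed_panel()
dir.create("results/tfpanel", showWarnings = FALSE, recursive = TRUE)

freq <- tf_frequency(bundle, panel)
write.table(freq, "results/tfpanel/tf_frequency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mask <- detection_mask(bundle)
for (variant in c("coexpr_subset", "full_panel")) {
  genes <- if (variant == "coexpr_subset") panel$coexpr_subset else
    panel$seed_tfs
  k <- coexpression_counts(mask, genes)
  cd <- coexpression_distribution(k, bundle$cell_meta, K = length(genes))
  write.table(cd$distribution,
              sprintf("results/tfpanel/coexpression_%s.tsv", variant),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cd$summary,
              sprintf("results/tfpanel/coexpression_%s_summary.tsv", variant),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

endo <- freq[freq$population == "endothelial", ]
message("mean endothelial panel detection by tissue:")
for (ts in unique(endo$tissue))
  message(sprintf("  %-12s %.2f", ts,
                  mean(endo$detect_fraction[endo$tissue == ts])))
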