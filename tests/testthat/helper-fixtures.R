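# Small in-code fixtures shared across test files.

toy_bundle <- function(normalized = FALSE) {
  counts <- matrix(c(2, 0, 5, 1,
                     0, 0, 3, 0,
                     0, 1, 4, 2,
                     7, 2, 0, 0), nrow = 4, byrow = TRUE)
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     tissue = c("t1", "t1", "t2", "t2"),
                     population = c("endothelial", "other",
                                    "endothelial", "endothelial"),
                     dataset = "toy")
  b <- expression_bundle(counts, paste0("g", 1:4), meta$cell_id, meta)
  if (normalized) b <- lognormalize(b) else b
}

# a bundle with the full seed panel plus a few extra genes, handy for
# panel-facing functions
panel_bundle <- function(n = 60, seed = 1, freq = 0.5) {
  set.seed(seed)
  tfs <- seed_panel()$seed_tfs
  genes <- c(tfs, paste0("x", 1:5))
  counts <- matrix(rbinom(n * length(genes), 1, freq) *
                     (1 + rpois(n * length(genes), 4)),
                   nrow = n, dimnames = list(NULL, genes))
  meta <- data.frame(cell_id = sprintf("pc%03d", 1:n), tissue = "tt",
                     population = "endothelial", dataset = "toy")
  lognormalize(expression_bundle(counts, genes, meta$cell_id, meta))
}
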