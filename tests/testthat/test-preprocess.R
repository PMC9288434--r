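test_that("gene filter applies the strict more-than-min_cells rule", {
  # gene a: detected in exactly 10 cells; gene b: in 11
  counts <- cbind(a = c(rep(1, 10), rep(0, 10)),
                  b = c(rep(1, 11), rep(0, 9)),
                  c = rep(1, 20))
  meta <- data.frame(cell_id = paste0("c", 1:20), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- expression_bundle(counts, c("a", "b", "c"), meta$cell_id, meta)
  f <- filter_genes(b, min_cells = 10)
  expect_identical(f$gene_ids, c("b", "c"))
  f0 <- filter_genes(b, min_cells = 0)
  expect_identical(f0$gene_ids, c("a", "b", "c"))
  expect_error(filter_genes(b, min_cells = 25), "every gene")
})

test_that("seed-panel genes are rescued from the gene filter", {
  n <- 30
  counts <- cbind(Runx1 = c(1, rep(0, n - 1)), other = rep(2, n))
  meta <- data.frame(cell_id = paste0("c", 1:n), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- expression_bundle(counts, c("Runx1", "other"), meta$cell_id, meta)
  f <- filter_genes(b, min_cells = 10, panel = seed_panel())
  expect_true("Runx1" %in% f$gene_ids)
})

test_that("cell filter keeps cells at or above min_genes and reports the histogram", {
  counts <- matrix(0, 4, 80)
  counts[1, 1:5] <- 1; counts[2, 1:50] <- 1
  counts[3, 1:60] <- 1; counts[4, 1:70] <- 1
  meta <- data.frame(cell_id = paste0("c", 1:4), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- expression_bundle(counts, paste0("g", 1:80), meta$cell_id, meta)
  f <- filter_cells(b, min_genes = 10)
  expect_equal(length(f$cell_ids), 3)
  expect_equal(as.numeric(attr(f, "genes_per_cell")), c(5, 50, 60, 70))
  expect_identical(filter_cells(b, 0)$cell_ids, b$cell_ids)
})

test_that("filters are idempotent", {
  b <- panel_bundle(n = 40)
  f1 <- filter_genes(b, 5)
  expect_identical(filter_genes(f1, 5)$gene_ids, f1$gene_ids)
  c1 <- filter_cells(b, 3)
  expect_identical(filter_cells(c1, 3)$cell_ids, c1$cell_ids)
})

test_that("lognormalize implements ln(1 + count/total * scale) and preserves counts", {
  counts <- matrix(c(1, 3, 0, 0), nrow = 1)
  meta <- data.frame(cell_id = "c1", tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- expression_bundle(counts, paste0("g", 1:4), "c1", meta)
  nb <- lognormalize(b, scale = 10000)
  expect_equal(nb$normalized[1, 1], log(1 + 1 / 4 * 10000), tolerance = 1e-12)
  expect_equal(nb$normalized[1, 1], log(2501), tolerance = 1e-12)
  expect_equal(nb$normalized[1, 3], 0)
  expect_identical(as.matrix(nb$counts), as.matrix(b$counts))
  # totals equal to scale cancel: normalized = ln(1 + count)
  counts2 <- matrix(c(2000, 3000, 5000), nrow = 1)  # total = scale
  b2 <- expression_bundle(counts2, paste0("g", 1:3), "c1", meta)
  nb2 <- lognormalize(b2, scale = 10000)
  expect_equal(as.numeric(nb2$normalized[1, ]), log(1 + c(2000, 3000, 5000)),
               tolerance = 1e-12)
})

test_that("lognormalize is monotone within each cell and rejects empty cells", {
  b <- panel_bundle(n = 25)
  nb <- lognormalize(b)
  v <- as.numeric(b$counts[3, ]); w <- as.numeric(nb$normalized[3, ])
  expect_true(all(sign(outer(v, v, "-")) == sign(outer(w, w, "-"))))
  empty <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE)
  meta <- data.frame(cell_id = c("c1", "c2"), tissue = "t",
                     population = "endothelial", dataset = "d")
  be <- expression_bundle(empty, c("g1", "g2"), meta$cell_id, meta)
  expect_error(lognormalize(be), "filter_cells")
})

test_that("detection mask marks exactly the positive counts", {
  b <- toy_bundle()
  m <- detection_mask(b)
  expect_identical(as.matrix(m), as.matrix(b$counts) > 0)
  expect_equal(as.numeric(Matrix::rowSums(m)),
               as.numeric(Matrix::rowSums(b$counts > 0)))
})
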