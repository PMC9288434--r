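test_that("overlap counts equal brute-force set intersections and the matrix is symmetric", {
  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"), c = c("q"))
  ov <- pairwise_overlap(sets)
  expect_equal(ov$count["a", "b"], 2L)
  expect_equal(ov$count["a", "c"], 0L)
  expect_identical(ov$count, t(ov$count))
  expect_equal(diag(ov$count), setNames(c(3L, 3L, 1L), c("a", "b", "c")))
  expect_equal(ov$frac["a", "b"], 2 / 3)   # |a n b| / |b|
  expect_equal(diag(ov$frac), setNames(rep(1, 3), c("a", "b", "c")))
})

test_that("identical sets form a full clique; the clique is found exhaustively", {
  sets <- setNames(rep(list(letters[1:6]), 8), paste0("tf", 1:8))
  ov <- pairwise_overlap(sets)
  expect_setequal(ov$clique_tfs, paste0("tf", 1:8))
  # a disjoint pair plus a reciprocal pair: clique is exactly the pair
  sets2 <- list(a = c("x", "y"), b = c("x", "y"), c = c("p", "q"))
  expect_setequal(pairwise_overlap(sets2)$clique_tfs, c("a", "b"))
  # one-sided overlap (frac >= 0.5 in one direction only) is not a clique
  sets3 <- list(big = paste0("g", 1:10), small = c("g1", "g2"))
  expect_length(pairwise_overlap(sets3)$clique_tfs, 0)
})

test_that("fifty percent reciprocal overlap sits exactly on the clique boundary", {
  sets <- list(Runx1 = c("a", "b", "c", "d"), Fli1 = c("c", "d", "e", "f"))
  ov <- pairwise_overlap(sets)
  expect_equal(ov$frac["Runx1", "Fli1"], 0.5)
  expect_setequal(ov$clique_tfs, c("Runx1", "Fli1"))
})

test_that("splitting by TF labels positive and negative cells and rejects degenerate splits", {
  n <- 100
  counts <- cbind(Runx1 = c(rep(3, 12), rep(0, n - 12)),
                  other = rep(1, n))
  meta <- data.frame(cell_id = paste0("c", 1:n), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- expression_bundle(counts, c("Runx1", "other"), meta$cell_id, meta)
  lab <- split_by_tf(b, "t")
  expect_equal(sum(lab == "tf_pos"), 12)
  expect_equal(sum(lab == "tf_neg"), 88)

  all_on <- expression_bundle(cbind(Runx1 = rep(2, 10), o = 1),
                              c("Runx1", "o"), paste0("c", 1:10),
                              data.frame(cell_id = paste0("c", 1:10),
                                         tissue = "t",
                                         population = "endothelial",
                                         dataset = "d"))
  expect_error(split_by_tf(all_on, "t"), "too small")
  none_on <- expression_bundle(cbind(Runx1 = rep(0, 10), o = 1),
                               c("Runx1", "o"), paste0("c", 1:10),
                               data.frame(cell_id = paste0("c", 1:10),
                                          tissue = "t",
                                          population = "endothelial",
                                          dataset = "d"))
  expect_error(split_by_tf(none_on, "t"), "no Runx1\\+")
})

test_that("marker detection finds a strongly separated gene and gates on fold change", {
  set.seed(6)
  n <- 100
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  counts <- cbind(Runx1 = ifelse(grp, 5, 0),
                  updiff = ifelse(grp, rpois(n, 30), rpois(n, 2)),
                  flat = rpois(n, 10),
                  base = rpois(n, 20) + 1)
  meta <- data.frame(cell_id = paste0("c", 1:n), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- lognormalize(expression_bundle(counts,
                                      c("Runx1", "updiff", "flat", "base"),
                                      meta$cell_id, meta))
  mk <- marker_genes(b, split_by_tf(b, "t"))
  expect_true(mk$marker[mk$gene == "updiff"])
  expect_lt(mk$p_adj[mk$gene == "updiff"], 1e-6)
  expect_false(mk$marker[mk$gene == "flat"])
})

test_that("marker detection respects the null (label permutation keeps markers at chance)", {
  set.seed(9)
  n <- 80
  counts <- matrix(rpois(n * 20, 8), nrow = n,
                   dimnames = list(NULL, paste0("g", 1:20)))
  counts <- cbind(counts, Runx1 = rbinom(n, 1, 0.4) * 3)
  meta <- data.frame(cell_id = paste0("c", 1:n), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- lognormalize(expression_bundle(counts, colnames(counts),
                                      meta$cell_id, meta))
  mk <- marker_genes(b, split_by_tf(b, "t"))
  expect_lte(sum(mk$marker[mk$gene != "Runx1"]), 1)
})

test_that("recurrence thresholds and boundaries behave as stated", {
  lists <- c(setNames(rep(list(c("m1", "m2")), 4), paste0("t", 1:4)),
             list(t5 = "m2", t6 = c("m2", "m3")))
  r <- recurrence(lists, min_tissues = 4)
  expect_setequal(r$recurrent_genes, c("m1", "m2"))
  expect_equal(r$gene_tissues$n_tissues[r$gene_tissues$gene == "m2"], 6L)
  r6 <- recurrence(lists, min_tissues = 6)
  expect_identical(r6$recurrent_genes, "m2")
  # order and duplicates within a tissue do not matter
  lists2 <- rev(lapply(lists, function(l) c(l, l)))
  expect_setequal(recurrence(lists2, 4)$recurrent_genes, r$recurrent_genes)
})
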