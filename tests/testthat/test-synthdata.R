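test_that("planted detection frequencies are honored at the extremes and in expectation", {
  tfs <- seed_panel()$seed_tfs
  freqs <- setNames(rep(0.5, 11), tfs)
  freqs["Runx1"] <- 0; freqs["Fli1"] <- 1
  spec <- tissue_spec("x", c(endothelial = 2000L), freqs, dropout_rate = 0)
  g <- generate_tissue(spec, seed = 123)
  mask <- g$counts > 0
  expect_equal(sum(mask[, "Runx1"]), 0)
  expect_equal(mean(mask[, "Fli1"]), 1)
  obs <- mean(mask[, "Tal1"])
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("generation is bit-reproducible given a seed and varies across seeds", {
  spec <- default_cohort()[[1]]
  a <- generate_tissue(spec, seed = 9)
  b <- generate_tissue(spec, seed = 9)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$tf_states, b$tf_states)
  c2 <- generate_tissue(spec, seed = 10)
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))

  ch1 <- generate_cohort(default_cohort(), seed = 4)
  ch2 <- generate_cohort(default_cohort(), seed = 4)
  expect_identical(as.matrix(ch1$bundle$counts), as.matrix(ch2$bundle$counts))
  expect_identical(ch1$truth$true_tissue_order, ch2$truth$true_tissue_order)
})

test_that("the default cohort has the documented structure", {
  specs <- default_cohort()
  ch <- generate_cohort(specs, seed = 1)
  expect_setequal(unique(ch$bundle$cell_meta$tissue),
                  c("embryo_AGM", "brain", "heart", "kidney", "liver",
                    "pancreas"))
  expect_identical(ch$truth$true_tissue_order[1], "embryo_AGM")
  expect_identical(ch$truth$true_tissue_order[6], "pancreas")
  # embryo: all 11 frequencies >= 0.9 and planted positive pool edges
  emb <- ch$truth$specs$embryo_AGM
  expect_true(all(emb$tf_detect_freq >= 0.9))
  expect_gt(sum(emb$planted_edges$sign > 0), 50)
  # null tissue: no planted endothelial edges, low freqs, Runx1 absent
  pan <- ch$truth$specs$pancreas
  expect_true(all(pan$tf_detect_freq <= 0.1))
  expect_equal(unname(pan$tf_detect_freq["Runx1"]), 0)
  expect_equal(sum(pan$planted_edges$population == "endothelial"), 0)
  # the leukocyte Fli1/Runx1 module lives in exactly one tissue
  leuk <- vapply(ch$truth$specs, function(sp)
    !is.null(sp$planted_edges) &&
      any(sp$planted_edges$population == "leukocyte"), TRUE)
  expect_equal(sum(leuk), 1)
  expect_true(leuk[["pancreas"]])
  shared_leuk <- with(pan$planted_edges,
                      intersect(target[tf == "Fli1"], target[tf == "Runx1"]))
  expect_gte(length(shared_leuk), 4)
  # Runx1 module recurs in exactly four tissues
  mod_tissues <- vapply(ch$truth$specs, function(sp)
    !is.null(sp$planted_edges) &&
      any(grepl("TgtRunx1", sp$planted_edges$target)), TRUE)
  expect_equal(sum(mod_tissues), 4)
})

test_that("truth serialization round-trips order, edges and cell states", {
  ch <- generate_cohort(default_cohort(n_endothelial = 40L, n_other = 10L,
                                       n_leukocyte = 35L), seed = 8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(ch$truth, f)
  tr <- read_truth(f)
  expect_identical(tr$true_tissue_order, ch$truth$true_tissue_order)
  expect_identical(unname(tr$tf_states), unname(ch$truth$tf_states))
  e1 <- ch$truth$specs$embryo_AGM$planted_edges
  e2 <- tr$tissues$embryo_AGM$planted_edges
  expect_equal(nrow(e2), nrow(e1))
  expect_setequal(paste(e2$tf, e2$target), paste(e1$tf, e1$target))
})

test_that("non-finite planted means are rejected", {
  tfs <- seed_panel()$seed_tfs
  spec <- tissue_spec("bad", c(endothelial = 50L),
                      setNames(rep(0.9, 11), tfs),
                      planted_edges = data.frame(
                        tf = "Erg", target = "t1", sign = 1, effect = 1e300,
                        population = "endothelial"))
  expect_error(generate_tissue(spec, seed = 1), "non-finite")
})

test_that("duplicate tissue names are rejected", {
  sp <- default_cohort()[1:2]
  sp[[2]]$name <- sp[[1]]$name
  expect_error(generate_cohort(sp, seed = 1), "duplicate")
})

test_that("indirect chains leave no conditional dependence between TF and end target", {
  # tf -> mediator -> target with no direct term: given the mediator,
  # partial distance correlation of (tf, target) should be null. Dropout is
  # disabled here: zeroing the observed mediator is measurement error on
  # the conditioning variable and genuinely re-opens the path.
  set.seed(31)
  pvals <- replicate(20, {
    seed <- sample.int(1e6, 1)
    spec <- tissue_spec("ch", c(endothelial = 300L),
                        setNames(rep(0.9, 11), seed_panel()$seed_tfs),
                        indirect_chains = data.frame(
                          tf = "Tal1", mediator = "MedX", target = "TgtX",
                          effect = 0.9, population = "endothelial"),
                        n_rare_genes = 0L, dropout_rate = 0)
    g <- generate_tissue(spec, seed = seed)
    b <- lognormalize(expression_bundle(g$counts, colnames(g$counts),
                                        g$cell_meta$cell_id, g$cell_meta))
    x <- as.numeric(b$normalized[, "Tal1"])
    y <- as.numeric(b$normalized[, "TgtX"])
    z <- as.numeric(b$normalized[, "MedX"])
    pdcor_pvalue(x, y, z, n_perm = 99, seed = seed)$p
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})
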