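test_that("detection fractions match brute-force counting and classes split at 25%", {
  b <- panel_bundle(n = 100, seed = 2, freq = 0.5)
  prof <- tf_frequency(b, seed_panel())
  mask <- as.matrix(detection_mask(b))
  for (tf in seed_panel()$seed_tfs) {
    row <- prof[prof$tf == tf, ]
    expect_equal(row$detect_fraction, mean(mask[, tf]))
    expect_identical(row$freq_class,
                     if (mean(mask[, tf]) > 0.25) "moderate" else "low")
  }
})

test_that("frequency boundary cases: 30% is moderate, 20% is low, absent TF is zero/low", {
  tfs <- seed_panel()$seed_tfs
  n <- 100
  counts <- sapply(tfs, function(tf) c(rep(1, 30), rep(0, 70)))
  counts[, "Erg"] <- c(rep(1, 20), rep(0, 80))
  counts[, "Runx1"] <- 0
  meta <- data.frame(cell_id = paste0("c", 1:n), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- lognormalize(filter_cells(
    expression_bundle(cbind(counts, pad = rep(1, n)), c(tfs, "pad"),
                      meta$cell_id, meta), 1))
  prof <- tf_frequency(b, seed_panel())
  expect_equal(prof$detect_fraction[prof$tf == "Cbfb"], 0.30)
  expect_identical(prof$freq_class[prof$tf == "Cbfb"], "moderate")
  expect_equal(prof$detect_fraction[prof$tf == "Erg"], 0.20)
  expect_identical(prof$freq_class[prof$tf == "Erg"], "low")
  expect_equal(prof$detect_fraction[prof$tf == "Runx1"], 0)
  expect_equal(prof$mean_expr_in_expressing[prof$tf == "Runx1"], 0)
  expect_identical(prof$freq_class[prof$tf == "Runx1"], "low")
})

test_that("mean expression among expressing cells follows the dot-plot convention", {
  tfs <- seed_panel()$seed_tfs
  counts <- matrix(0, 4, 12, dimnames = list(NULL, c(tfs, "pad")))
  counts[, "pad"] <- 10
  counts[1:2, "Runx1"] <- c(4, 8)
  meta <- data.frame(cell_id = paste0("c", 1:4), tissue = "t",
                     population = "endothelial", dataset = "d")
  b <- lognormalize(expression_bundle(counts, colnames(counts),
                                      meta$cell_id, meta))
  prof <- tf_frequency(b, seed_panel())
  want <- mean(b$normalized[1:2, "Runx1"])
  expect_equal(prof$mean_expr_in_expressing[prof$tf == "Runx1"], want)
})

test_that("co-expression counts are per-cell detection sums", {
  mask <- matrix(FALSE, 3, 8,
                 dimnames = list(paste0("c", 1:3),
                                 seed_panel()$coexpr_subset))
  mask[1, 1:2] <- TRUE; mask[2, 1:5] <- TRUE; mask[3, ] <- TRUE
  k <- coexpression_counts(Matrix::Matrix(mask), seed_panel()$coexpr_subset)
  expect_identical(as.integer(k), c(2L, 5L, 8L))
  expect_error(coexpression_counts(Matrix::Matrix(mask), "NotAGene"),
               "absent")
})

test_that("co-expression distribution gives exact tails and the k* summary", {
  groups <- data.frame(tissue = "t", population = "endothelial")[rep(1, 10), ]
  cd <- coexpression_distribution(rep(8L, 10), groups, K = 8)
  d <- cd$distribution
  expect_equal(d$frac_at_least_k[d$k == 8], 1.0)
  expect_equal(cd$summary$k_star, 8)
  cd2 <- coexpression_distribution(c(0L, 0L, 8L, 8L),
                                   groups[1:4, ], K = 8)
  expect_equal(cd2$distribution$frac_at_least_k[cd2$distribution$k == 8], 0.5)
  expect_equal(cd2$summary$k_star, 8)
  expect_equal(cd2$distribution$frac_at_least_k[cd2$distribution$k == 0], 1)
  # tail fractions are non-increasing in k
  expect_true(all(diff(cd2$distribution$frac_at_least_k) <= 0))
})

test_that("independent TFs at freq one-half follow the binomial co-expression law", {
  spec <- tissue_spec("iid", c(endothelial = 2000L),
                      setNames(rep(0.5, 11), seed_panel()$seed_tfs))
  g <- generate_tissue(spec, seed = 77)
  mask <- g$counts[, seed_panel()$coexpr_subset] > 0
  k <- as.integer(Matrix::rowSums(mask))
  groups <- data.frame(tissue = "iid", population = "endothelial")[rep(1, 2000), ]
  cd <- coexpression_distribution(k, groups, K = 8)
  got <- cd$distribution$frac_at_least_k[cd$distribution$k == 4]
  want <- pbinom(3, 8, 0.5, lower.tail = FALSE)  # 0.6367
  se <- sqrt(want * (1 - want) / 2000)
  expect_lt(abs(got - want), 3 * se)
  # adding a detection can only raise the tails
  k2 <- k; k2[which(k2 < 8)[1]] <- k2[which(k2 < 8)[1]] + 1L
  cd2 <- coexpression_distribution(k2, groups, K = 8)
  expect_true(all(cd2$distribution$frac_at_least_k >=
                  cd$distribution$frac_at_least_k - 1e-12))
})
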