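make_profile <- function(fracs_by_tissue) {
  do.call(rbind, lapply(names(fracs_by_tissue), function(ts)
    data.frame(tissue = ts, population = "endothelial",
               tf = seed_panel()$seed_tfs,
               detect_fraction = fracs_by_tissue[[ts]],
               mean_expr_in_expressing = 1, n_cells = 100,
               freq_class = "moderate")))
}

test_that("frequency score is the mean panel detection fraction", {
  prof <- make_profile(list(A = rep(1, 11), B = rep(0.5, 11), C = rep(0, 11)))
  p <- seed_panel()
  expect_equal(frequency_score(prof, "A", p), 1)
  expect_equal(frequency_score(prof, "B", p), 0.5)
  expect_equal(frequency_score(prof, "C", p), 0)
  # a missing TF counts as zero
  prof2 <- prof[prof$tf != "Runx1" | prof$tissue != "A", ]
  expect_equal(frequency_score(prof2, "A", p), 10 / 11)
})

test_that("co-expression score is mean k over K", {
  k <- c(rep(8L, 5), rep(0L, 5))
  groups <- data.frame(tissue = "A", population = "endothelial")[rep(1, 10), ]
  cd <- coexpression_distribution(k, groups, K = 8)
  expect_equal(coexpression_score(cd, "A", K = 8), 0.5)
  k2 <- rep(8L, 10)
  cd2 <- coexpression_distribution(k2, groups, K = 8)
  expect_equal(coexpression_score(cd2, "A", K = 8), 1)
})

test_that("max-normalization, composite and ranks behave as specified", {
  cards <- data.frame(tissue = c("A", "B", "C"),
                      freq_score = c(0.9, 0.45, 0.09),
                      coexpr_score = c(0.8, 0.4, 0.08),
                      grn_score = c(0.6, 0.3, 0.0))
  r <- rank_tissues(cards)
  expect_equal(r$rank, 1:3)
  expect_identical(r$tissue, c("A", "B", "C"))
  expect_equal(r$composite[1], 1)
  expect_equal(max(r$freq_norm), 1)
  expect_true(all(r$composite >= 0 & r$composite <= 1))
  # scale invariance: scaling one component leaves ranks unchanged
  cards2 <- cards; cards2$grn_score <- cards2$grn_score * 17
  expect_identical(rank_tissues(cards2)$tissue, r$tissue)
  expect_equal(rank_tissues(cards2)$composite, r$composite)
  # monotonicity: raising a tissue's component never lowers its rank
  cards3 <- cards; cards3$coexpr_score[2] <- 0.9
  r3 <- rank_tissues(cards3)
  expect_lte(r3$rank[r3$tissue == "B"], r$rank[r$tissue == "B"])
})

test_that("composite ties are broken deterministically and flagged", {
  cards <- data.frame(tissue = c("zeta", "alpha"),
                      freq_score = c(0.5, 0.5),
                      coexpr_score = c(0.5, 0.5),
                      grn_score = c(0.5, 0.5))
  r <- rank_tissues(cards)
  expect_true(all(r$tie))
  expect_identical(r$tissue, c("alpha", "zeta"))
  expect_identical(rank_tissues(cards)$tissue, r$tissue)
})

test_that("an all-zero component contributes zero everywhere without distorting ranks", {
  cards <- data.frame(tissue = c("A", "B"),
                      freq_score = c(0.8, 0.2),
                      coexpr_score = c(0.7, 0.1),
                      grn_score = c(0, 0))
  r <- rank_tissues(cards)
  expect_equal(r$grn_norm, c(0, 0))
  expect_identical(r$tissue, c("A", "B"))
})

test_that("grn score combines positive-regulation and clique evidence", {
  p <- seed_panel()
  edges <- data.frame(tf = c("Runx1", "Fli1", "Erg"),
                      target = c("t1", "t2", "t3"),
                      dcor = 0.5, p = 0.001, p_adj = 0.01,
                      pruned_by = NA_character_,
                      sign = c("positive", "positive", "negative"))
  grn <- structure(list(tissue = "A", population = "endothelial",
                        n_cells = 100, edges = edges), class = "grn_result")
  ov <- structure(list(clique_tfs = c("Runx1", "Fli1")),
                  class = "overlap_matrix")
  act <- data.frame(tf = c("Runx1", "Fli1"), frac_assigned_endo = c(0.2, 0.1))
  # Erg is negative-only; Runx1 and Fli1 positive and expressed
  expect_equal(grn_score(grn, act, ov, p), 0.5 * 2 / 11 + 0.5 * 2 / 11)
  # empty network scores zero
  grn0 <- structure(list(edges = edges[0, ]), class = "grn_result")
  expect_equal(grn_score(grn0, act, ov, p), 0)
  # unexpressed target sets do not count
  act0 <- data.frame(tf = c("Runx1", "Fli1"), frac_assigned_endo = c(0, 0))
  expect_equal(grn_score(grn, act0, ov, p), 0.5 * 0 + 0.5 * 2 / 11)
})
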