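test_that("rankings are permutations, ordered by expression, reproducible", {
  b <- panel_bundle(n = 30)
  rk <- build_rankings(b, seed = 3)
  expect_true(all(apply(rk, 1, function(r)
    identical(sort(unname(r)), 1:ncol(rk)))))
  # strictly decreasing values get ranks 1..k ahead of everything tied at 0
  v <- b$normalized[1, ]
  expr <- which(v > 0)
  expect_true(all(rk[1, expr] <= length(expr) |
                  duplicated(v[expr]) | duplicated(v[expr], fromLast = TRUE)))
  expect_identical(rk, build_rankings(b, seed = 3))
  rk2 <- build_rankings(b, seed = 4)
  expect_false(identical(rk, rk2))  # tie-break shuffles differ
})

test_that("recovery-curve AUC matches exhaustive enumeration across configurations", {
  set.seed(10)
  for (n_genes in c(8, 12, 20)) {
    for (s in 1:5) {
      for (rep in 1:20) {
        L <- sample(2:min(10, n_genes - 1), 1)
        top_fraction <- L / n_genes + 1e-9
        ranks <- sample(n_genes)
        rk <- matrix(ranks, nrow = 1,
                     dimnames = list("c1", paste0("g", 1:n_genes)))
        set <- paste0("g", sample(n_genes, s))
        got <- auc_score(rk, set, top_fraction)
        want <- oracle_auc(ranks[match(set, colnames(rk))], n_genes, L)
        expect_equal(as.numeric(got), want, tolerance = 1e-12)
      }
    }
  }
})

test_that("AUC is 1 for a set filling the top ranks and 0 outside the window", {
  rk <- matrix(1:20, nrow = 1, dimnames = list("c", paste0("g", 1:20)))
  expect_equal(as.numeric(auc_score(rk, paste0("g", 1:3), 0.5)), 1.0)
  expect_equal(as.numeric(auc_score(rk, paste0("g", 15:20), 0.5)), 0.0)
  expect_error(auc_score(rk, c("absent1", "absent2"), 0.5), "no genes")
})

test_that("AUC depends on ranks only (monotone-transform invariant)", {
  b <- panel_bundle(n = 25)
  rk1 <- build_rankings(b, seed = 9)
  b2 <- b
  b2$normalized@x <- b2$normalized@x^3  # strictly monotone
  rk2 <- build_rankings(b2, seed = 9)
  set <- seed_panel()$seed_tfs[1:4]
  expect_equal(auc_score(rk1, set, 0.3), auc_score(rk2, set, 0.3))
})

test_that("Holm stepwise rule reproduces the worked example and the reference implementation", {
  r <- holm_adjust(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_identical(r$significant, c(TRUE, FALSE, FALSE))
  r2 <- holm_adjust(c(0.001, 0.002, 0.003), alpha = 0.05)
  expect_identical(r2$significant, rep(TRUE, 3))
  set.seed(8)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- holm_adjust(p, 0.05)
    expect_equal(got$p_adj, p.adjust(p, method = "holm"), tolerance = 1e-12)
    # flags from adjusted p must agree with the stepwise flags
    expect_identical(got$significant, got$p_adj < 0.05)
  }
})

test_that("Holm flags are invariant to input order", {
  set.seed(2)
  p <- runif(12)^2
  o <- sample(12)
  a <- holm_adjust(p, 0.05)
  b <- holm_adjust(p[o], 0.05)
  expect_identical(a$significant[o], b$significant)
  expect_equal(a$p_adj[o], b$p_adj)
})

test_that("per-cell Kruskal-Wallis agrees with a rank-sum oracle and detects extreme sets", {
  set.seed(14)
  n_genes <- 120
  rk <- matrix(sample(n_genes), nrow = 1,
               dimnames = list("c1", paste0("g", 1:n_genes)))
  set <- paste0("g", sample(n_genes, 10))
  kw <- kw_significance(rk, set, alpha = 0.05)
  p_oracle <- oracle_ranksum_p(rk[1, set], n_genes)
  # chi-square(1) KW and two-sided normal rank-sum are asymptotically equal
  expect_equal(kw$p, p_oracle, tolerance = 1e-8)
  # a large set occupying the very top ranks -> overwhelming significance
  N <- 1000
  rk_top <- matrix(c(1:50, sample(51:N)), nrow = 1,
                   dimnames = list("c1", c(paste0("s", 1:50),
                                           paste0("g", 1:(N - 50)))))
  expect_lt(kw_significance(rk_top, paste0("s", 1:50), 0.05)$p, 1e-10)
})

test_that("threshold exploration separates a bimodal AUC mixture and falls back when unimodal", {
  set.seed(5)
  auc <- c(rnorm(100, 0.05, 0.02), rnorm(100, 0.8, 0.02))
  r <- explore_threshold(pmin(pmax(auc, 0), 1))
  expect_true(r$bimodal)
  expect_gt(r$threshold, 0.1)
  expect_lt(r$threshold, 0.7)
  flat <- rep(0, 100) + abs(rnorm(100, 0, 1e-4))
  r2 <- explore_threshold(flat)
  expect_false(r2$bimodal)
  r3 <- explore_threshold(pmin(pmax(auc, 0), 1))
  expect_equal(r$threshold, r3$threshold)  # deterministic fit
})

test_that("cell assignment is the strict intersection of AUC and significance", {
  auc <- setNames(c(0.9, 0.9, 0.1, 0.5), paste0("c", 1:4))
  p_adj <- c(0.001, 0.5, 0.001, 0.001)
  got <- assign_cells(auc, threshold = 0.4, p_adj = p_adj, alpha = 0.05)
  expect_identical(got, c("c1", "c4"))
})
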