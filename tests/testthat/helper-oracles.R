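# Independent brute-force oracles, kept deliberately naive: explicit loops
# and elementwise centering, no shared code with the package internals.

oracle_dcor <- function(x, y) {
  n <- length(x)
  ctr <- function(v) {
    M <- abs(outer(v, v, "-"))
    A <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      A[i, j] <- M[i, j] - mean(M[i, ]) - mean(M[, j]) + mean(M)
    A
  }
  A <- ctr(x); B <- ctr(y)
  dcov2 <- sum(A * B) / n^2
  vx <- sum(A * A) / n^2
  vy <- sum(B * B) / n^2
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(vx * vy))
}

oracle_ucenter <- function(v) {
  n <- length(v)
  M <- abs(outer(v, v, "-"))
  A <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j)
      A[i, j] <- M[i, j] - sum(M[i, ]) / (n - 2) - sum(M[, j]) / (n - 2) +
        sum(M) / ((n - 1) * (n - 2))
  }
  A
}

oracle_pdcor <- function(x, y, z) {
  n <- length(x)
  ip <- function(A, B) sum(A * B) / (n * (n - 3))
  Ax <- oracle_ucenter(x); Ay <- oracle_ucenter(y); Az <- oracle_ucenter(z)
  Rxy <- ip(Ax, Ay) / sqrt(ip(Ax, Ax) * ip(Ay, Ay))
  Rxz <- ip(Ax, Az) / sqrt(ip(Ax, Ax) * ip(Az, Az))
  Rzy <- ip(Az, Ay) / sqrt(ip(Az, Az) * ip(Ay, Ay))
  (Rxy - Rxz * Rzy) / sqrt((1 - Rxz^2) * (1 - Rzy^2))
}

# step-by-step recovery curve: walk ranks 1..L, count cumulative hits,
# normalize by the best possible curve
oracle_auc <- function(ranks_of_set, n_genes, L) {
  hits <- 0; area <- 0
  for (r in 1:L) {
    hits <- hits + sum(ranks_of_set == r)
    area <- area + hits
  }
  best <- 0; bh <- 0
  s <- length(ranks_of_set)
  for (r in 1:L) {
    bh <- min(r, s)
    best <- best + bh
  }
  area / best
}

# two-group rank-sum p-value (normal approximation, no ties expected)
oracle_ranksum_p <- function(set_ranks, all_n) {
  n1 <- length(set_ranks); n2 <- all_n - n1
  W <- sum(set_ranks) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig <- sqrt(n1 * n2 * (all_n + 1) / 12)
  2 * pnorm(-abs((W - mu) / sig))
}
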