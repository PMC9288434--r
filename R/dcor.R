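#' Sample distance correlation
#'
#' Distance correlation (dCor) between two univariate samples, computed from
#' double-centered pairwise absolute-difference matrices (the V-statistic
#' form): dCor = dCov / sqrt(dVar_x * dVar_y). dCor lies in \[0, 1\] and is 0
#' in the population exactly under independence, which makes it the workhorse
#' dependence measure for seed-TF network inference: it picks up monotone and
#' non-monotone regulation alike, at the price of an O(n^2) computation.
#'
#' If either input is constant its distance variance is 0 and the statistic
#' is undefined; the function then returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), finite values.
#' @return A number in \[0, 1\]; attribute `degenerate` flags a constant
#'   input.
#' @examples
#' distance_correlation(1:10, (1:10)^2)
#' @export
distance_correlation <- function(x, y) {
  check_dcor_input(x, y)
  res <- cpp_dcor(as.numeric(x), as.numeric(y))
  out <- res$dcor
  attr(out, "degenerate") <- res$degenerate
  out
}

#' Permutation p-value for distance correlation
#'
#' One-sided permutation test of independence: y is permuted `n_perm` times
#' and p = (1 + #\{permuted dCov^2 >= observed\}) / (n_perm + 1). dCov^2 is
#' used as the test statistic because it is a monotone function of dCor when
#' marginals are fixed, as they are under permutation.
#'
#' `early_stop_k` enables Besag-Clifford sequential stopping: once that many
#' exceedances have been seen the true p-value is already known to be large
#' and sampling stops, with p estimated from the permutations actually drawn.
#' The default (0) runs all `n_perm` permutations, giving the exact
#' (1 + k)/(n_perm + 1) form.
#'
#' @param x,y Numeric vectors, equal length.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; the test is deterministic given it.
#' @param early_stop_k Stop after this many exceedances (0 = never).
#' @return List with `dcor`, `p`, `n_perm_used`, `degenerate`.
#' @export
dcor_pvalue <- function(x, y, n_perm = 999, seed = 1L, early_stop_k = 0L) {
  check_dcor_input(x, y)
  stopifnot(n_perm >= 99)
  perms <- make_perms(length(x), n_perm, seed)
  res <- cpp_dcor_perm(as.numeric(x), as.numeric(y), perms,
                       as.integer(early_stop_k))
  if (res$degenerate) res$p <- 1.0
  res
}

#' Partial distance correlation
#'
#' Bias-corrected sample partial distance correlation of `x` and `y` removing
#' `z` (Szekely-Rizzo): U-centered distance matrices are treated as elements
#' of a Hilbert space, `z`'s component is projected out of both `x`'s and
#' `y`'s matrices, and the cosine of the residuals is returned. Unlike plain
#' dCor it can be negative. It is the instrument used to flag indirect
#' TF -> mediator -> target relationships: when conditioning on a co-seed TF
#' collapses the x-y dependence, the direct edge is suspect.
#'
#' A constant (degenerate) `z` carries no information to remove; the function
#' then falls back to the bias-corrected dCor of `x` and `y` with a warning.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 4 for the U-statistic).
#' @return A number in \[-1, 1\].
#' @export
partial_distance_correlation <- function(x, y, z) {
  check_dcor_input(x, y)
  stopifnot(length(z) == length(x), all(is.finite(z)))
  res <- cpp_pdcor(as.numeric(x), as.numeric(y), as.numeric(z))
  if (res$degenerate_z) {
    warning("degenerate conditioning variable; returning unconditional ",
            "bias-corrected dCor")
    return(res$Rxy)
  }
  res$pdcor
}

#' Permutation p-value for partial distance correlation
#'
#' Tests the null "x independent of y given z", one-sided against positive
#' residual dependence. Permuting `y` freely would test full independence
#' and is miscalibrated whenever y genuinely depends on z, so the
#' permutations are stratified: cells are binned by quantiles of `z` and
#' `y` is shuffled within bins, which approximately preserves the y-z
#' relationship under the conditional null.
#'
#' @inheritParams dcor_pvalue
#' @param z Conditioning vector.
#' @param n_bins Number of z-quantile strata for the permutations.
#' @return List with `pdcor`, `p`, `n_perm_used`, `degenerate`.
#' @export
pdcor_pvalue <- function(x, y, z, n_perm = 199, seed = 1L,
                         early_stop_k = 0L, n_bins = 10L) {
  check_dcor_input(x, y)
  stopifnot(length(z) == length(x), n_perm >= 99)
  perms <- make_stratified_perms(z, n_perm, seed, n_bins)
  cpp_pdcor_perm(as.numeric(x), as.numeric(y), as.numeric(z), perms,
                 as.integer(early_stop_k))
}

check_dcor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  invisible(TRUE)
}

# n x n_perm matrix of permutations of 1..n, deterministic given seed
make_perms <- function(n, n_perm, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(replicate(n_perm, sample.int(n)), nrow = n)
}

# permutations that shuffle indices only within quantile strata of z
make_stratified_perms <- function(z, n_perm, seed, n_bins = 10L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(z)
  n_bins <- max(1L, min(as.integer(n_bins), n %/% 4L))
  bins <- ceiling(rank(z, ties.method = "first") * n_bins / n)
  members <- split(seq_len(n), bins)
  out <- matrix(0L, n, n_perm)
  for (c in seq_len(n_perm)) {
    idx <- seq_len(n)
    for (m in members) if (length(m) > 1) idx[m] <- m[sample.int(length(m))]
    out[, c] <- idx
  }
  out
}
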