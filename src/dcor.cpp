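// Distance-correlation kernels.
//
// Sample (V-statistic) distance covariance/correlation via double-centered
// pairwise |x_i - x_j| matrices, and bias-corrected (U-centered) inner
// products for partial distance correlation. Permutation tests reuse the
// centered matrices: centering commutes with a simultaneous row/column
// permutation, so each permuted statistic is a single O(n^2) inner product.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <R_ext/BLAS.h>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// pairwise absolute-difference distance matrix, double-centered in place:
// A_ij = d_ij - rowmean_i - colmean_j + grandmean
static void dcenter(const NumericVector& x, std::vector<double>& A, int n) {
  std::vector<double> rm(n, 0.0);
  double gm = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = std::fabs(x[i] - x[j]);
      A[(size_t)i * n + j] = d;
      rm[i] += d;
    }
  }
  for (int i = 0; i < n; ++i) { rm[i] /= n; gm += rm[i]; }
  gm /= n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A[(size_t)i * n + j] += gm - rm[i] - rm[j];
}

// U-centered matrix (Szekely & Rizzo bias-corrected form):
// for i != j: A_ij = d_ij - d_i./(n-2) - d_.j/(n-2) + d_../((n-1)(n-2));
// diagonal is 0.
static void ucenter(const NumericVector& x, std::vector<double>& A, int n) {
  std::vector<double> rs(n, 0.0);
  double ts = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = std::fabs(x[i] - x[j]);
      A[(size_t)i * n + j] = d;
      rs[i] += d;
    }
    ts += rs[i];
  }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) {
        A[(size_t)i * n + j] = 0.0;
      } else {
        A[(size_t)i * n + j] += ts / ((double)(n - 1) * (n - 2))
          - rs[i] / (n - 2) - rs[j] / (n - 2);
      }
    }
  }
}

static double vinner(const std::vector<double>& A, const std::vector<double>& B,
                     int n) {
  double s = 0.0;
  size_t nn = (size_t)n * n;
  for (size_t k = 0; k < nn; ++k) s += A[k] * B[k];
  return s / ((double)n * n);
}

// U-centered inner product <A,B> = sum_{i!=j} A_ij B_ij / (n(n-3))
static double uinner(const std::vector<double>& A, const std::vector<double>& B,
                     int n) {
  double s = 0.0;
  size_t nn = (size_t)n * n;
  for (size_t k = 0; k < nn; ++k) s += A[k] * B[k];  // diagonals are zero
  return s / ((double)n * (n - 3));
}

// inner product of A with B permuted simultaneously in rows and columns
static double vinner_perm(const std::vector<double>& A,
                          const std::vector<double>& B,
                          const int* p, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* Ai = &A[(size_t)i * n];
    const double* Bp = &B[(size_t)p[i] * n];
    for (int j = 0; j < n; ++j) s += Ai[j] * Bp[p[j]];
  }
  return s / ((double)n * n);
}

static double uinner_perm(const std::vector<double>& A,
                          const std::vector<double>& B,
                          const int* p, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* Ai = &A[(size_t)i * n];
    const double* Bp = &B[(size_t)p[i] * n];
    for (int j = 0; j < n; ++j) s += Ai[j] * Bp[p[j]];
  }
  return s / ((double)n * (n - 3));
}

// [[Rcpp::export]]
List cpp_dcor(NumericVector x, NumericVector y) {
  int n = x.size();
  std::vector<double> A((size_t)n * n), B((size_t)n * n);
  dcenter(x, A, n);
  dcenter(y, B, n);
  double dcov2 = vinner(A, B, n);
  double vx = vinner(A, A, n);
  double vy = vinner(B, B, n);
  double dcor = 0.0;
  bool degenerate = (vx <= 0.0 || vy <= 0.0);
  if (!degenerate) {
    double r2 = dcov2 / std::sqrt(vx * vy);
    dcor = r2 > 0.0 ? std::sqrt(r2) : 0.0;
    if (dcor > 1.0) dcor = 1.0;  // guard numerical overshoot
  }
  return List::create(_["dcor"] = dcor, _["dcov2"] = dcov2,
                      _["dvarx"] = vx, _["dvary"] = vy,
                      _["degenerate"] = degenerate);
}

// Permutation test on dCov^2 (monotone in dCor for fixed marginals).
// perms: n x n_perm matrix of 1-based permutations. early_k > 0 enables
// Besag-Clifford sequential stopping after early_k exceedances.
// [[Rcpp::export]]
List cpp_dcor_perm(NumericVector x, NumericVector y, IntegerMatrix perms,
                   int early_k) {
  int n = x.size();
  int n_perm = perms.ncol();
  std::vector<double> A((size_t)n * n), B((size_t)n * n);
  dcenter(x, A, n);
  dcenter(y, B, n);
  double dcov2 = vinner(A, B, n);
  double vx = vinner(A, A, n);
  double vy = vinner(B, B, n);
  bool degenerate = (vx <= 0.0 || vy <= 0.0);
  double dcor = 0.0;
  if (!degenerate) {
    double r2 = dcov2 / std::sqrt(vx * vy);
    dcor = r2 > 0.0 ? std::sqrt(r2) : 0.0;
    if (dcor > 1.0) dcor = 1.0;
  }
  int exceed = 0, used = 0;
  std::vector<int> p(n);
  if (!degenerate) {
    for (int c = 0; c < n_perm; ++c) {
      for (int i = 0; i < n; ++i) p[i] = perms(i, c) - 1;
      double s = vinner_perm(A, B, p.data(), n);
      if (s >= dcov2 - 1e-14) ++exceed;
      ++used;
      if (early_k > 0 && exceed >= early_k) break;
    }
  }
  double pval = degenerate ? 1.0 : (1.0 + exceed) / (1.0 + used);
  return List::create(_["dcor"] = dcor, _["p"] = pval, _["exceed"] = exceed,
                      _["n_perm_used"] = used, _["degenerate"] = degenerate);
}

static double pdcor_from_R(double Rxy, double Rxz, double Rzy) {
  double den = (1.0 - Rxz * Rxz) * (1.0 - Rzy * Rzy);
  if (den <= 0.0) return 0.0;
  return (Rxy - Rxz * Rzy) / std::sqrt(den);
}

// Bias-corrected distance correlation R* of x,y and partial distance
// correlation of x,y removing z, via U-centered projections.
// [[Rcpp::export]]
List cpp_pdcor(NumericVector x, NumericVector y, NumericVector z) {
  int n = x.size();
  std::vector<double> Ax((size_t)n * n), Ay((size_t)n * n), Az((size_t)n * n);
  ucenter(x, Ax, n);
  ucenter(y, Ay, n);
  ucenter(z, Az, n);
  double vxx = uinner(Ax, Ax, n), vyy = uinner(Ay, Ay, n),
         vzz = uinner(Az, Az, n);
  bool degx = vxx <= 0.0, degy = vyy <= 0.0, degz = vzz <= 0.0;
  double Rxy = 0.0, Rxz = 0.0, Rzy = 0.0;
  if (!degx && !degy) Rxy = uinner(Ax, Ay, n) / std::sqrt(vxx * vyy);
  if (!degx && !degz) Rxz = uinner(Ax, Az, n) / std::sqrt(vxx * vzz);
  if (!degz && !degy) Rzy = uinner(Az, Ay, n) / std::sqrt(vzz * vyy);
  double pd = pdcor_from_R(Rxy, Rxz, Rzy);
  return List::create(_["pdcor"] = pd, _["Rxy"] = Rxy, _["Rxz"] = Rxz,
                      _["Rzy"] = Rzy,
                      _["degenerate_z"] = degz,
                      _["degenerate"] = (degx || degy));
}

// Permutation test for pdcor: y is permuted (rows+columns of its U-centered
// matrix); Rxz is fixed, Rxy and Rzy recomputed per permutation.
// [[Rcpp::export]]
List cpp_pdcor_perm(NumericVector x, NumericVector y, NumericVector z,
                    IntegerMatrix perms, int early_k) {
  int n = x.size();
  int n_perm = perms.ncol();
  std::vector<double> Ax((size_t)n * n), Ay((size_t)n * n), Az((size_t)n * n);
  ucenter(x, Ax, n);
  ucenter(y, Ay, n);
  ucenter(z, Az, n);
  double vxx = uinner(Ax, Ax, n), vyy = uinner(Ay, Ay, n),
         vzz = uinner(Az, Az, n);
  if (vxx <= 0.0 || vyy <= 0.0 || vzz <= 0.0) {
    return List::create(_["pdcor"] = 0.0, _["p"] = 1.0, _["exceed"] = 0,
                        _["n_perm_used"] = 0, _["degenerate"] = true);
  }
  double sxy = std::sqrt(vxx * vyy), szy = std::sqrt(vzz * vyy);
  double Rxz = uinner(Ax, Az, n) / std::sqrt(vxx * vzz);
  double Rxy = uinner(Ax, Ay, n) / sxy;
  double Rzy = uinner(Az, Ay, n) / szy;
  double obs = pdcor_from_R(Rxy, Rxz, Rzy);
  int exceed = 0, used = 0;
  std::vector<int> p(n);
  for (int c = 0; c < n_perm; ++c) {
    for (int i = 0; i < n; ++i) p[i] = perms(i, c) - 1;
    double Rxy_p = uinner_perm(Ax, Ay, p.data(), n) / sxy;
    double Rzy_p = uinner_perm(Az, Ay, p.data(), n) / szy;
    double s = pdcor_from_R(Rxy_p, Rxz, Rzy_p);
    if (s >= obs - 1e-14) ++exceed;
    ++used;
    if (early_k > 0 && exceed >= early_k) break;
  }
  double pval = (1.0 + exceed) / (1.0 + used);
  return List::create(_["pdcor"] = obs, _["p"] = pval, _["exceed"] = exceed,
                      _["n_perm_used"] = used, _["degenerate"] = false);
}

// Family-batched permutation test: one seed TF against k candidate targets,
// sharing each permutation's gathered matrix across candidates. Candidates
// reaching early_k exceedances stop accumulating (Besag-Clifford).
// [[Rcpp::export]]
List cpp_dcor_perm_family(NumericVector x, NumericMatrix Y,
                          IntegerMatrix perms, int early_k) {
  int n = x.size();
  int k = Y.ncol();
  int n_perm = perms.ncol();
  std::vector<double> A((size_t)n * n);
  dcenter(x, A, n);
  double vx = vinner(A, A, n);
  std::vector<std::vector<double>> B(k);
  std::vector<double> dcov2(k), vy(k), dc(k);
  std::vector<bool> degenerate(k);
  for (int j = 0; j < k; ++j) {
    B[j].resize((size_t)n * n);
    NumericVector yj = Y(_, j);
    dcenter(yj, B[j], n);
    dcov2[j] = vinner(A, B[j], n);
    vy[j] = vinner(B[j], B[j], n);
    degenerate[j] = (vx <= 0.0 || vy[j] <= 0.0);
    dc[j] = 0.0;
    if (!degenerate[j]) {
      double r2 = dcov2[j] / std::sqrt(vx * vy[j]);
      dc[j] = r2 > 0.0 ? std::sqrt(r2) : 0.0;
      if (dc[j] > 1.0) dc[j] = 1.0;
    }
  }
  std::vector<int> exceed(k, 0), used(k, 0);
  std::vector<bool> active(k);
  int n_active = 0;
  for (int j = 0; j < k; ++j) {
    active[j] = !degenerate[j];
    if (active[j]) ++n_active;
  }
  std::vector<double> Ap((size_t)n * n);
  std::vector<int> p(n), q(n);
  size_t nn = (size_t)n * n;
  // stacked matrix of the currently active candidates' centered matrices
  // (nn x n_active, column-major) so each permutation is one BLAS dgemv;
  // compacted whenever a candidate stops
  std::vector<int> act_idx;
  for (int j = 0; j < k; ++j) if (active[j]) act_idx.push_back(j);
  std::vector<double> Bst(nn * act_idx.size());
  std::vector<double> stats(k);
  for (size_t a = 0; a < act_idx.size(); ++a)
    std::copy(B[act_idx[a]].begin(), B[act_idx[a]].end(),
              Bst.begin() + a * nn);
  int inn = (int)nn;
  double one = 1.0, zero = 0.0;
  int ione = 1;
  for (int c = 0; c < n_perm && n_active > 0; ++c) {
    for (int i = 0; i < n; ++i) p[i] = perms(i, c) - 1;
    // gather A by the inverse permutation so that <Ap, B> equals the
    // pairwise statistic <A, B[p,p]> of the per-pair kernel exactly
    for (int i = 0; i < n; ++i) q[p[i]] = i;
    for (int i = 0; i < n; ++i) {
      const double* Ar = &A[(size_t)q[i] * n];
      double* Apr = &Ap[(size_t)i * n];
      for (int j2 = 0; j2 < n; ++j2) Apr[j2] = Ar[q[j2]];
    }
    int ka = (int)act_idx.size();
    F77_CALL(dgemv)("T", &inn, &ka, &one, Bst.data(), &inn, Ap.data(),
                    &ione, &zero, stats.data(), &ione FCONE);
    bool removed = false;
    for (int a = 0; a < ka; ++a) {
      int j = act_idx[a];
      double s = stats[a] / ((double)n * n);
      if (s >= dcov2[j] - 1e-14) ++exceed[j];
      ++used[j];
      if (early_k > 0 && exceed[j] >= early_k) {
        active[j] = false;
        --n_active;
        removed = true;
      }
    }
    if (removed && n_active > 0) {
      std::vector<int> keep;
      for (int j2 : act_idx) if (active[j2]) keep.push_back(j2);
      for (size_t a = 0; a < keep.size(); ++a)
        std::copy(B[keep[a]].begin(), B[keep[a]].end(), Bst.begin() + a * nn);
      act_idx = keep;
    }
  }
  NumericVector pval(k), dcor_out(k);
  IntegerVector used_out(k), exceed_out(k);
  LogicalVector deg_out(k);
  for (int j = 0; j < k; ++j) {
    pval[j] = degenerate[j] ? 1.0 : (1.0 + exceed[j]) / (1.0 + used[j]);
    dcor_out[j] = dc[j];
    used_out[j] = used[j];
    exceed_out[j] = exceed[j];
    deg_out[j] = degenerate[j];
  }
  return List::create(_["dcor"] = dcor_out, _["p"] = pval,
                      _["exceed"] = exceed_out, _["n_perm_used"] = used_out,
                      _["degenerate"] = deg_out);
}

// Batched conditional pruning statistics for one target: partial distance
// correlation pdcor(a, y; b) and its permutation p-value for every ordered
// pair (a, b) of the k TFs in X, permuting y once per draw and reusing the
// k inner products across all pairs.
// [[Rcpp::export]]
List cpp_pdcor_prune_family(NumericVector y, NumericMatrix X,
                            IntegerMatrix perms, int early_k) {
  int n = y.size();
  int k = X.ncol();
  int n_perm = perms.ncol();
  std::vector<double> Uy((size_t)n * n);
  ucenter(y, Uy, n);
  double vyy = uinner(Uy, Uy, n);
  std::vector<std::vector<double>> Ux(k);
  std::vector<double> vxx(k);
  for (int a = 0; a < k; ++a) {
    Ux[a].resize((size_t)n * n);
    NumericVector xa = X(_, a);
    ucenter(xa, Ux[a], n);
    vxx[a] = uinner(Ux[a], Ux[a], n);
  }
  bool deg_y = vyy <= 0.0;
  NumericMatrix obs(k, k), pval(k, k);
  std::fill(pval.begin(), pval.end(), 1.0);
  if (deg_y) {
    return List::create(_["pdcor"] = obs, _["p"] = pval,
                        _["degenerate"] = true);
  }
  std::vector<double> Ray(k);
  std::vector<std::vector<double>> Rab(k, std::vector<double>(k, 0.0));
  for (int a = 0; a < k; ++a) {
    Ray[a] = vxx[a] > 0.0 ?
      uinner(Ux[a], Uy, n) / std::sqrt(vxx[a] * vyy) : 0.0;
    for (int b = 0; b < a; ++b) {
      double r = (vxx[a] > 0.0 && vxx[b] > 0.0) ?
        uinner(Ux[a], Ux[b], n) / std::sqrt(vxx[a] * vxx[b]) : 0.0;
      Rab[a][b] = Rab[b][a] = r;
    }
  }
  std::vector<std::vector<int>> exceed(k, std::vector<int>(k, 0)),
      used(k, std::vector<int>(k, 0));
  std::vector<std::vector<bool>> active(k, std::vector<bool>(k, false));
  int n_active = 0;
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      if (a == b || vxx[a] <= 0.0 || vxx[b] <= 0.0) continue;
      obs(a, b) = pdcor_from_R(Ray[a], Rab[a][b], Ray[b]);
      active[a][b] = true;
      ++n_active;
    }
  }
  std::vector<double> Uyp((size_t)n * n), say(k);
  std::vector<int> p(n);
  size_t nn = (size_t)n * n;
  for (int c = 0; c < n_perm && n_active > 0; ++c) {
    for (int i = 0; i < n; ++i) p[i] = perms(i, c) - 1;
    for (int i = 0; i < n; ++i) {
      const double* Ur = &Uy[(size_t)p[i] * n];
      double* Upr = &Uyp[(size_t)i * n];
      for (int j2 = 0; j2 < n; ++j2) Upr[j2] = Ur[p[j2]];
    }
    for (int a = 0; a < k; ++a) {
      if (vxx[a] <= 0.0) { say[a] = 0.0; continue; }
      const double* Ua = Ux[a].data();
      double s = 0.0;
      for (size_t q = 0; q < nn; ++q) s += Ua[q] * Uyp[q];
      say[a] = s / ((double)n * (n - 3)) / std::sqrt(vxx[a] * vyy);
    }
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < k; ++b) {
        if (!active[a][b]) continue;
        double s = pdcor_from_R(say[a], Rab[a][b], say[b]);
        if (s >= obs(a, b) - 1e-14) ++exceed[a][b];
        ++used[a][b];
        if (early_k > 0 && exceed[a][b] >= early_k) {
          active[a][b] = false;
          --n_active;
        }
      }
    }
  }
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      if (a != b && used[a][b] > 0)
        pval(a, b) = (1.0 + exceed[a][b]) / (1.0 + used[a][b]);
  return List::create(_["pdcor"] = obs, _["p"] = pval,
                      _["degenerate"] = false);
}
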