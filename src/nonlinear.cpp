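// O(N^2) kernels behind the nonlinear movement-variability features.
// Kept minimal: plain pair loops, no approximate neighbour structures,
// so the R-level brute-force oracles in the test suite check the same
// arithmetic through an independent code path.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sample-entropy pair counts: templates i = 0..N-m-1 (so the m+1 template
// exists for every counted i), Chebyshev distance, self-matches excluded.
// Returns c(A, B): matches at length m+1 and at length m.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of templates of length m with an m+1 extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        B += 1.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, dd) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Phi_m for approximate entropy: mean over i of log(C_i), where C_i is the
// fraction of templates (self-match included) within Chebyshev r.
// [[Rcpp::export]]
double cpp_apen_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  std::vector<double> cnt(nt, 1.0);  // self-match
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) { cnt[i] += 1.0; cnt[j] += 1.0; }
    }
  }
  double phi = 0.0;
  for (int i = 0; i < nt; ++i) phi += std::log(cnt[i] / nt);
  return phi / nt;
}

// Correlation sums C(r) for a vector of radii on an embedded point matrix
// (rows = points). Euclidean norm, strict inequality (Heaviside H(u)=1 for
// u > 0 with u = r - distance): pairs at distance exactly r do not count.
// [[Rcpp::export]]
NumericVector cpp_corr_sum(NumericMatrix pts, NumericVector radii) {
  int n = pts.nrow(), d = pts.ncol(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int q = 0; q < nr; ++q) r2[q] = radii[q] * radii[q];
  std::vector<double> counts(nr, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = pts(i, k) - pts(j, k);
        dist2 += dd * dd;
      }
      for (int q = 0; q < nr; ++q) {
        if (dist2 < r2[q]) counts[q] += 1.0;
      }
    }
  }
  double npairs = 0.5 * (double)n * (n - 1);
  NumericVector out(nr);
  for (int q = 0; q < nr; ++q) out[q] = counts[q] / npairs;
  return out;
}

// Nearest Euclidean neighbour of each embedded point among candidates with
// temporal separation > min_sep, both indices <= max_i (1-based result;
// NA when no candidate exists).
// [[Rcpp::export]]
IntegerVector cpp_nearest_neighbor(NumericMatrix pts, int min_sep, int max_i) {
  int d = pts.ncol();
  IntegerVector out(max_i);
  for (int i = 0; i < max_i; ++i) {
    double best = R_PosInf;
    int bi = -1;
    for (int j = 0; j < max_i; ++j) {
      if (std::abs(i - j) <= min_sep) continue;
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = pts(i, k) - pts(j, k);
        dist2 += dd * dd;
      }
      if (dist2 < best) { best = dist2; bi = j; }
    }
    out[i] = (bi < 0) ? NA_INTEGER : bi + 1;
  }
  return out;
}

// Mean log-divergence curve: ldiv[k+1] = mean_i ln ||Y_{i+k} - Y_{i*+k}||
// over pairs with positive distance, for k = 0..kmax.
// [[Rcpp::export]]
NumericVector cpp_divergence_curve(NumericMatrix pts, IntegerVector nn, int kmax) {
  int d = pts.ncol();
  int npairs = nn.size();
  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < npairs; ++i) {
      if (nn[i] == NA_INTEGER) continue;
      int j = nn[i] - 1;
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double dd = pts(i + k, c) - pts(j + k, c);
        dist2 += dd * dd;
      }
      if (dist2 > 0.0) { s += 0.5 * std::log(dist2); cnt += 1; }
    }
    out[k] = (cnt > 0) ? s / cnt : NA_REAL;
  }
  return out;
}
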