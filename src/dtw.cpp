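#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic DTW: symmetric steps, squared-Euclidean local cost, no warping
// window; the returned value is the square root of the accumulated cost.

static inline double sq(double x) { return x * x; }

static double dtw_core(const double *a, int n, const double *b, int m) {
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = sq(a[i - 1] - b[j - 1]) + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// Full DP matrix + backtracked warping path (1-based indices).
static double dtw_path_core(const double *a, int n, const double *b, int m,
                            std::vector<int> &pi, std::vector<int> &pj) {
  std::vector<double> D((n + 1) * (m + 1), R_PosInf);
  D[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = D[(i - 1) * (m + 1) + (j - 1)];
      double up = D[(i - 1) * (m + 1) + j];
      double left = D[i * (m + 1) + (j - 1)];
      if (up < best) best = up;
      if (left < best) best = left;
      D[i * (m + 1) + j] = sq(a[i - 1] - b[j - 1]) + best;
    }
  }
  int i = n, j = m;
  pi.clear(); pj.clear();
  while (i > 0 && j > 0) {
    pi.push_back(i); pj.push_back(j);
    if (i == 1 && j == 1) break;
    double diag = (i > 1 && j > 1) ? D[(i - 1) * (m + 1) + (j - 1)] : R_PosInf;
    double up = (i > 1) ? D[(i - 1) * (m + 1) + j] : R_PosInf;
    double left = (j > 1) ? D[i * (m + 1) + (j - 1)] : R_PosInf;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left) { --i; }
    else { --j; }
  }
  return std::sqrt(D[n * (m + 1) + m]);
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b) {
  return dtw_core(a.begin(), a.size(), b.begin(), b.size());
}

// [[Rcpp::export]]
List dtw_path_cpp(NumericVector a, NumericVector b) {
  std::vector<int> pi, pj;
  double d = dtw_path_core(a.begin(), a.size(), b.begin(), b.size(), pi, pj);
  int L = pi.size();
  IntegerVector ii(L), jj(L);
  for (int t = 0; t < L; ++t) { // path was built backwards
    ii[t] = pi[L - 1 - t];
    jj[t] = pj[L - 1 - t];
  }
  return List::create(_["dist"] = d, _["i"] = ii, _["j"] = jj);
}

// Assign every row of X to its nearest centroid (rows of C).
// [[Rcpp::export]]
List dtw_assign_cpp(NumericMatrix X, NumericMatrix C) {
  int n = X.nrow(), k = C.nrow(), L = X.ncol(), M = C.ncol();
  IntegerVector lab(n);
  NumericVector dist(n);
  std::vector<double> row(L), cen(M);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < L; ++t) row[t] = X(i, t);
    double best = R_PosInf; int bj = 0;
    for (int c = 0; c < k; ++c) {
      for (int t = 0; t < M; ++t) cen[t] = C(c, t);
      double d = dtw_core(&row[0], L, &cen[0], M);
      if (d < best) { best = d; bj = c; }
    }
    lab[i] = bj + 1;
    dist[i] = best;
  }
  return List::create(_["label"] = lab, _["dist"] = dist);
}

// DTW barycenter averaging: iteratively align members to the current
// centroid and average the values mapped onto each centroid position.
// [[Rcpp::export]]
NumericVector dba_cpp(NumericMatrix X, NumericVector init,
                      int max_iter = 10, double tol = 1e-6) {
  int n = X.nrow(), L = init.size(), M = X.ncol();
  NumericVector cent = clone(init);
  std::vector<double> row(M);
  std::vector<int> pi, pj;
  for (int iter = 0; iter < max_iter; ++iter) {
    std::vector<double> sum(L, 0.0);
    std::vector<int> cnt(L, 0);
    for (int r = 0; r < n; ++r) {
      for (int t = 0; t < M; ++t) row[t] = X(r, t);
      dtw_path_core(cent.begin(), L, &row[0], M, pi, pj);
      for (size_t s = 0; s < pi.size(); ++s) {
        sum[pi[s] - 1] += row[pj[s] - 1];
        cnt[pi[s] - 1] += 1;
      }
    }
    double delta = 0.0;
    for (int t = 0; t < L; ++t) {
      if (cnt[t] > 0) {
        double v = sum[t] / cnt[t];
        delta = std::max(delta, std::fabs(v - cent[t]));
        cent[t] = v;
      }
    }
    if (delta < tol) break;
  }
  return cent;
}
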