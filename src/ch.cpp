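#include <Rcpp.h>
using namespace Rcpp;

// Calinski-Harabasz index: CH = [B/(k-1)] / [W/(n-k)] with
// B = sum_g n_g * ||mu_g - mu||^2 and W = sum_g sum_{i in g} ||x_i - mu_g||^2.
// `g` holds 1-based group codes, `k` the number of groups. W = 0 with B > 0
// returns +Inf (perfectly tight, separated clusters); B = 0 returns 0.
// [[Rcpp::export]]
double ch_index_cpp(const NumericMatrix& X, const IntegerVector& g, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 2) stop("need at least 2 groups");
  if (n <= k) stop("need more points than groups");

  std::vector<double> gm(k * d, 0.0), mu(d, 0.0);
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; ++i) {
    int gi = g[i] - 1;
    if (gi < 0 || gi >= k) stop("group code out of range");
    ++cnt[gi];
    for (int j = 0; j < d; ++j) {
      double x = X(i, j);
      gm[gi * d + j] += x;
      mu[j] += x;
    }
  }
  for (int c = 0; c < k; ++c) {
    if (cnt[c] == 0) stop("empty group");
    for (int j = 0; j < d; ++j) gm[c * d + j] /= cnt[c];
  }
  for (int j = 0; j < d; ++j) mu[j] /= n;

  double B = 0.0, W = 0.0;
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < d; ++j) {
      double diff = gm[c * d + j] - mu[j];
      B += cnt[c] * diff * diff;
    }
  for (int i = 0; i < n; ++i) {
    int gi = g[i] - 1;
    for (int j = 0; j < d; ++j) {
      double diff = X(i, j) - gm[gi * d + j];
      W += diff * diff;
    }
  }
  if (B == 0.0) return 0.0;
  if (W == 0.0) return R_PosInf;
  return (B / (k - 1)) / (W / (n - k));
}

// CH evaluated on a list of row-index subsets (1-based) of X, with a fixed
// group labelling per subset; hot loop of the permutative Mann-Whitney test.
// [[Rcpp::export]]
NumericVector ch_subsets_cpp(const NumericMatrix& X, const List& idx,
                             const IntegerVector& g, int k) {
  const int S = idx.size();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector rows = idx[s];
    const int m = rows.size();
    NumericMatrix sub(m, X.ncol());
    for (int i = 0; i < m; ++i) {
      int r = rows[i] - 1;
      for (int j = 0; j < X.ncol(); ++j) sub(i, j) = X(r, j);
    }
    out[s] = ch_index_cpp(sub, g, k);
  }
  return out;
}

// Topographic prominences for peaks at 1-based indices `idx` of `y`:
// walk away from each peak tracking the minimum until a strictly higher
// sample (or the signal edge); prominence = height - max(left min, right min).
// [[Rcpp::export]]
NumericVector peak_prominences_cpp(const NumericVector& y,
                                   const IntegerVector& idx) {
  const int n = y.size(), m = idx.size();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    int i = idx[p] - 1;
    double h = y[i];
    double left = h, right = h;
    if (i > 0) {
      left = R_PosInf;
      for (int j = i - 1; j >= 0 && y[j] <= h; --j)
        if (y[j] < left) left = y[j];
    }
    if (i < n - 1) {
      right = R_PosInf;
      for (int j = i + 1; j < n && y[j] <= h; ++j)
        if (y[j] < right) right = y[j];
    }
    double base = left > right ? left : right;
    out[p] = h - base;
  }
  return out;
}
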