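#include <Rcpp.h>
using namespace Rcpp;

// Separable 2-D convolution with edge replication. Used for Gaussian
// smoothing in the difference-of-Gaussians proposal stage; kept in C++
// because it sits in the inner loop of training and evaluation.
// [[Rcpp::export]]
NumericMatrix sep_convolve(const NumericMatrix& x, const NumericVector& k) {
  const int n = x.nrow(), m = x.ncol();
  const int ks = k.size(), r = (ks - 1) / 2;
  const std::vector<double> kk(k.begin(), k.end());
  NumericMatrix tmp(n, m), out(n, m);

  // vertical pass over contiguous (column-major) columns
  std::vector<double> buf(n + 2 * r);
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    for (int t = 0; t < r; ++t) buf[t] = col[0];
    std::copy(col, col + n, buf.begin() + r);
    for (int t = 0; t < r; ++t) buf[n + r + t] = col[n - 1];
    double* o = &tmp(0, j);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double* b = &buf[i];
      for (int t = 0; t < ks; ++t) s += b[t] * kk[t];
      o[i] = s;
    }
  }
  // horizontal pass through a padded row buffer
  std::vector<double> rbuf(m + 2 * r);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) rbuf[r + j] = tmp(i, j);
    for (int t = 0; t < r; ++t) {
      rbuf[t] = rbuf[r];
      rbuf[m + r + t] = rbuf[m + r - 1];
    }
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      const double* b = &rbuf[j];
      for (int t = 0; t < ks; ++t) s += b[t] * kk[t];
      out(i, j) = s;
    }
  }
  return out;
}

// 8-neighbourhood local maxima at or above `thresh`. Plateau pixels all
// qualify; the caller deduplicates overlapping candidates afterwards.
// Border pixels are excluded.
// [[Rcpp::export]]
LogicalMatrix local_maxima8(const NumericMatrix& x, double thresh) {
  const int n = x.nrow(), m = x.ncol();
  LogicalMatrix out(n, m);
  for (int j = 1; j < m - 1; ++j) {
    for (int i = 1; i < n - 1; ++i) {
      const double v = x(i, j);
      if (v < thresh) continue;
      bool ok = true;
      for (int dj = -1; dj <= 1 && ok; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          if (x(i + di, j + dj) > v) { ok = false; break; }
        }
      if (ok) out(i, j) = true;
    }
  }
  return out;
}
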