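#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012). One-dimensional lower envelope of parabolas,
// applied first along columns then along rows.

static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericMatrix edt_sq_cpp(Rcpp::LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  Rcpp::NumericMatrix out(nr, nc);

  // distance to nearest background (FALSE) pixel; background itself is 0
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? INF : 0.0;
    f.resize(nr);
    d.resize(nr);
    dt1d(f, d);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  // pass 2: rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    f.resize(nc);
    d.resize(nc);
    dt1d(f, d);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
    f.resize(std::max(nr, nc));
    d.resize(std::max(nr, nc));
  }
  return out;
}
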