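#include <Rcpp.h>
#include <vector>
#include <cmath>

// C-support-vector classifier trained by sequential minimal optimization
// with maximal-violating-pair working-set selection (the WSS1 rule of
// LIBSVM). The kernel matrix is precomputed, which bounds problem sizes to
// a few thousand rows -- the scale of the per-signal single-cell datasets
// this package assembles.

static inline double kern(const Rcpp::NumericMatrix &X, int a, int b,
                          int kernel, double gamma) {
  const int p = X.ncol();
  if (kernel == 0) { // linear
    double s = 0.0;
    for (int k = 0; k < p; k++) s += X(a, k) * X(b, k);
    return s;
  }
  double d2 = 0.0; // rbf
  for (int k = 0; k < p; k++) {
    double d = X(a, k) - X(b, k);
    d2 += d * d;
  }
  return std::exp(-gamma * d2);
}

// [[Rcpp::export]]
Rcpp::List svm_train_cpp(Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                         double C, double gamma, int kernel,
                         double eps, int max_iter) {
  const int n = X.nrow();
  if ((int)y.size() != n) Rcpp::stop("label length mismatch");
  if (n > 8000) Rcpp::stop("dataset too large for dense kernel SMO");

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; i++) {
    for (int j = i; j < n; j++) {
      double v = kern(X, i, j, kernel, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), f(n, 0.0); // f_i = sum_t alpha_t y_t K_it
  const double TAU = 1e-12;
  int iter = 0;
  double m = 0.0, M = 0.0;

  while (iter++ < max_iter) {
    // working-set selection over the violating pair
    int i = -1, j = -1;
    m = -1e30;
    M = 1e30;
    for (int t = 0; t < n; t++) {
      double g = y[t] - f[t]; // -E_t = -y_t * grad_t
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (up && g > m) { m = g; i = t; }
      if (lo && g < M) { M = g; j = t; }
    }
    if (i < 0 || j < 0 || m - M <= eps) break;

    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta < TAU) eta = TAU;
    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double aj_old = alpha[j], ai_old = alpha[i];
    double aj = aj_old + y[j] * (Ei - Ej) / eta;

    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (aj > H) aj = H;
    if (aj < L) aj = L;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);

    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    if (std::fabs(di) < TAU && std::fabs(dj) < TAU) break;
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; t++)
      f[t] += di * K[(size_t)i * n + t] + dj * K[(size_t)j * n + t];
  }

  // intercept from free support vectors, else midpoint of the KKT bounds
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; t++) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) {
      b += y[t] - f[t];
      nfree++;
    }
  }
  if (nfree > 0) b /= nfree; else b = (m + M) / 2.0;

  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iter") = iter);
}

// [[Rcpp::export]]
Rcpp::NumericVector svm_decision_cpp(Rcpp::NumericMatrix Xtr,
                                     Rcpp::IntegerVector y,
                                     Rcpp::NumericVector alpha, double b,
                                     int kernel, double gamma,
                                     Rcpp::NumericMatrix Xnew) {
  const int n = Xtr.nrow(), m = Xnew.nrow(), p = Xtr.ncol();
  if (Xnew.ncol() != p) Rcpp::stop("feature count mismatch");
  Rcpp::NumericVector out(m);
  for (int q = 0; q < m; q++) {
    double s = b;
    for (int t = 0; t < n; t++) {
      if (alpha[t] == 0.0) continue;
      double kv;
      if (kernel == 0) {
        kv = 0.0;
        for (int k = 0; k < p; k++) kv += Xtr(t, k) * Xnew(q, k);
      } else {
        double d2 = 0.0;
        for (int k = 0; k < p; k++) {
          double d = Xtr(t, k) - Xnew(q, k);
          d2 += d * d;
        }
        kv = std::exp(-gamma * d2);
      }
      s += alpha[t] * y[t] * kv;
    }
    out[q] = s;
  }
  return out;
}
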