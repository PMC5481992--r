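#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Binary C-SVC via sequential minimal optimization with most-violating-pair
// working-set selection. Deterministic: no randomness, fixed scan order.
// Solves min 0.5 a'Qa - e'a, 0 <= a <= C, y'a = 0, with Q_ij = y_i y_j K_ij.

static const double SMO_EPS = 1e-3;
static const double SMO_TAU = 1e-12;
static const int SMO_MAX_ITER = 10000;

struct SvmFit {
  std::vector<double> alpha;
  double rho;  // decision: f(x) = sum_i a_i y_i K(x_i,x) - rho
};

static void smo_solve(const std::vector<double> &K, const std::vector<int> &y,
                      int n, double C, SvmFit &fit) {
  std::vector<double> &a = fit.alpha;
  a.assign(n, 0.0);
  std::vector<double> G(n, -1.0);

  for (int iter = 0; iter < SMO_MAX_ITER; ++iter) {
    // i: argmax -y_i G_i over I_up, j: argmin -y_j G_j over I_low
    int i = -1, j = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      if ((y[t] == 1 && a[t] < C) || (y[t] == -1 && a[t] > 0)) {
        double v = -y[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
      if ((y[t] == 1 && a[t] > 0) || (y[t] == -1 && a[t] < C)) {
        double v = -y[t] * G[t];
        if (v < gmin) { gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < SMO_EPS) break;

    // curvature along the feasible direction u_i = y_i, u_j = -y_j
    double quad = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    if (quad <= 0) quad = SMO_TAU;
    double oldAi = a[i], oldAj = a[j];
    double delta = (gmax - gmin) / quad;
    a[i] += y[i] * delta;
    a[j] -= y[j] * delta;
    // re-project onto the box keeping y_i a_i + y_j a_j fixed
    double s = y[i] * oldAi + y[j] * oldAj;
    if (a[i] > C) a[i] = C;
    if (a[i] < 0) a[i] = 0;
    a[j] = y[j] * (s - y[i] * a[i]);
    if (a[j] > C) a[j] = C;
    if (a[j] < 0) a[j] = 0;
    a[i] = y[i] * (s - y[j] * a[j]);

    double dI = a[i] - oldAi, dJ = a[j] - oldAj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[t * n + i] * dI + y[j] * K[t * n + j] * dJ);
  }

  // rho from free support vectors, else midpoint of the KKT bounds
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (a[t] >= C - SMO_TAU) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (a[t] <= SMO_TAU) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum += yG; ++nfree;
    }
  }
  fit.rho = nfree > 0 ? sum / nfree : (ub + lb) / 2.0;
}

static inline double kern(const double *xi, const double *xj, int p,
                          int kernel, double gamma) {
  if (kernel == 0) {
    double s = 0;
    for (int d = 0; d < p; ++d) s += xi[d] * xj[d];
    return s;
  }
  double s = 0;
  for (int d = 0; d < p; ++d) { double u = xi[d] - xj[d]; s += u * u; }
  return std::exp(-gamma * s);
}

// Fit on rows `tr` of Z (row-major n x p), predict rows `te`; returns
// number of correct predictions. y in {-1,+1}; first class level maps to +1
// upstream, and prediction ties (f == 0) resolve to +1.
static int fit_predict(const std::vector<double> &Z, int p,
                       const std::vector<int> &tr, const std::vector<int> &te,
                       const std::vector<int> &ylab, double C, int kernel,
                       double gamma) {
  int n = (int)tr.size();
  std::vector<int> y(n);
  int npos = 0;
  for (int t = 0; t < n; ++t) {
    y[t] = ylab[tr[t]];
    if (y[t] == 1) ++npos;
  }

  bool degenerate = true;
  for (int t = 1; t < n && degenerate; ++t)
    for (int d = 0; d < p; ++d)
      if (Z[tr[t] * p + d] != Z[tr[0] * p + d]) { degenerate = false; break; }
  bool oneclass = (npos == 0 || npos == n);

  int correct = 0;
  if (degenerate || oneclass) {
    int maj = (2 * npos >= n) ? 1 : -1;  // tie -> first class level
    for (size_t t = 0; t < te.size(); ++t)
      if (ylab[te[t]] == maj) ++correct;
    return correct;
  }

  std::vector<double> K((size_t)n * n);
  for (int u = 0; u < n; ++u)
    for (int v = u; v < n; ++v) {
      double k = kern(&Z[tr[u] * p], &Z[tr[v] * p], p, kernel, gamma);
      K[u * n + v] = k;
      K[v * n + u] = k;
    }
  SvmFit fit;
  smo_solve(K, y, n, C, fit);

  for (size_t t = 0; t < te.size(); ++t) {
    double f = -fit.rho;
    for (int u = 0; u < n; ++u)
      if (fit.alpha[u] > 0)
        f += fit.alpha[u] * y[u] *
             kern(&Z[tr[u] * p], &Z[te[t] * p], p, kernel, gamma);
    int pred = (f >= 0) ? 1 : -1;
    if (ylab[te[t]] == pred) ++correct;
  }
  return correct;
}

//' @name cv_accuracy_batch
//' @title Batched repeated-CV SVM accuracy (internal)
//' @description For each feature subset, runs the full repeated k-fold CV
//'   with per-fold training standardization and returns per-repeat accuracy.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cv_accuracy_batch(NumericMatrix X, IntegerVector y01,
                                IntegerMatrix folds, List subsets,
                                double cost, int kernel, double gamma,
                                bool standardize) {
  int n = X.nrow();            // samples
  int R = folds.ncol();        // repeats
  int nsub = subsets.size();
  int nfolds = 0;
  for (int r = 0; r < R; ++r)
    for (int s = 0; s < n; ++s) nfolds = std::max(nfolds, folds(s, r));

  std::vector<int> ylab(n);
  for (int s = 0; s < n; ++s) ylab[s] = y01[s] == 0 ? 1 : -1;

  // Precompute standardized columns per (feature, repeat, fold): value for
  // every sample, scaled by the training-fold mean/sd of that feature.
  // Constant training features become all-zero columns.
  int N = X.ncol();
  std::vector<double> std_col;
  if (standardize)
    std_col.resize((size_t)N * R * nfolds * n);
  for (int j = 0; standardize && j < N; ++j)
    for (int r = 0; r < R; ++r)
      for (int f = 1; f <= nfolds; ++f) {
        double m = 0, m2 = 0;
        int ntr = 0;
        for (int s = 0; s < n; ++s)
          if (folds(s, r) != f) { m += X(s, j); ++ntr; }
        m /= ntr;
        for (int s = 0; s < n; ++s)
          if (folds(s, r) != f) { double d = X(s, j) - m; m2 += d * d; }
        double sd = ntr > 1 ? std::sqrt(m2 / (ntr - 1)) : 0.0;
        double *dst = &std_col[(((size_t)j * R + r) * nfolds + (f - 1)) * n];
        for (int s = 0; s < n; ++s)
          dst[s] = sd > 0 ? (X(s, j) - m) / sd : 0.0;
      }

  NumericMatrix out(nsub, R);
  std::vector<int> tr, te;
  for (int b = 0; b < nsub; ++b) {
    IntegerVector sub = subsets[b];
    int p = sub.size();
    std::vector<double> Z((size_t)n * p);
    double g = gamma > 0 ? gamma : 1.0 / p;
    for (int r = 0; r < R; ++r) {
      int correct = 0;
      for (int f = 1; f <= nfolds; ++f) {
        tr.clear(); te.clear();
        for (int s = 0; s < n; ++s)
          (folds(s, r) == f ? te : tr).push_back(s);
        if (te.empty()) continue;
        for (int d = 0; d < p; ++d) {
          int j = sub[d] - 1;
          if (standardize) {
            const double *src =
                &std_col[(((size_t)j * R + r) * nfolds + (f - 1)) * n];
            for (int s = 0; s < n; ++s) Z[s * p + d] = src[s];
          } else {
            for (int s = 0; s < n; ++s) Z[s * p + d] = X(s, j);
          }
        }
        correct += fit_predict(Z, p, tr, te, ylab, cost, kernel, g);
      }
      out(b, r) = (double)correct / n;
    }
  }
  return out;
}

//' @name smo_decision_values
//' @title Decision values of one SMO fit (internal, for cross-checks)
//' @keywords internal
// [[Rcpp::export]]
NumericVector smo_decision_values(NumericMatrix Xtrain, IntegerVector y01,
                                  NumericMatrix Xtest, double cost,
                                  int kernel, double gamma) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xtest.nrow();
  std::vector<int> y(n);
  for (int s = 0; s < n; ++s) y[s] = y01[s] == 0 ? 1 : -1;
  std::vector<double> Z((size_t)n * p), T((size_t)m * p);
  for (int s = 0; s < n; ++s)
    for (int d = 0; d < p; ++d) Z[s * p + d] = Xtrain(s, d);
  for (int s = 0; s < m; ++s)
    for (int d = 0; d < p; ++d) T[s * p + d] = Xtest(s, d);
  double g = gamma > 0 ? gamma : 1.0 / p;
  std::vector<double> K((size_t)n * n);
  for (int u = 0; u < n; ++u)
    for (int v = u; v < n; ++v) {
      double k = kern(&Z[u * p], &Z[v * p], p, kernel, g);
      K[u * n + v] = k;
      K[v * n + u] = k;
    }
  SvmFit fit;
  smo_solve(K, y, n, cost, fit);
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double f = -fit.rho;
    for (int u = 0; u < n; ++u)
      if (fit.alpha[u] > 0)
        f += fit.alpha[u] * y[u] * kern(&Z[u * p], &T[t * p], p, kernel, g);
    out[t] = f;
  }
  return out;
}
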