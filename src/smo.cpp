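// Sequential minimal optimization solvers for the linear decoders used
// throughout the package: a two-class C-SVC (why-vs-how decoding) and a
// nu-SVR (score prediction), both operating on precomputed Gram matrices so
// that label permutations and cross-validation folds reuse one kernel.
// Working-set selection is the first-order maximal-violating-pair rule.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TAU = 1e-12;

// ---------------------------------------------------------------------------
// C-SVC dual on a Gram matrix: min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0,
// Q_ij = y_i y_j K_ij.  Returns alpha and rho; decision
// f(x) = sum_i y_i alpha_i K(x_i, x) - rho.
struct SvcModel {
  std::vector<double> alpha;
  double rho;
};

static SvcModel svc_solve(const double *K, int n, int ldk,
                          const int *idx, int ntr, const int *y,
                          double C, double eps = 1e-6, int max_iter = 100000) {
  std::vector<double> a(ntr, 0.0), G(ntr, -1.0);
  // cached kernel accessor over the training subset
  #define KK(i, j) K[(size_t)idx[(i)] * ldk + idx[(j)]]
  int iter = 0;
  double Gmax = 0, Gmin = 0;
  while (iter++ < max_iter) {
    int i = -1, j = -1;
    Gmax = -HUGE_VAL; Gmin = HUGE_VAL;
    for (int t = 0; t < ntr; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      bool lo = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;
    double s = (double)y[i] * y[j];
    double L, H;
    if (s < 0) { L = std::max(0.0, a[j] - a[i]); H = std::min(C, C + a[j] - a[i]); }
    else       { L = std::max(0.0, a[i] + a[j] - C); H = std::min(C, a[i] + a[j]); }
    double eta = KK(i, i) + KK(j, j) - 2.0 * KK(i, j);
    if (eta <= 0) eta = TAU;
    double Ei = y[i] * G[i], Ej = y[j] * G[j];  // E_t = f(x_t) - y_t
    double aj_new = a[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L; else if (aj_new > H) aj_new = H;
    double dj = aj_new - a[j];
    if (std::fabs(dj) < 1e-14) break;
    double di = -s * dj;
    a[i] += di; a[j] += dj;
    // snap to the box so bound membership stays exact
    if (a[i] < 1e-12) a[i] = 0; else if (a[i] > C - 1e-12) a[i] = C;
    if (a[j] < 1e-12) a[j] = 0; else if (a[j] > C - 1e-12) a[j] = C;
    for (int t = 0; t < ntr; ++t)
      G[t] += y[t] * (y[i] * KK(t, i) * di + y[j] * KK(t, j) * dj);
  }
  // rho from free support vectors, else midpoint of the violating bounds
  double r = 0; int nfree = 0;
  for (int t = 0; t < ntr; ++t)
    if (a[t] > 1e-12 && a[t] < C - 1e-12) { r += y[t] * G[t]; ++nfree; }
  double rho = nfree ? r / nfree : -(Gmax + Gmin) / 2.0;
  #undef KK
  SvcModel m; m.alpha = a; m.rho = rho;
  return m;
}

// decision value for a test point given its kernel row against training points
static double svc_decide(const SvcModel &m, const double *Krow, int ldk,
                         const int *idx, int ntr, const int *y) {
  double f = 0;
  for (int t = 0; t < ntr; ++t)
    if (m.alpha[t] > 0) f += y[t] * m.alpha[t] * Krow[(size_t)idx[t]];
  return f - m.rho;
}

// [[Rcpp::export(name = ".svc_fit_gram")]]
List svc_fit_gram(NumericMatrix K, IntegerVector y, double cost) {
  int n = K.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  SvcModel m = svc_solve(REAL(K), n, n, idx.data(), n, INTEGER(y), cost);
  return List::create(_["alpha"] = NumericVector(m.alpha.begin(), m.alpha.end()),
                      _["rho"] = m.rho);
}

// [[Rcpp::export(name = ".svc_decision_gram")]]
NumericVector svc_decision_gram(NumericMatrix Ktt, IntegerVector y,
                                NumericVector alpha, double rho) {
  // Ktt: n_test x n_train kernel block
  int ntest = Ktt.nrow(), ntr = Ktt.ncol();
  NumericVector out(ntest);
  for (int s = 0; s < ntest; ++s) {
    double f = 0;
    for (int t = 0; t < ntr; ++t) f += y[t] * alpha[t] * Ktt(s, t);
    out[s] = f - rho;
  }
  return out;
}

// cross-validated accuracy on one Gram matrix; folds = list of 1-based test
// index vectors, training set is the complement within the same Gram
// [[Rcpp::export(name = ".svc_cv_accuracy_gram")]]
double svc_cv_accuracy_gram(NumericMatrix K, IntegerVector y, List folds,
                            double cost) {
  int n = K.nrow();
  const double *Kp = REAL(K);
  int ncorrect = 0, ntested = 0;
  for (int f = 0; f < folds.size(); ++f) {
    IntegerVector test = folds[f];
    std::vector<bool> is_test(n, false);
    for (int t = 0; t < test.size(); ++t) is_test[test[t] - 1] = true;
    std::vector<int> tr, yt;
    for (int t = 0; t < n; ++t)
      if (!is_test[t]) { tr.push_back(t); yt.push_back(y[t]); }
    SvcModel m = svc_solve(Kp, n, n, tr.data(), (int)tr.size(), yt.data(), cost);
    for (int t = 0; t < test.size(); ++t) {
      int ti = test[t] - 1;
      double d = svc_decide(m, Kp + (size_t)ti * n, n, tr.data(), (int)tr.size(),
                            yt.data());
      int pred = d >= 0 ? 1 : -1;
      if (pred == y[ti]) ++ncorrect;
      ++ntested;
    }
  }
  return 100.0 * ncorrect / std::max(1, ntested);
}

// ---------------------------------------------------------------------------
// Searchlight driver.  X: n_blocks x n_vox pattern matrix; sphere: n_vox x m
// matrix of 1-based voxel indices per center (0 = unused slot); folds as above.
// Writes the cross-validated accuracy of each center voxel.
// [[Rcpp::export(name = ".searchlight_accuracy")]]
NumericVector searchlight_accuracy(NumericMatrix X, IntegerVector y,
                                   IntegerMatrix sphere, List folds,
                                   double cost) {
  int nb = X.nrow(), nvox = X.ncol();
  int m = sphere.ncol();
  if (sphere.nrow() != nvox) stop("sphere table and pattern matrix disagree");
  const double *Xp = REAL(X);
  int nf = folds.size();
  std::vector<std::vector<int> > test_idx(nf);
  for (int f = 0; f < nf; ++f) {
    IntegerVector tf = folds[f];
    for (int t = 0; t < tf.size(); ++t) test_idx[f].push_back(tf[t] - 1);
  }
  // per-fold training sets are identical for every voxel: prepare once
  std::vector<std::vector<int> > tr_idx(nf), tr_y(nf);
  for (int f = 0; f < nf; ++f) {
    std::vector<bool> is_test(nb, false);
    for (size_t t = 0; t < test_idx[f].size(); ++t) is_test[test_idx[f][t]] = true;
    for (int t = 0; t < nb; ++t)
      if (!is_test[t]) { tr_idx[f].push_back(t); tr_y[f].push_back(y[t]); }
  }
  NumericVector out(nvox);
  std::vector<double> Kf((size_t)nb * nb);
  for (int v = 0; v < nvox; ++v) {
    // local Gram over sphere voxels; accumulate one member column at a time
    std::fill(Kf.begin(), Kf.end(), 0.0);
    for (int s = 0; s < m; ++s) {
      int w = sphere(v, s);
      if (w <= 0) continue;
      const double *col = Xp + (size_t)(w - 1) * nb;
      for (int i = 0; i < nb; ++i) {
        double ci = col[i];
        double *Ki = &Kf[(size_t)i * nb];
        for (int j = i; j < nb; ++j) Ki[j] += ci * col[j];
      }
    }
    for (int i = 1; i < nb; ++i)
      for (int j = 0; j < i; ++j) Kf[(size_t)i * nb + j] = Kf[(size_t)j * nb + i];
    int ncorrect = 0, ntested = 0;
    for (int f = 0; f < nf; ++f) {
      SvcModel mod = svc_solve(Kf.data(), nb, nb, tr_idx[f].data(),
                               (int)tr_idx[f].size(), tr_y[f].data(), cost);
      for (size_t t = 0; t < test_idx[f].size(); ++t) {
        int ti = test_idx[f][t];
        double d = svc_decide(mod, Kf.data() + (size_t)ti * nb, nb,
                              tr_idx[f].data(), (int)tr_idx[f].size(),
                              tr_y[f].data());
        if ((d >= 0 ? 1 : -1) == y[ti]) ++ncorrect;
        ++ntested;
      }
    }
    out[v] = 100.0 * ncorrect / std::max(1, ntested);
  }
  return out;
}

// ---------------------------------------------------------------------------
// nu-SVR dual (Gram form): variables t = (alpha, alpha*), boxes [0, C],
// sum(alpha - alpha*) = 0, sum(alpha + alpha*) = C * nu * l.  Working pairs
// are chosen within the alpha block or within the alpha* block so both
// equality constraints are preserved.
struct NusvrModel {
  std::vector<double> beta;  // alpha - alpha*
  double b;
  double eps_tube;
};

static NusvrModel nusvr_solve(const double *K, int n, int ldk,
                              const int *idx, int ntr, const double *yv,
                              double C, double nu, double eps = 1e-8,
                              int max_iter = 200000) {
  #define KK(i, j) K[(size_t)idx[(i)] * ldk + idx[(j)]]
  std::vector<double> a(ntr), as(ntr), G(ntr), Gs(ntr);
  double sum = C * nu * ntr / 2.0;
  for (int i = 0; i < ntr; ++i) {
    double v = std::min(sum, C);
    a[i] = as[i] = v;
    sum -= v;
  }
  // gradient: G_i = (K beta)_i - y_i (alpha block), Gs_i = -(K beta)_i + y_i
  for (int i = 0; i < ntr; ++i) {
    double kb = 0;
    for (int j = 0; j < ntr; ++j) kb += KK(i, j) * (a[j] - as[j]);
    G[i] = kb - yv[i];
    Gs[i] = -kb + yv[i];
  }
  int iter = 0;
  while (iter++ < max_iter) {
    // maximal violating pair within each block: move t_i up, t_j down
    int i1 = -1, j1 = -1, i2 = -1, j2 = -1;
    double up1 = HUGE_VAL, lo1 = -HUGE_VAL, up2 = HUGE_VAL, lo2 = -HUGE_VAL;
    for (int t = 0; t < ntr; ++t) {
      if (a[t] < C && G[t] < up1) { up1 = G[t]; i1 = t; }
      if (a[t] > 0 && G[t] > lo1) { lo1 = G[t]; j1 = t; }
      if (as[t] < C && Gs[t] < up2) { up2 = Gs[t]; i2 = t; }
      if (as[t] > 0 && Gs[t] > lo2) { lo2 = Gs[t]; j2 = t; }
    }
    double gap1 = (i1 >= 0 && j1 >= 0) ? lo1 - up1 : -HUGE_VAL;
    double gap2 = (i2 >= 0 && j2 >= 0) ? lo2 - up2 : -HUGE_VAL;
    if (std::max(gap1, gap2) < eps) break;
    bool blk1 = gap1 >= gap2;
    int i = blk1 ? i1 : i2, j = blk1 ? j1 : j2;
    std::vector<double> &t = blk1 ? a : as;
    std::vector<double> &g = blk1 ? G : Gs;
    double eta = KK(i, i) + KK(j, j) - 2.0 * KK(i, j);
    if (eta <= 0) eta = TAU;
    double d = (g[j] - g[i]) / eta;     // increase t_i, decrease t_j
    d = std::min(d, std::min(C - t[i], t[j]));
    if (d <= 1e-14) break;
    t[i] += d; t[j] -= d;
    if (t[i] < 1e-12) t[i] = 0; else if (t[i] > C - 1e-12) t[i] = C;
    if (t[j] < 1e-12) t[j] = 0; else if (t[j] > C - 1e-12) t[j] = C;
    for (int s = 0; s < ntr; ++s) {
      double dk = d * (KK(s, i) - KK(s, j));
      if (blk1) { G[s] += dk; Gs[s] -= dk; }
      else      { G[s] -= dk; Gs[s] += dk; }
    }
  }
  // offsets from free variables in each block: free alpha -> G = eps - b,
  // free alpha* -> Gs = eps + b
  double r1, r2, acc; int nf;
  acc = 0; nf = 0;
  double ub = HUGE_VAL, lb = -HUGE_VAL;
  for (int s = 0; s < ntr; ++s) {
    if (a[s] > 1e-12 && a[s] < C - 1e-12) { acc += G[s]; ++nf; }
    else if (a[s] <= 1e-12) ub = std::min(ub, G[s]);
    else lb = std::max(lb, G[s]);
  }
  r1 = nf ? acc / nf : (ub + lb) / 2.0;
  acc = 0; nf = 0; ub = HUGE_VAL; lb = -HUGE_VAL;
  for (int s = 0; s < ntr; ++s) {
    if (as[s] > 1e-12 && as[s] < C - 1e-12) { acc += Gs[s]; ++nf; }
    else if (as[s] <= 1e-12) ub = std::min(ub, Gs[s]);
    else lb = std::max(lb, Gs[s]);
  }
  r2 = nf ? acc / nf : (ub + lb) / 2.0;
  NusvrModel m;
  m.beta.resize(ntr);
  for (int s = 0; s < ntr; ++s) m.beta[s] = a[s] - as[s];
  m.b = (r2 - r1) / 2.0;
  m.eps_tube = (r1 + r2) / 2.0;
  #undef KK
  return m;
}

// [[Rcpp::export(name = ".nusvr_fit_gram")]]
List nusvr_fit_gram(NumericMatrix K, NumericVector y, double cost, double nu) {
  int n = K.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NusvrModel m = nusvr_solve(REAL(K), n, n, idx.data(), n, REAL(y), cost, nu);
  return List::create(_["beta"] = NumericVector(m.beta.begin(), m.beta.end()),
                      _["b"] = m.b, _["epsilon"] = m.eps_tube);
}

// leave-one-out predictions over one Gram matrix (LOPO when rows = subjects)
// [[Rcpp::export(name = ".loo_svr_gram")]]
NumericVector loo_svr_gram(NumericMatrix K, NumericVector y, double cost,
                           double nu) {
  int n = K.nrow();
  const double *Kp = REAL(K);
  NumericVector pred(n);
  std::vector<int> tr(n - 1);
  std::vector<double> yt(n - 1);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int t = 0; t < n; ++t)
      if (t != i) { tr[k] = t; yt[k] = y[t]; ++k; }
    NusvrModel m = nusvr_solve(Kp, n, n, tr.data(), n - 1, yt.data(), cost, nu);
    double f = m.b;
    const double *Krow = Kp + (size_t)i * n;
    for (int t = 0; t < n - 1; ++t) f += m.beta[t] * Krow[tr[t]];
    pred[i] = f;
  }
  return pred;
}
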