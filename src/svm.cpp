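// Linear C-SVC via SMO on a precomputed Gram matrix, plus the
// cross-validation / permutation / elimination loops that dominate runtime.
//
// The solver follows the standard SMO formulation with second-order working
// set selection (maximal violating pair refined by the quadratic gain), the
// same dual problem libsvm solves for kernel="linear", cost C:
//   min_a 0.5 a' Q a - e' a,  0 <= a_i <= C,  sum_i y_i a_i = 0,
// with Q_ij = y_i y_j K_ij.  Decision value f(x) = sum_i a_i y_i K(x_i,x) - rho.
// All fits address rows of one shared Gram matrix through an index vector, so
// a fit's cost is independent of the voxel count.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double TAU = 1e-12;

struct SvmFit {
  std::vector<double> alpha; // length n_sub
  double rho;
  int iter;
};

// K: full Gram; idx: 0-based rows of this fit; y: +1/-1 per element of idx
static SvmFit smo_solve(const double* K, int n_all,
                        const std::vector<int>& idx,
                        const std::vector<signed char>& y,
                        double C, double eps, int max_iter,
                        const std::vector<double>* alpha0 = nullptr) {
  const int n = (int)idx.size();
  std::vector<double> alpha(n, 0.0), G(n, -1.0), QD(n);
  for (int i = 0; i < n; ++i) QD[i] = K[(size_t)idx[i] * n_all + idx[i]];
  if (alpha0) {
    alpha = *alpha0;
    // G_i = sum_j a_j y_i y_j K_ij - 1
    for (int j = 0; j < n; ++j) {
      if (alpha[j] == 0.0) continue;
      const double* Kj = K + (size_t)idx[j] * n_all;
      double ay = alpha[j] * y[j];
      for (int i = 0; i < n; ++i) G[i] += y[i] * ay * Kj[idx[i]];
    }
  }

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set selection
    double Gmax = -HUGE_VAL, Gmax2 = -HUGE_VAL;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      if (y[t] == +1 ? (alpha[t] < C) : (alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v >= Gmax) { Gmax = v; i = t; }
      }
    }
    int j = -1;
    double obj_min = HUGE_VAL;
    const double* Ki = (i >= 0) ? K + (size_t)idx[i] * n_all : nullptr;
    for (int t = 0; t < n; ++t) {
      if (y[t] == +1 ? (alpha[t] > 0) : (alpha[t] < C)) {
        double v = y[t] * G[t];
        if (v > Gmax2) Gmax2 = v;
        double grad_diff = Gmax + v;
        if (grad_diff > 0 && i >= 0) {
          double quad = QD[i] + QD[t] - 2.0 * Ki[idx[t]];
          if (quad <= 0) quad = TAU;
          double obj = -(grad_diff * grad_diff) / quad;
          if (obj <= obj_min) { obj_min = obj; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < eps) break;

    const double* Kj = K + (size_t)idx[j] * n_all;
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = QD[i] + QD[j] - 2.0 * Ki[idx[j]];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * Ki[idx[j]];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t) {
      double Kti_ = Ki[idx[t]], Ktj_ = Kj[idx[t]];
      G[t] += y[t] * (y[i] * Kti_ * dai + y[j] * Ktj_ * daj);
    }
  }

  // rho
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12 * C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12 * C) {
      if (y[t] == +1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  SvmFit fit;
  fit.alpha = std::move(alpha);
  fit.rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
  fit.iter = iter;
  return fit;
}

// decision value of a fit at Gram row `t`
static double decision_at(const double* K, int n_all,
                          const std::vector<int>& idx,
                          const std::vector<signed char>& y,
                          const std::vector<double>& alpha,
                          double rho, int t) {
  const double* Kt = K + (size_t)t * n_all; // column t == row t (symmetric)
  double f = 0.0;
  for (size_t s = 0; s < idx.size(); ++s)
    if (alpha[s] > 0) f += alpha[s] * y[s] * Kt[idx[s]];
  return f - rho;
}

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix K, IntegerVector rows, IntegerVector y,
                   double cost, double eps = 1e-3, int max_iter = 200000) {
  int n_all = K.nrow();
  std::vector<int> idx(rows.begin(), rows.end());
  std::vector<signed char> yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = (signed char)y[i];
  SvmFit fit = smo_solve(REAL(K), n_all, idx, yy, cost, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["rho"] = fit.rho, _["iterations"] = fit.iter);
}

struct OvoProblem {
  const double* K;
  int n;
  std::vector<int> cls;            // sorted distinct labels
  int nc;
};

// one-vs-one LOSO: returns predicted label per sample
static void loso_ovo_predict(const double* K, int n, const int* labels,
                             double C, double eps, int max_iter, int tie_rule,
                             int* pred_out) {
  std::vector<int> cls;
  for (int i = 0; i < n; ++i)
    if (std::find(cls.begin(), cls.end(), labels[i]) == cls.end())
      cls.push_back(labels[i]);
  std::sort(cls.begin(), cls.end());
  const int nc = (int)cls.size();

  std::vector<double> votes(n * nc, 0.0), dsum(n * nc, 0.0);

  for (int a = 0; a < nc; ++a) for (int b = a + 1; b < nc; ++b) {
    // full pair fit: used for every test sample not in this pair
    std::vector<int> pidx;
    std::vector<signed char> py;
    for (int i = 0; i < n; ++i) {
      if (labels[i] == cls[a]) { pidx.push_back(i); py.push_back(+1); }
      else if (labels[i] == cls[b]) { pidx.push_back(i); py.push_back(-1); }
    }
    SvmFit full = smo_solve(K, n, pidx, py, C, eps, max_iter);
    for (int t = 0; t < n; ++t) {
      double f;
      bool in_pair = (labels[t] == cls[a] || labels[t] == cls[b]);
      double alpha_t = 0.0;
      if (in_pair) {
        for (size_t s = 0; s < pidx.size(); ++s)
          if (pidx[s] == t) { alpha_t = full.alpha[s]; break; }
      }
      if (in_pair && alpha_t > 0.0) {
        // refit with t excluded, warm-started from the full-pair solution
        std::vector<int> idx2; std::vector<signed char> y2;
        std::vector<double> a0;
        idx2.reserve(pidx.size() - 1); y2.reserve(pidx.size() - 1);
        a0.reserve(pidx.size() - 1);
        signed char yt = 0; double at = 0.0;
        for (size_t s = 0; s < pidx.size(); ++s) {
          if (pidx[s] == t) { yt = py[s]; at = full.alpha[s]; continue; }
          idx2.push_back(pidx[s]); y2.push_back(py[s]);
          a0.push_back(full.alpha[s]);
        }
        if (at > 0) {
          // restore sum_i y_i a_i = 0: add y_t*at using remaining slack,
          // preferring free SVs (their gradients are already zero)
          double deficit = at;
          for (int pass = 0; pass < 2 && deficit > 1e-15; ++pass) {
            for (size_t s = 0; s < idx2.size() && deficit > 1e-15; ++s) {
              bool free_sv = a0[s] > 0 && a0[s] < C;
              if (pass == 0 && !free_sv) continue;
              double room = (y2[s] == yt) ? (C - a0[s]) : a0[s];
              if (room <= 0) continue;
              double d = std::min(room, deficit);
              a0[s] += (y2[s] == yt) ? d : -d;
              deficit -= d;
            }
          }
        }
        SvmFit fit = smo_solve(K, n, idx2, y2, C, eps, max_iter, &a0);
        f = decision_at(K, n, idx2, y2, fit.alpha, fit.rho, t);
      } else {
        // t outside the pair, or a non-support vector of the full pair fit:
        // removing it leaves the KKT conditions (hence the model) unchanged
        f = decision_at(K, n, pidx, py, full.alpha, full.rho, t);
      }
      int winner = (f > 0) ? a : b;   // f == 0 -> lower label, fixed rule
      votes[(size_t)t * nc + winner] += 1.0;
      dsum[(size_t)t * nc + a] += f;
      dsum[(size_t)t * nc + b] -= f;
    }
  }

  for (int t = 0; t < n; ++t) {
    const double* v = &votes[(size_t)t * nc];
    const double* d = &dsum[(size_t)t * nc];
    int best = 0;
    for (int c = 1; c < nc; ++c) {
      if (v[c] > v[best]) best = c;
      else if (tie_rule == 1 && v[c] == v[best] && d[c] > d[best]) best = c;
      // tie_rule 0: keep lower label (earlier index wins ties)
    }
    pred_out[t] = cls[best];
  }
}

// [[Rcpp::export]]
IntegerVector cpp_loso_ovo(NumericMatrix K, IntegerVector labels, double cost,
                           int tie_rule = 0, double eps = 1e-3,
                           int max_iter = 200000) {
  int n = K.nrow();
  IntegerVector pred(n);
  loso_ovo_predict(REAL(K), n, INTEGER(labels), cost, eps, max_iter, tie_rule,
                   INTEGER(pred));
  return pred;
}

// Accuracy of LOSO one-vs-one decoding for each column of `label_perms`.
// [[Rcpp::export]]
NumericVector cpp_perm_null_ovo(NumericMatrix K, IntegerMatrix label_perms,
                                double cost, int tie_rule = 0,
                                double eps = 1e-3, int max_iter = 200000) {
  int n = K.nrow(), np = label_perms.ncol();
  NumericVector acc(np);
  std::vector<int> pred(n);
  for (int p = 0; p < np; ++p) {
    const int* lab = INTEGER(label_perms) + (size_t)p * n;
    loso_ovo_predict(REAL(K), n, lab, cost, eps, max_iter, tie_rule, pred.data());
    int ok = 0;
    for (int t = 0; t < n; ++t) if (pred[t] == lab[t]) ++ok;
    acc[p] = (double)ok / n;
    if ((p & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}

// Backward voxel elimination under LOSO.
// X: n x p data; for every fold, voxels are dropped one at a time by lowest
// mean squared pairwise weight on the training rows (ties -> lowest index).
// Returns per-fold elimination order and per-(m, fold) correctness.
// [[Rcpp::export]]
List cpp_rfe(NumericMatrix X, IntegerVector labels, double cost,
             int tie_rule = 0, double eps = 1e-3, int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> cls;
  for (int i = 0; i < n; ++i)
    if (std::find(cls.begin(), cls.end(), labels[i]) == cls.end())
      cls.push_back(labels[i]);
  std::sort(cls.begin(), cls.end());
  const int nc = (int)cls.size();
  const int npair = nc * (nc - 1) / 2;

  // base Gram over all voxels
  std::vector<double> K0((size_t)n * n, 0.0);
  {
    const double* x = REAL(X);
    for (int v = 0; v < p; ++v) {
      const double* xv = x + (size_t)v * n;
      for (int i = 0; i < n; ++i) {
        double xi = xv[i];
        if (xi == 0.0) continue;
        double* Ki = &K0[(size_t)i * n];
        for (int j = 0; j <= i; ++j) Ki[j] += xi * xv[j];
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) K0[(size_t)i * n + j] = K0[(size_t)j * n + i];
  }

  IntegerMatrix order(p, n);       // elimination order (1-based voxel ids), per fold
  IntegerMatrix correct(p, n);     // row m-1: prediction correct at voxel count m
  std::vector<double> K((size_t)n * n);
  std::vector<double> sens(p), w(p);
  const double* x = REAL(X);

  for (int t = 0; t < n; ++t) {
    std::copy(K0.begin(), K0.end(), K.begin());
    std::vector<int> active(p);
    for (int v = 0; v < p; ++v) active[v] = v;
    int ord_pos = 0;

    for (int m = p; m >= 1; --m) {
      std::fill(sens.begin(), sens.end(), 0.0);
      double votes[16] = {0}, dsum[16] = {0};
      for (int a = 0; a < nc; ++a) for (int b = a + 1; b < nc; ++b) {
        std::vector<int> idx; std::vector<signed char> yy;
        for (int i = 0; i < n; ++i) {
          if (i == t) continue;
          if (labels[i] == cls[a]) { idx.push_back(i); yy.push_back(+1); }
          else if (labels[i] == cls[b]) { idx.push_back(i); yy.push_back(-1); }
        }
        SvmFit fit = smo_solve(K.data(), n, idx, yy, cost, eps, max_iter);
        double f = decision_at(K.data(), n, idx, yy, fit.alpha, fit.rho, t);
        int winner = (f > 0) ? a : b;
        votes[winner] += 1.0; dsum[a] += f; dsum[b] -= f;
        if (m > 1) {
          // accumulate squared weights over active voxels
          for (int vi = 0; vi < m; ++vi) w[vi] = 0.0;
          for (size_t s = 0; s < idx.size(); ++s) {
            double ay = fit.alpha[s] * yy[s];
            if (ay == 0.0) continue;
            const double* xr = x + idx[s];
            for (int vi = 0; vi < m; ++vi)
              w[vi] += ay * xr[(size_t)active[vi] * n];
          }
          for (int vi = 0; vi < m; ++vi) sens[vi] += w[vi] * w[vi];
        }
      }
      int best = 0;
      for (int c = 1; c < nc; ++c) {
        if (votes[c] > votes[best]) best = c;
        else if (tie_rule == 1 && votes[c] == votes[best] && dsum[c] > dsum[best]) best = c;
      }
      correct(m - 1, t) = (cls[best] == labels[t]) ? 1 : 0;

      if (m == 1) { order(ord_pos++, t) = active[0] + 1; break; }
      // least mean squared weight; mean over npair is a constant factor
      int drop = 0;
      for (int vi = 1; vi < m; ++vi) {
        if (sens[vi] < sens[drop]) drop = vi;
        // ties: keep lower voxel index; active[] is ascending so first wins
      }
      int vdrop = active[drop];
      order(ord_pos++, t) = vdrop + 1;
      // Gram downdate
      const double* xv = x + (size_t)vdrop * n;
      for (int i = 0; i < n; ++i) {
        double xi = xv[i];
        if (xi == 0.0) continue;
        double* Ki = &K[(size_t)i * n];
        for (int j = 0; j < n; ++j) Ki[j] -= xi * xv[j];
      }
      active.erase(active.begin() + drop);
    }
    Rcpp::checkUserInterrupt();
  }
  (void)npair;
  return List::create(_["order"] = order, _["correct"] = correct);
}

// Accuracy per voxel count for label permutations of the elimination
// procedure (null curves for the sparsity analysis).
// [[Rcpp::export]]
NumericMatrix cpp_rfe_perm_null(NumericMatrix X, IntegerMatrix label_perms,
                                double cost, int tie_rule = 0,
                                double eps = 1e-3, int max_iter = 200000) {
  const int p = X.ncol(), np = label_perms.ncol(), n = X.nrow();
  NumericMatrix acc(p, np); // row m-1: null accuracy at voxel count m
  for (int q = 0; q < np; ++q) {
    IntegerVector lab(n);
    for (int i = 0; i < n; ++i) lab[i] = label_perms(i, q);
    List r = cpp_rfe(X, lab, cost, tie_rule, eps, max_iter);
    IntegerMatrix correct = r["correct"];
    for (int m = 0; m < p; ++m) {
      int ok = 0;
      for (int t = 0; t < n; ++t) ok += correct(m, t);
      acc(m, q) = (double)ok / n;
    }
    Rcpp::checkUserInterrupt();
  }
  return acc;
}
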