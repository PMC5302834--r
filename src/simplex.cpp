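#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex for the small LPs of flux validation:
//   maximize c'x  s.t.  A x = b,  0 <= x <= u.
// Upper bounds are handled as explicit slack rows, equality rows get
// artificial variables in phase 1. Dantzig pricing with a Bland fallback
// after a pivot budget guards against cycling; tolerances suit the
// integer-coefficient stoichiometric systems this package builds.
//
// Returns: status (0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit),
// objective value and primal solution.

static const double EPS = 1e-9;

struct Tableau {
  int m, n;                       // rows, structural+slack columns
  std::vector<double> T;          // (m+1) x (n+1), row-major; last col = rhs
  std::vector<int> basis;
  double& at(int i, int j) { return T[(size_t)i * (n + 1) + j]; }
};

static void pivot(Tableau& tb, int pr, int pc) {
  double piv = tb.at(pr, pc);
  double inv = 1.0 / piv;
  for (int j = 0; j <= tb.n; ++j) tb.at(pr, j) *= inv;
  for (int i = 0; i <= tb.m; ++i) {
    if (i == pr) continue;
    double f = tb.at(i, pc);
    if (std::fabs(f) < EPS) continue;
    for (int j = 0; j <= tb.n; ++j) tb.at(i, j) -= f * tb.at(pr, j);
  }
  tb.basis[pr] = pc;
}

// optimize current objective row (row m); allowed[j] = column may enter
static int run_simplex(Tableau& tb, const std::vector<bool>& allowed,
                       int max_iter) {
  int iter = 0;
  int bland_after = max_iter / 2;
  while (true) {
    if (++iter > max_iter) return 3;
    int pc = -1;
    if (iter <= bland_after) {
      double best = EPS;
      for (int j = 0; j < tb.n; ++j) {
        if (!allowed[j]) continue;
        double r = tb.at(tb.m, j);
        if (r > best) { best = r; pc = j; }
      }
    } else {  // Bland: smallest eligible index
      for (int j = 0; j < tb.n; ++j) {
        if (allowed[j] && tb.at(tb.m, j) > EPS) { pc = j; break; }
      }
    }
    if (pc < 0) return 0;  // optimal
    int pr = -1;
    double best_ratio = 0.0;
    for (int i = 0; i < tb.m; ++i) {
      double a = tb.at(i, pc);
      if (a > EPS) {
        double ratio = tb.at(i, tb.n) / a;
        if (pr < 0 || ratio < best_ratio - EPS ||
            (ratio < best_ratio + EPS && tb.basis[i] < tb.basis[pr])) {
          pr = i; best_ratio = ratio;
        }
      }
    }
    if (pr < 0) return 2;  // unbounded
    pivot(tb, pr, pc);
  }
}

// [[Rcpp::export]]
List cpp_lp_max(NumericVector obj, NumericMatrix Aeq, NumericVector beq,
                NumericVector upper, int max_iter = 20000) {
  int me = Aeq.nrow();          // equality rows
  int nx = obj.size();          // structural variables
  std::vector<int> bounded;     // variables with finite upper bound rows
  for (int j = 0; j < nx; ++j) {
    if (R_finite(upper[j])) bounded.push_back(j);
  }
  int mu = (int)bounded.size();
  int m = me + mu;
  int n = nx + mu + me;         // structurals + ub slacks + artificials
  Tableau tb;
  tb.m = m; tb.n = n;
  tb.T.assign((size_t)(m + 1) * (n + 1), 0.0);
  tb.basis.assign(m, -1);

  // equality rows, sign-flipped so rhs >= 0, artificial basis
  for (int i = 0; i < me; ++i) {
    double s = (beq[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < nx; ++j) tb.at(i, j) = s * Aeq(i, j);
    tb.at(i, n) = s * beq[i];
    tb.at(i, nx + mu + i) = 1.0;
    tb.basis[i] = nx + mu + i;
  }
  // upper-bound rows x_j + s = u_j, slack basis
  for (int k = 0; k < mu; ++k) {
    int i = me + k;
    tb.at(i, bounded[k]) = 1.0;
    tb.at(i, nx + k) = 1.0;
    tb.at(i, n) = upper[bounded[k]];
    tb.basis[i] = nx + k;
  }

  std::vector<bool> allowed(n, true);

  // phase 1: maximize -sum(artificials) => row = sum of artificial rows
  for (int i = 0; i < me; ++i) {
    for (int j = 0; j <= n; ++j) tb.at(m, j) += tb.at(i, j);
  }
  for (int i = 0; i < me; ++i) tb.at(m, nx + mu + i) = 0.0;
  int st = run_simplex(tb, allowed, max_iter);
  if (st == 3) return List::create(_["status"] = 3);
  if (tb.at(m, n) > 1e-7) {
    return List::create(_["status"] = 1);  // infeasible
  }
  // drive any residual artificial out of the basis
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] >= nx + mu) {
      int pc = -1;
      for (int j = 0; j < nx + mu; ++j) {
        if (std::fabs(tb.at(i, j)) > 1e-7) { pc = j; break; }
      }
      if (pc >= 0) pivot(tb, i, pc);
      // else: redundant row, harmless to leave
    }
  }
  for (int j = nx + mu; j < n; ++j) allowed[j] = false;

  // phase 2 objective
  for (int j = 0; j <= n; ++j) tb.at(m, j) = 0.0;
  for (int j = 0; j < nx; ++j) tb.at(m, j) = obj[j];
  for (int i = 0; i < m; ++i) {
    int bj = tb.basis[i];
    double cb = (bj < nx) ? obj[bj] : 0.0;
    if (cb != 0.0) {
      for (int j = 0; j <= n; ++j) tb.at(m, j) -= cb * tb.at(i, j);
    }
  }
  // row m now holds reduced costs (entering where > 0) and -objective in rhs
  st = run_simplex(tb, allowed, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(nx);
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] < nx) x[tb.basis[i]] = tb.at(i, n);
  }
  double val = 0.0;
  for (int j = 0; j < nx; ++j) val += obj[j] * x[j];
  return List::create(_["status"] = 0, _["objective"] = val, _["x"] = x);
}
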