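// Dense bounded-variable two-phase primal simplex.
//
// Solves   min c'x   s.t.  A x = b,  l <= x <= u
// with finite bounds (the R wrapper caps +/-Inf). Sized for genome-scale-
// metabolic-model toys (tens of metabolites, a few hundred fluxes): the
// basis is refactorised with a fresh LU solve every iteration, which is
// slower asymptotically but numerically the most stable choice at this
// scale. Dantzig pricing with a Bland's-rule fallback guarantees
// termination on degenerate flux polytopes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double FEAS_TOL = 1e-9;
const double OPT_TOL  = 1e-9;

// status of a nonbasic variable
enum NB { AT_LB = 0, AT_UB = 1, BASIC = 2 };

struct SimplexState {
  const mat &A;
  const vec &b;
  vec c;
  vec lb, ub;
  uvec basis;             // m basic column indices
  std::vector<int> stat;  // per-column NB status
  vec x;
  int n, m;

  SimplexState(const mat &A_, const vec &b_) : A(A_), b(b_) {
    m = A.n_rows; n = A.n_cols;
  }

  void recompute_basics() {
    mat B = A.cols(basis);
    vec rhs = b;
    for (int j = 0; j < n; ++j) {
      if (stat[j] == BASIC) continue;
      double xj = (stat[j] == AT_LB) ? lb(j) : ub(j);
      x(j) = xj;
      if (xj != 0.0) rhs -= A.col(j) * xj;
    }
    vec xB = solve(B, rhs, solve_opts::no_approx);
    for (int i = 0; i < m; ++i) x(basis(i)) = xB(i);
  }

  // one phase of simplex; returns 0 optimal, 2 numerical/iteration trouble
  int run(int max_iter) {
    int iter = 0;
    bool bland = false;
    while (true) {
      if (++iter > max_iter) return 2;
      if (iter > max_iter / 2) bland = true;

      mat B = A.cols(basis);
      vec cB(m);
      for (int i = 0; i < m; ++i) cB(i) = c(basis(i));
      vec y;
      bool ok = solve(y, B.t(), cB, solve_opts::no_approx);
      if (!ok) return 2;

      // pricing
      int enter = -1, dir = 0;  // dir +1: increase from lb, -1: decrease from ub
      double best = OPT_TOL;
      for (int j = 0; j < n; ++j) {
        if (stat[j] == BASIC) continue;
        if (ub(j) - lb(j) < 1e-15) continue;  // fixed variable
        double dj = c(j) - dot(y, A.col(j));
        double viol = 0.0; int d = 0;
        if (stat[j] == AT_LB && dj < -OPT_TOL) { viol = -dj; d = +1; }
        else if (stat[j] == AT_UB && dj > OPT_TOL) { viol = dj; d = -1; }
        else continue;
        if (bland) { enter = j; dir = d; break; }
        if (viol > best) { best = viol; enter = j; dir = d; }
      }
      if (enter < 0) return 0;  // optimal

      vec w;
      ok = solve(w, B, A.col(enter), solve_opts::no_approx);
      if (!ok) return 2;

      // ratio test: entering moves by t*dir; basics move by -dir*w*t
      double tmax = ub(enter) - lb(enter);  // bound flip
      int leave = -1;          // index into basis
      int leave_to = AT_LB;    // which bound the leaving variable hits
      for (int i = 0; i < m; ++i) {
        double wi = -dir * w(i);  // d x_B(i) / d t
        int bi = basis(i);
        double t;
        if (wi > 1e-11) {
          t = (ub(bi) - x(bi)) / wi;
          if (t < tmax) { tmax = t; leave = i; leave_to = AT_UB; }
        } else if (wi < -1e-11) {
          t = (lb(bi) - x(bi)) / wi;
          if (t < tmax) { tmax = t; leave = i; leave_to = AT_LB; }
        }
      }
      if (tmax > 1e290) return 3;  // unbounded (cannot occur with finite bounds)
      if (tmax < 0) tmax = 0;

      if (leave < 0) {
        // bound flip: entering goes to its opposite bound
        stat[enter] = (dir > 0) ? AT_UB : AT_LB;
      } else {
        int out = basis(leave);
        stat[out] = leave_to;
        stat[enter] = BASIC;
        basis(leave) = enter;
      }
      recompute_basics();
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".lp_simplex")]]
Rcpp::List lp_simplex(const arma::mat &A, const arma::vec &b,
                      const arma::vec &cost, const arma::vec &lower,
                      const arma::vec &upper, int max_iter = 20000) {
  int m = A.n_rows, n = A.n_cols;

  // Phase 1: append artificials with signed identity columns.
  mat A1(m, n + m);
  A1.cols(0, n - 1) = A;
  vec lb1(n + m), ub1(n + m), c1(n + m, fill::zeros);
  lb1.subvec(0, n - 1) = lower;
  ub1.subvec(0, n - 1) = upper;

  vec x0(n);
  for (int j = 0; j < n; ++j)
    x0(j) = (std::abs(lower(j)) <= std::abs(upper(j))) ? lower(j) : upper(j);
  vec r = b - A * x0;
  for (int i = 0; i < m; ++i) {
    double s = (r(i) >= 0) ? 1.0 : -1.0;
    A1.col(n + i) = zeros<vec>(m);
    A1(i, n + i) = s;
    lb1(n + i) = 0.0;
    ub1(n + i) = std::abs(r(i)) + 1.0;
    c1(n + i) = 1.0;
  }

  SimplexState st(A1, b);
  st.c = c1; st.lb = lb1; st.ub = ub1;
  st.x = vec(n + m, fill::zeros);
  st.basis = regspace<uvec>(n, n + m - 1);
  st.stat.assign(n + m, AT_LB);
  for (int j = 0; j < n; ++j)
    st.stat[j] = (x0(j) == lower(j)) ? AT_LB : AT_UB;
  for (int i = 0; i < m; ++i) st.stat[n + i] = BASIC;
  st.recompute_basics();

  int code = st.run(max_iter);
  if (code != 0)
    return Rcpp::List::create(Rcpp::Named("status") = 2);
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) p1 += st.x(n + i);
  if (p1 > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = 1);  // infeasible

  // Phase 2: real costs; pin artificials to zero.
  for (int i = 0; i < m; ++i) { st.ub(n + i) = 0.0; st.c(n + i) = 0.0; }
  for (int j = 0; j < n; ++j) st.c(j) = cost(j);
  st.recompute_basics();
  code = st.run(max_iter);
  if (code != 0)
    return Rcpp::List::create(Rcpp::Named("status") = 2);

  vec xout = st.x.subvec(0, n - 1);
  // clip rounding noise back into bounds
  for (int j = 0; j < n; ++j) {
    if (xout(j) < lower(j)) xout(j) = lower(j);
    if (xout(j) > upper(j)) xout(j) = upper(j);
  }
  double obj = dot(cost, xout);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = xout,
                            Rcpp::Named("objective") = obj);
}
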