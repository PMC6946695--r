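// Bounded-variable primal simplex (two-phase, dense tableau) with
// branch-and-bound on integer variables.  Sized for the small, dense
// LP/MILP instances that constraint-based metabolic analysis produces
// (hundreds of variables, hundreds of rows).  Deterministic: Dantzig
// pricing with a Bland fallback, fixed tie-breaks, fixed DFS branching.

#include <RcppArmadillo.h>
#include <limits>
#include <vector>
#include <stack>
#include <ctime>

using namespace arma;

static const double INF = std::numeric_limits<double>::infinity();

enum LpStatus { LP_OPTIMAL = 0, LP_INFEASIBLE = 1, LP_UNBOUNDED = 2,
                LP_ITERLIMIT = 3 };

struct LpResult {
  int status;
  double objective;
  vec x;
};

// Solve: maximize c'x  s.t.  A x (sense) b,  lb <= x <= ub.
// sense: -1 "<=", 0 "=", +1 ">=".
static LpResult simplex_solve(const mat& A0, const vec& b0,
                              const ivec& sense, const vec& c,
                              const vec& lb, const vec& ub,
                              int max_iter) {
  const uword m = A0.n_rows, n = A0.n_cols;
  LpResult res;
  res.status = LP_INFEASIBLE;
  res.objective = NA_REAL;
  res.x = vec(n, fill::zeros);

  // Row equilibration for numerical stability.
  mat A = A0;
  vec b = b0;
  for (uword i = 0; i < m; ++i) {
    double s = std::max(std::abs(b(i)), abs(A.row(i)).max());
    if (s > 1e-12 && (s > 1e4 || s < 1e-4)) {
      A.row(i) /= s;
      b(i) /= s;
    }
  }

  // Augment with one slack per row: A x + s = b.
  const uword N = n + m;
  vec vlb(N), vub(N);
  vlb.head(n) = lb; vub.head(n) = ub;
  for (uword i = 0; i < m; ++i) {
    if (sense(i) < 0)      { vlb(n + i) = 0.0;  vub(n + i) = INF; }
    else if (sense(i) > 0) { vlb(n + i) = -INF; vub(n + i) = 0.0; }
    else                   { vlb(n + i) = 0.0;  vub(n + i) = 0.0; }
  }

  // Full tableau over real variables; artificial basis handled implicitly.
  mat T(m, N);
  T.head_cols(n) = A;
  T.tail_cols(m) = eye(m, m);

  // Nonbasic start: each variable at the finite bound nearest zero.
  vec xval(N);
  for (uword j = 0; j < N; ++j) {
    double v = 0.0;
    bool lf = std::isfinite(vlb(j)), uf = std::isfinite(vub(j));
    if (lf && uf) v = (std::abs(vlb(j)) <= std::abs(vub(j))) ? vlb(j) : vub(j);
    else if (lf) v = vlb(j);
    else if (uf) v = vub(j);
    xval(j) = v;
  }

  // Artificial basis: artificial i has column e_i after flipping rows with
  // negative residual, and initial value |r_i|.
  vec r = b - T * xval;
  for (uword i = 0; i < m; ++i)
    if (r(i) < 0.0) T.row(i) *= -1.0;
  vec xB = abs(r);
  std::vector<long> basic(m);            // variable index; >= (long)N => artificial
  std::vector<int> is_basic(N, 0);
  for (uword i = 0; i < m; ++i) basic[i] = (long)N + (long)i;

  auto var_lb = [&](long j) -> double { return j >= (long)N ? 0.0 : vlb((uword)j); };
  auto var_ub = [&](long j) -> double { return j >= (long)N ? INF : vub((uword)j); };

  const double dtol = 1e-9, piv_tol = 1e-9;
  int iter = 0;
  bool bland = false;
  int phase = 1;
  vec cost(N, fill::zeros);              // phase-1: maximize -(sum artificials)

  while (true) {
    if (iter++ > max_iter) { res.status = LP_ITERLIMIT; return res; }
    if (iter > max_iter / 2) bland = true;

    vec cB(m);
    for (uword i = 0; i < m; ++i) {
      long bj = basic[i];
      cB(i) = (bj >= (long)N) ? (phase == 1 ? -1.0 : 0.0) : cost((uword)bj);
    }
    vec d = cost - T.t() * cB;           // reduced costs, real variables

    // Entering variable.
    long enter = -1;
    int dir = 0;
    double best = dtol;
    for (uword j = 0; j < N; ++j) {
      if (is_basic[j]) continue;
      bool can_up = xval(j) < vub(j) - 1e-12;
      bool can_dn = xval(j) > vlb(j) + 1e-12;
      double score = 0.0;
      int dj = 0;
      if (can_up && d(j) > dtol) { score = d(j); dj = 1; }
      if (can_dn && -d(j) > std::max(score, dtol)) { score = -d(j); dj = -1; }
      if (dj == 0) continue;
      if (bland) { enter = (long)j; dir = dj; break; }
      if (score > best) { best = score; enter = (long)j; dir = dj; }
    }

    if (enter < 0) {                     // optimal for current phase
      if (phase == 1) {
        double art_sum = 0.0;
        for (uword i = 0; i < m; ++i)
          if (basic[i] >= (long)N) art_sum += xB(i);
        if (art_sum > 1e-7) { res.status = LP_INFEASIBLE; return res; }
        // Drive residual artificials out of the basis (degenerate pivots).
        for (uword i = 0; i < m; ++i) {
          if (basic[i] < (long)N) continue;
          uword jbest = N; double pbest = piv_tol;
          for (uword j = 0; j < N; ++j)
            if (!is_basic[j] && std::abs(T(i, j)) > pbest) {
              pbest = std::abs(T(i, j)); jbest = j;
            }
          if (jbest < N) {
            double piv = T(i, jbest);
            double entv = xval(jbest);
            T.row(i) /= piv;
            vec colj = T.col(jbest);
            for (uword k = 0; k < m; ++k)
              if (k != i && std::abs(colj(k)) > 1e-13)
                T.row(k) -= colj(k) * T.row(i);
            basic[i] = (long)jbest;
            is_basic[jbest] = 1;
            xB(i) = entv;
          }
          // else: zero row; artificial pinned at ~0, harmless.
        }
        phase = 2;
        cost.zeros();
        cost.head(n) = c;
        bland = false;
        iter = 0;
        continue;
      }
      // Phase 2 optimal: assemble solution.
      vec x = xval;
      for (uword i = 0; i < m; ++i)
        if (basic[i] < (long)N) x((uword)basic[i]) = xB(i);
      res.status = LP_OPTIMAL;
      res.x = x.head(n);
      res.objective = dot(c, res.x);
      // Safety: verify feasibility of the returned point on original data.
      vec resid = A0 * res.x - b0;
      for (uword i = 0; i < m; ++i) {
        double viol;
        if (sense(i) < 0) viol = std::max(0.0, resid(i));
        else if (sense(i) > 0) viol = std::max(0.0, -resid(i));
        else viol = std::abs(resid(i));
        if (viol > 1e-5 * std::max(1.0, std::abs(b0(i)))) {
          res.status = LP_INFEASIBLE;
          return res;
        }
      }
      return res;
    }

    // Ratio test.  Step t limited by the entering variable's own span
    // (bound flip) and by each basic variable hitting one of its bounds.
    uword je = (uword)enter;
    vec a = T.col(je);
    double tmax = (dir > 0) ? (vub(je) - xval(je)) : (xval(je) - vlb(je));
    double t = tmax;                     // may be +inf (free variable)
    long leave = -1;
    int leave_to = 0;
    double best_piv = 0.0;
    for (uword i = 0; i < m; ++i) {
      double ai = dir * a(i);
      double ti;
      int lto;
      double blo = var_lb(basic[i]), bhi = var_ub(basic[i]);
      if (ai > piv_tol) {                // basic value decreases
        if (!std::isfinite(blo)) continue;
        ti = (xB(i) - blo) / ai; lto = -1;
      } else if (ai < -piv_tol) {        // basic value increases
        if (!std::isfinite(bhi)) continue;
        ti = (bhi - xB(i)) / (-ai); lto = +1;
      } else continue;
      if (ti < 0) ti = 0;
      if (ti < t - 1e-10) {
        t = ti; leave = (long)i; leave_to = lto; best_piv = std::abs(a(i));
      } else if (leave >= 0 && ti <= t + 1e-10) {
        // Tie: prefer kicking out artificials, then the largest pivot.
        bool cand_art = basic[i] >= (long)N;
        bool curr_art = basic[leave] >= (long)N;
        if ((cand_art && !curr_art) ||
            (cand_art == curr_art && std::abs(a(i)) > best_piv)) {
          leave = (long)i; leave_to = lto; best_piv = std::abs(a(i));
        }
      }
    }

    if (!std::isfinite(t)) {
      res.status = (phase == 1) ? LP_ITERLIMIT : LP_UNBOUNDED;
      return res;
    }

    if (leave < 0) {                     // bound flip, no basis change
      xval(je) += dir * t;
      for (uword i = 0; i < m; ++i) xB(i) -= dir * a(i) * t;
      continue;
    }

    // Pivot: entering je replaces basic[leave].
    uword rp = (uword)leave;
    double entval = xval(je) + dir * t;
    for (uword i = 0; i < m; ++i) if (i != rp) xB(i) -= dir * a(i) * t;
    long lv = basic[rp];
    if (lv < (long)N) {
      is_basic[(uword)lv] = 0;
      xval((uword)lv) = (leave_to < 0) ? vlb((uword)lv) : vub((uword)lv);
    }
    double piv = a(rp);
    T.row(rp) /= piv;
    for (uword i = 0; i < m; ++i)
      if (i != rp && std::abs(a(i)) > 1e-13) T.row(i) -= a(i) * T.row(rp);
    basic[rp] = enter;
    is_basic[je] = 1;
    xB(rp) = entval;
  }
}

struct BnbNode {
  vec lb, ub;
};

// support: for each variable, -1 or the 0-based index of a continuous
// "support" variable; an integer variable with support is an indicator
// that must be 1 whenever its support carries flux, which drives the
// round-and-fix repair heuristic (propose 1 iff support > tol).
// [[Rcpp::export(name = ".solve_milp_cpp")]]
Rcpp::List solve_milp_cpp(const arma::mat& A, const arma::vec& b,
                          const arma::ivec& sense, const arma::vec& c,
                          arma::vec lb, arma::vec ub,
                          const arma::uvec& int_idx,
                          const arma::ivec& support,
                          bool maximize = true,
                          int max_iter = 200000,
                          int max_nodes = 200000,
                          double int_tol = 1e-6,
                          double time_limit = -1.0) {
  vec cc = maximize ? c : vec(-c);
  const uword n = A.n_cols;

  auto wrap_res = [&](int status, double obj, const vec& x,
                      bool flip_obj = true) {
    std::string st;
    switch (status) {
      case LP_OPTIMAL: st = "optimal"; break;
      case LP_INFEASIBLE: st = "infeasible"; break;
      case LP_UNBOUNDED: st = "unbounded"; break;
      case LP_ITERLIMIT: st = "iteration_limit"; break;
      default: st = "time_limit";
    }
    double o = obj;
    if (status == LP_OPTIMAL && !maximize && flip_obj) o = -o;
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("objective") = o,
                              Rcpp::Named("x") = x);
  };

  if (int_idx.n_elem == 0) {
    LpResult r = simplex_solve(A, b, sense, cc, lb, ub, max_iter);
    return wrap_res(r.status, r.objective, r.x);
  }

  // Branch and bound (DFS, most-fractional branching, up-branch first)
  // with a round-and-fix repair heuristic: integer variables are proposed
  // from their support variables (indicators follow flux), fixed, and the
  // LP re-solved; a feasible re-solve yields a verified incumbent.
  std::clock_t t0 = std::clock();
  double incumbent = -INF;
  vec best_x(n, fill::zeros);
  bool have_incumbent = false;
  bool hit_limit = false;
  std::stack<BnbNode> nodes_stack;
  nodes_stack.push(BnbNode{lb, ub});
  int nodes = 0;

  auto try_fix = [&](const BnbNode& nd, const vec& prop) {
    // fix integer vars at proposed values, re-solve, accept if feasible
    vec flb = nd.lb, fub = nd.ub;
    for (uword k = 0; k < int_idx.n_elem; ++k) {
      uword j = int_idx(k);
      double v = prop(j);
      if (v < nd.lb(j) - 0.5 || v > nd.ub(j) + 0.5) return false;
      flb(j) = v; fub(j) = v;
    }
    LpResult rr = simplex_solve(A, b, sense, cc, flb, fub, max_iter);
    if (rr.status != LP_OPTIMAL) return false;
    if (!have_incumbent || rr.objective > incumbent + 1e-9) {
      incumbent = rr.objective;
      best_x = rr.x;
      for (uword k = 0; k < int_idx.n_elem; ++k)
        best_x(int_idx(k)) = std::round(best_x(int_idx(k)));
      have_incumbent = true;
    }
    return true;
  };

  while (!nodes_stack.empty()) {
    if (++nodes > max_nodes) { hit_limit = true; break; }
    if (time_limit > 0 &&
        (double)(std::clock() - t0) / CLOCKS_PER_SEC > time_limit) {
      hit_limit = true; break;
    }
    BnbNode nd = nodes_stack.top(); nodes_stack.pop();
    LpResult r = simplex_solve(A, b, sense, cc, nd.lb, nd.ub, max_iter);
    if (r.status == LP_UNBOUNDED)
      return wrap_res(LP_UNBOUNDED, NA_REAL, vec(n, fill::zeros));
    if (r.status != LP_OPTIMAL) continue;                  // prune
    if (have_incumbent && r.objective <= incumbent + 1e-7) continue;

    long bvar = -1;
    double bfrac = int_tol;
    double any_frac = 0.0;
    long any_var = -1;
    for (uword k = 0; k < int_idx.n_elem; ++k) {
      uword j = int_idx(k);
      double fr = std::abs(r.x(j) - std::round(r.x(j)));
      if (fr > bfrac + 1e-12) { bfrac = fr; bvar = (long)j; }
      if (fr > any_frac + 1e-15) { any_frac = fr; any_var = (long)j; }
    }

    if (bvar < 0) {
      // integral within tolerance: verify by fixing and re-solving
      // (rounding without verification could accept an infeasible point
      // through a loose big-M constraint)
      vec prop = r.x;
      for (uword k = 0; k < int_idx.n_elem; ++k)
        prop(int_idx(k)) = std::round(prop(int_idx(k)));
      if (try_fix(nd, prop)) continue;
      // verification failed: branch on the largest residual fractionality
      if (any_var < 0 || any_frac < 1e-12) continue;       // numerics; drop
      bvar = any_var;
    } else {
      // repair heuristic: indicators follow their support variables
      vec prop = r.x;
      for (uword k = 0; k < int_idx.n_elem; ++k) {
        uword j = int_idx(k);
        long s = support(j);
        if (s >= 0) prop(j) = (r.x((uword)s) > 1e-7) ? 1.0 : 0.0;
        else prop(j) = std::round(prop(j));
      }
      try_fix(nd, prop);
      if (have_incumbent && r.objective <= incumbent + 1e-7) continue;
    }

    uword j = (uword)bvar;
    double v = r.x(j);
    BnbNode down = nd, up = nd;
    down.ub(j) = std::floor(v);
    up.lb(j) = std::ceil(v);
    if (down.ub(j) < nd.lb(j) - 0.5 || up.lb(j) > nd.ub(j) + 0.5) continue;
    nodes_stack.push(down);
    nodes_stack.push(up);                 // explored first
  }

  if (!have_incumbent) {
    if (hit_limit)
      return Rcpp::List::create(Rcpp::Named("status") = "time_limit",
                                Rcpp::Named("objective") = NA_REAL,
                                Rcpp::Named("x") = vec(n, fill::zeros));
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = vec(n, fill::zeros));
  }
  double obj = maximize ? incumbent : -incumbent;
  std::string st = hit_limit ? "time_limit" : "optimal";
  return Rcpp::List::create(Rcpp::Named("status") = st,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = best_x);
}
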