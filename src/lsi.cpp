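// Inequality-constrained least squares min ||G w - b||_2 s.t. C w <= d,
// via the classical reduction chain LSI -> LDP -> NNLS (Lawson & Hanson).
// The NNLS runs on the Gram matrix with Cholesky solves, which keeps the
// many nearly collinear collocation constraints cheap and stable.
// Columns of G are normalised to unit length before solving so basis
// terms of very different scales are treated evenly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve Q_PP z_P = h_P for the passive set via Cholesky, adding a tiny
// ridge if the submatrix is numerically singular.
static bool chol_solve(const mat &Q, const vec &h, const uvec &P, vec &z) {
  mat Qpp = Q.submat(P, P);
  vec hp = h.elem(P);
  mat Rc;
  if (!chol(Rc, Qpp)) {
    Qpp.diag() += 1e-12 * (trace(Qpp) / Qpp.n_rows + 1e-300);
    if (!chol(Rc, Qpp)) return false;
  }
  z = solve(trimatu(Rc), solve(trimatl(Rc.t()), hp, solve_opts::fast), solve_opts::fast);
  return true;
}

// NNLS in Gram form: minimise ||A u - f|| with u >= 0, given Q = A'A and
// h = A'f.  Returns u.
static vec nnls_gram(const mat &Q, const vec &h, int maxit) {
  const int m = Q.n_rows;
  vec u(m, fill::zeros);
  std::vector<bool> passive(m, false);
  const double tol = 1e-12 * std::max(1.0, Q.diag().max());
  vec grad = h;
  int outer = 0;
  while (outer++ < maxit) {
    int t = -1;
    double gmax = tol;
    for (int j = 0; j < m; ++j)
      if (!passive[j] && grad[j] > gmax) { gmax = grad[j]; t = j; }
    if (t < 0) break;
    passive[t] = true;
    for (int inner = 0; inner < maxit; ++inner) {
      std::vector<uword> pid;
      for (int j = 0; j < m; ++j)
        if (passive[j]) pid.push_back(j);
      if (pid.empty()) break;
      uvec P(pid);
      vec zp;
      if (!chol_solve(Q, h, P, zp)) { passive[t] = false; return u; }
      vec z(m, fill::zeros);
      for (uword k = 0; k < P.n_elem; ++k) z[P[k]] = zp[k];
      const double ztol = 1e-12 * std::max(1.0, abs(zp).max());
      bool ok = true;
      for (uword k = 0; k < P.n_elem; ++k)
        if (zp[k] <= ztol) { ok = false; break; }
      if (ok) { u = z; break; }
      double alpha = datum::inf;
      for (int j = 0; j < m; ++j)
        if (passive[j] && z[j] <= ztol) {
          const double a = u[j] / (u[j] - z[j]);
          if (a < alpha) alpha = a;
        }
      if (!std::isfinite(alpha)) alpha = 0.0;
      u += alpha * (z - u);
      for (int j = 0; j < m; ++j)
        if (passive[j] && u[j] <= ztol) { passive[j] = false; u[j] = 0.0; }
    }
    grad = h - Q * u;
  }
  return u;
}

// [[Rcpp::export]]
arma::vec cpp_nnls(const arma::mat &A, const arma::vec &b) {
  return nnls_gram(A.t() * A, A.t() * b, 10 * (int)A.n_cols + 200);
}

// Primal active-set quadratic programming fallback:
// min ||Ga w - ba||^2  s.t.  C w <= d  (d >= 0 so w = 0 is feasible).
// Used when the least-distance route loses feasibility on degenerate
// constraint geometry.
static bool asqp(const mat &Ga, const vec &ba, const mat &C, const vec &d,
                 vec &w, int maxit) {
  const int n = Ga.n_cols, mc = C.n_rows;
  mat Q = Ga.t() * Ga;
  vec cvec = Ga.t() * ba;
  w.zeros(n);
  std::vector<int> W;           // working set (constraint rows)
  for (int it = 0; it < maxit; ++it) {
    const int k = W.size();
    mat K(n + k, n + k, fill::zeros);
    K.submat(0, 0, n - 1, n - 1) = Q;
    for (int a = 0; a < k; ++a) {
      K.submat(n + a, 0, n + a, n - 1) = C.row(W[a]);
      K.submat(0, n + a, n - 1, n + a) = C.row(W[a]).t();
    }
    vec rhs(n + k, fill::zeros);
    rhs.subvec(0, n - 1) = cvec - Q * w;
    for (int a = 0; a < k; ++a) rhs[n + a] = d[W[a]] - dot(C.row(W[a]), w);
    vec sol;
    bool ok_solve = solve(sol, K, rhs, solve_opts::fast + solve_opts::no_approx);
    if (!ok_solve && !solve(sol, K, rhs, solve_opts::force_approx)) return false;
    vec p = sol.subvec(0, n - 1);
    const double pn = norm(p);
    if (pn <= 1e-11 * (1.0 + norm(w))) {
      // stationary on the working set: check multipliers
      if (k == 0) return true;
      int drop = -1;
      double lmin = -1e-9;
      for (int a = 0; a < k; ++a) {
        const double lambda = -sol[n + a];
        if (lambda < lmin) { lmin = lambda; drop = a; }
      }
      if (drop < 0) return true;
      W.erase(W.begin() + drop);
      continue;
    }
    // longest feasible step along p
    double alpha = 1.0;
    int block = -1;
    for (int j = 0; j < mc; ++j) {
      if (std::find(W.begin(), W.end(), j) != W.end()) continue;
      const double cp = dot(C.row(j), p);
      if (cp > 1e-13 * (1.0 + pn)) {
        const double a_j = (d[j] - dot(C.row(j), w)) / cp;
        if (a_j < alpha) { alpha = a_j; block = j; }
      }
    }
    if (alpha < 0) alpha = 0;
    w += alpha * p;
    if (block >= 0) W.push_back(block);
    else if (alpha >= 1.0) continue;
  }
  return true;   // iteration cap: return best feasible iterate
}

// [[Rcpp::export]]
Rcpp::List cpp_lsi(const arma::mat &G, const arma::vec &b,
                   const arma::mat &C, const arma::vec &d) {
  const int n = G.n_cols;
  if (n == 0)
    return Rcpp::List::create(Rcpp::Named("w") = vec(),
                              Rcpp::Named("feasible") = true,
                              Rcpp::Named("constrained") = false);
  vec s(n);
  for (int j = 0; j < n; ++j) {
    s[j] = norm(G.col(j));
    if (s[j] == 0.0) s[j] = 1.0;
  }
  mat Gn = G;
  Gn.each_row() /= s.t();
  mat Cn;
  if (C.n_rows) {
    Cn = C;
    Cn.each_row() /= s.t();
  } else {
    Cn.set_size(0, n);
  }

  mat Q, R;
  if (!qr_econ(Q, R, Gn)) Rcpp::stop("QR factorisation failed");
  const double dmax = abs(R.diag()).max();
  if ((int)Gn.n_rows < n) {
    // underdetermined system: degenerate geometry defeats the
    // least-distance reduction, so run the primal active-set program on
    // a ridge-stabilised system (the ridge distortion is far below the
    // downstream thresholding scale)
    mat Ga = join_cols(Gn, 1e-4 * std::max(dmax, 1.0) * eye(n, n));
    vec ba = join_cols(b, vec(n, fill::zeros));
    vec w_ls = solve(Ga.t() * Ga, Ga.t() * ba, solve_opts::likely_sympd);
    bool ok = true;
    if (Cn.n_rows) ok = vec(Cn * w_ls - d).max() <= 1e-10;
    if (ok)
      return Rcpp::List::create(Rcpp::Named("w") = vec(w_ls / s),
                                Rcpp::Named("feasible") = true,
                                Rcpp::Named("constrained") = false);
    vec w;
    if (!asqp(Ga, ba, Cn, d, w, 800))
      Rcpp::stop("constrained least-squares solve failed");
    return Rcpp::List::create(Rcpp::Named("w") = vec(w / s),
                              Rcpp::Named("feasible") = true,
                              Rcpp::Named("constrained") = true);
  }
  if (abs(R.diag()).min() < 1e-12 * dmax) {
    // near rank-deficient: stabilise with a tiny ridge before factoring
    mat Ga = join_cols(Gn, 1e-8 * dmax * eye(n, n));
    vec ba = join_cols(b, vec(n, fill::zeros));
    if (!qr_econ(Q, R, Ga)) Rcpp::stop("QR factorisation failed");
    vec Qtb = Q.t() * ba;
    vec w_ls = solve(trimatu(R), Qtb, solve_opts::fast);
    bool ok = true;
    if (Cn.n_rows) {
      vec cw = Cn * w_ls;
      ok = vec(cw - d).max() <= 1e-9 * std::max(1.0, norm(w_ls));
    }
    if (ok)
      return Rcpp::List::create(Rcpp::Named("w") = vec(w_ls / s),
                                Rcpp::Named("feasible") = true,
                                Rcpp::Named("constrained") = false);
    mat Rinv = solve(trimatu(R), eye(n, n), solve_opts::fast);
    mat T = Cn * Rinv;
    vec h = T * Qtb - d;
    mat Qg = T * T.t() + h * h.t();
    vec u = nnls_gram(Qg, h, 10 * (int)Cn.n_rows + 200);
    const double rlast = dot(h, u) - 1.0;
    if (std::abs(rlast) < 1e-12)
      Rcpp::stop("constrained least-squares subproblem is infeasible");
    vec z = (T.t() * u) / rlast;
    vec w = Rinv * (z + Qtb);
    return Rcpp::List::create(Rcpp::Named("w") = vec(w / s),
                              Rcpp::Named("feasible") = true,
                              Rcpp::Named("constrained") = true);
  }

  vec Qtb = Q.t() * b;
  vec w_ls = solve(trimatu(R), Qtb, solve_opts::fast);
  bool ok = true;
  if (Cn.n_rows) {
    vec cw = Cn * w_ls;
    ok = vec(cw - d).max() <= 1e-11 * (1.0 + abs(cw).max());
  }
  if (ok)
    return Rcpp::List::create(Rcpp::Named("w") = vec(w_ls / s),
                              Rcpp::Named("feasible") = true,
                              Rcpp::Named("constrained") = false);

  // LDP: with w = Rinv (z + Q'b), the constraint C w <= d becomes
  // H z >= h with H = -C Rinv and h = C Rinv Q'b - d; solve by NNLS on
  // the Gram matrix H H' + h h'.
  mat Rinv = solve(trimatu(R), eye(n, n), solve_opts::fast);
  mat T = Cn * Rinv;
  vec h = T * Qtb - d;
  mat Qg = T * T.t() + h * h.t();
  vec u = nnls_gram(Qg, h, 10 * (int)Cn.n_rows + 200);
  // residual of the NNLS system: r_(1:n) = -T' u, r_last = h'u - 1
  const double rlast = dot(h, u) - 1.0;
  if (std::abs(rlast) < 1e-12)
    Rcpp::stop("constrained least-squares subproblem is infeasible");
  vec z = (T.t() * u) / rlast;   // z = -r_(1:n) / r_last
  vec w = Rinv * (z + Qtb);
  return Rcpp::List::create(Rcpp::Named("w") = vec(w / s),
                            Rcpp::Named("feasible") = true,
                            Rcpp::Named("constrained") = true);
}

// Direct primal active-set solve of min ||G w - b|| s.t. C w <= d;
// every iterate is feasible, so the result honours the constraints even
// if stopped early.  Used to repair the final model of a thresholding
// run when the fast least-distance route has lost feasibility.
// [[Rcpp::export]]
arma::vec cpp_asqp(const arma::mat &G, const arma::vec &b,
                   const arma::mat &C, const arma::vec &d) {
  const int n = G.n_cols;
  vec s(n);
  for (int j = 0; j < n; ++j) {
    s[j] = norm(G.col(j));
    if (s[j] == 0.0) s[j] = 1.0;
  }
  mat Gn = G;
  Gn.each_row() /= s.t();
  mat Cn;
  if (C.n_rows) {
    Cn = C;
    Cn.each_row() /= s.t();
  } else {
    Cn.set_size(0, n);
  }
  mat Ga = join_cols(Gn, 1e-6 * eye(n, n));
  vec ba = join_cols(b, vec(n, fill::zeros));
  vec w;
  if (!asqp(Ga, ba, Cn, d, w, 1000))
    Rcpp::stop("active-set solve failed");
  return w / s;
}
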