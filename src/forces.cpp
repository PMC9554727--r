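// Numerical cores: ground-truth and library-model particle simulators,
// per-focal-cell library evaluation, data-driven validation simulations,
// and pairwise-statistics accumulators.  All pair sums follow the
// second-order directional interaction model
//   xdd_i = (1/Ntot) sum_j f_ar(r_ij, th_ij) (x_i - x_j)
//         + (1/Ntot) sum_j f_align(r_ij, th_ij) (v_i - v_j)
//         + (1/Ntot) sum_j f_drag(|v_i|, th_ij) v_i
// with th_ij the angle between v_i and x_j - x_i.  When |v_i| falls
// below eps_v the directional factors cos(n th) for n >= 1 are taken
// to be 0 (no direction is defined; only isotropic modes act).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double R_COINCIDENT = 1e-14;

// Laguerre polynomials L_0..L_maxdeg at x by the three-term recurrence.
static inline void laguerre_all(double x, int maxdeg, double *p) {
  p[0] = 1.0;
  if (maxdeg >= 1) p[1] = 1.0 - x;
  for (int k = 1; k < maxdeg; ++k)
    p[k + 1] = ((2.0 * k + 1.0 - x) * p[k] - k * p[k - 1]) / (k + 1.0);
}

// cos(theta) and cos(2 theta) for velocity v and displacement x_j - x_i,
// applying the degenerate-speed convention.
static inline void dir_factors(double vx, double vy, double s,
                               double dx, double dy, double r,
                               double eps_v, double &c1, double &c2) {
  if (s < eps_v || r < R_COINCIDENT) { c1 = 0.0; c2 = 0.0; return; }
  c1 = (vx * dx + vy * dy) / (s * r);
  if (c1 > 1.0) c1 = 1.0; else if (c1 < -1.0) c1 = -1.0;
  c2 = 2.0 * c1 * c1 - 1.0;
}

// ---------------------------------------------------------------------------
// Ground-truth forces (benchmark species)
// ---------------------------------------------------------------------------

static inline double f_ar_true(double r, double c2) {
  return (15.0 + 10.0 * c2) * (std::exp(-20.0 * r) - 0.25 * std::exp(-10.0 * r));
}
static inline double f_align_true(double r, double c1) {
  return -(8.0 + 8.0 * c1) * std::exp(-8.0 * r);
}
static inline double f_drag_true(double s) { return -5.0 * s; }

// Accelerations under the ground-truth forces; flags switch each force
// per cell.  Errors on exactly coincident distinct cells.
static void true_accel(const vec &x, const vec &y, const vec &vx, const vec &vy,
                       const ivec &har, const ivec &hal, const ivec &hdr,
                       double eps_v, vec &ax, vec &ay) {
  const int N = x.n_elem;
  ax.zeros(N); ay.zeros(N);
  for (int i = 0; i < N; ++i) {
    const double vxi = vx[i], vyi = vy[i];
    const double s = std::sqrt(vxi * vxi + vyi * vyi);
    double axi = 0.0, ayi = 0.0;
    const bool ar = har[i] != 0, al = hal[i] != 0;
    if (ar || al) {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        const double dx = x[j] - x[i], dy = y[j] - y[i];
        const double r = std::sqrt(dx * dx + dy * dy);
        if (r < R_COINCIDENT)
          Rcpp::stop("coincident cells %d and %d (r = 0): volume exclusion violated",
                     i + 1, j + 1);
        double c1, c2;
        dir_factors(vxi, vyi, s, dx, dy, r, eps_v, c1, c2);
        if (ar) {
          const double f = f_ar_true(r, c2);
          axi -= f * dx; ayi -= f * dy;      // times (x_i - x_j)
        }
        if (al) {
          const double f = f_align_true(r, c1);
          axi += f * (vxi - vx[j]); ayi += f * (vyi - vy[j]);
        }
      }
    }
    if (hdr[i] != 0) {
      // isotropic drag: sum over j != i collapses to (N - 1) f(s) v_i
      const double f = f_drag_true(s) * (N - 1.0);
      axi += f * vxi; ayi += f * vyi;
    }
    ax[i] = axi / N; ay[i] = ayi / N;
  }
}

// [[Rcpp::export]]
arma::mat cpp_true_accel(const arma::vec &x, const arma::vec &y,
                         const arma::vec &vx, const arma::vec &vy,
                         const arma::ivec &har, const arma::ivec &hal,
                         const arma::ivec &hdr, double eps_v) {
  vec ax, ay;
  true_accel(x, y, vx, vy, har, hal, hdr, eps_v, ax, ay);
  mat out(x.n_elem, 2);
  out.col(0) = ax; out.col(1) = ay;
  return out;
}

// RK4 on the coupled (x, v) system, recording every coarse frame.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_true(const arma::vec &x0, const arma::vec &y0,
                             const arma::vec &vx0, const arma::vec &vy0,
                             const arma::ivec &har, const arma::ivec &hal,
                             const arma::ivec &hdr, int L, double dt,
                             int substeps, double blow_bound, double eps_v) {
  const int N = x0.n_elem;
  mat PX(L, N), PY(L, N), VX(L, N), VY(L, N);
  vec x = x0, y = y0, vx = vx0, vy = vy0;
  vec ax, ay, k1x, k1y, k2x, k2y, k3x, k3y;
  const double h = dt / substeps;

  auto record = [&](int k) {
    PX.row(k) = x.t(); PY.row(k) = y.t();
    VX.row(k) = vx.t(); VY.row(k) = vy.t();
  };
  auto check_blow = [&](int k) {
    for (int i = 0; i < N; ++i) {
      const double nrm = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      if (!std::isfinite(nrm) || nrm > blow_bound)
        Rcpp::stop("simulation blow-up: cell %d exceeded bound %g at t = %g",
                   i + 1, blow_bound, k * dt);
    }
  };

  record(0);
  for (int k = 1; k < L; ++k) {
    for (int s = 0; s < substeps; ++s) {
      // classic RK4 with state (x, v), dx/dt = v, dv/dt = a(x, v)
      vec ax1, ay1, ax2, ay2, ax3, ay3, ax4, ay4;
      true_accel(x, y, vx, vy, har, hal, hdr, eps_v, ax1, ay1);
      vec x2 = x + 0.5 * h * vx,               y2 = y + 0.5 * h * vy;
      vec vx2 = vx + 0.5 * h * ax1,            vy2 = vy + 0.5 * h * ay1;
      true_accel(x2, y2, vx2, vy2, har, hal, hdr, eps_v, ax2, ay2);
      vec x3 = x + 0.5 * h * vx2,              y3 = y + 0.5 * h * vy2;
      vec vx3 = vx + 0.5 * h * ax2,            vy3 = vy + 0.5 * h * ay2;
      true_accel(x3, y3, vx3, vy3, har, hal, hdr, eps_v, ax3, ay3);
      vec x4 = x + h * vx3,                    y4 = y + h * vy3;
      vec vx4 = vx + h * ax3,                  vy4 = vy + h * ay3;
      true_accel(x4, y4, vx4, vy4, har, hal, hdr, eps_v, ax4, ay4);
      x  += (h / 6.0) * (vx + 2.0 * vx2 + 2.0 * vx3 + vx4);
      y  += (h / 6.0) * (vy + 2.0 * vy2 + 2.0 * vy3 + vy4);
      vx += (h / 6.0) * (ax1 + 2.0 * ax2 + 2.0 * ax3 + ax4);
      vy += (h / 6.0) * (ay1 + 2.0 * ay2 + 2.0 * ay3 + ay4);
    }
    check_blow(k);
    record(k);
  }
  return Rcpp::List::create(Rcpp::Named("px") = PX, Rcpp::Named("py") = PY,
                            Rcpp::Named("vx") = VX, Rcpp::Named("vy") = VY);
}

// ---------------------------------------------------------------------------
// Library-model forces (arbitrary coefficient vectors over the basis)
// ---------------------------------------------------------------------------

// Per-cell decomposition of a coefficient vector into per-block term lists.
struct ModelTerms {
  std::vector<int> ar_n, ar_l; std::vector<double> ar_w;
  std::vector<int> al_n, al_l; std::vector<double> al_w;
  std::vector<int> dr_n, dr_l; std::vector<double> dr_w;
  int max_ar_l = -1;
  bool any() const { return !ar_w.empty() || !al_w.empty() || !dr_w.empty(); }
};

static ModelTerms split_terms(const vec &w, const imat &terms) {
  ModelTerms m;
  for (uword j = 0; j < w.n_elem; ++j) {
    if (w[j] == 0.0) continue;
    const int blk = terms(j, 0), n = terms(j, 1), l = terms(j, 2);
    if (blk == 0) { m.ar_n.push_back(n); m.ar_l.push_back(l); m.ar_w.push_back(w[j]);
                    if (l > m.max_ar_l) m.max_ar_l = l; }
    else if (blk == 1) { m.al_n.push_back(n); m.al_l.push_back(l); m.al_w.push_back(w[j]); }
    else { m.dr_n.push_back(n); m.dr_l.push_back(l); m.dr_w.push_back(w[j]); }
  }
  return m;
}

// Accelerations with per-cell models evaluated exactly over the basis.
static void model_accel(const vec &x, const vec &y, const vec &vx, const vec &vy,
                        const std::vector<ModelTerms> &models, double alpha,
                        double eps_v, vec &ax, vec &ay) {
  const int N = x.n_elem;
  ax.zeros(N); ay.zeros(N);
  double lag[32];
  for (int i = 0; i < N; ++i) {
    const ModelTerms &m = models[i];
    if (!m.any()) continue;
    const double vxi = vx[i], vyi = vy[i];
    const double s = std::sqrt(vxi * vxi + vyi * vyi);
    double spow[5];
    if (!m.dr_w.empty()) {
      spow[0] = 1.0;
      for (int k = 1; k < 5; ++k) spow[k] = spow[k - 1] * s;
    }
    double axi = 0.0, ayi = 0.0, dragsum = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double r = std::sqrt(dx * dx + dy * dy);
      if (r < R_COINCIDENT)
        Rcpp::stop("coincident cells %d and %d (r = 0)", i + 1, j + 1);
      double c1, c2;
      dir_factors(vxi, vyi, s, dx, dy, r, eps_v, c1, c2);
      const double cn[3] = {1.0, c1, c2};
      if (!m.ar_w.empty()) {
        laguerre_all(alpha * r, m.max_ar_l, lag);
        const double E = std::exp(-0.5 * alpha * r);
        double f = 0.0;
        for (size_t t = 0; t < m.ar_w.size(); ++t)
          f += m.ar_w[t] * cn[m.ar_n[t]] * lag[m.ar_l[t]] * E;
        axi -= f * dx; ayi -= f * dy;
      }
      if (!m.al_w.empty()) {
        double f = 0.0;
        for (size_t t = 0; t < m.al_w.size(); ++t)
          f += m.al_w[t] * (1.0 + cn[m.al_n[t]]) * std::exp(-2.0 * m.al_l[t] * r);
        axi += f * (vxi - vx[j]); ayi += f * (vyi - vy[j]);
      }
      if (!m.dr_w.empty()) {
        double f = 0.0;
        for (size_t t = 0; t < m.dr_w.size(); ++t)
          f += m.dr_w[t] * (1.0 + cn[m.dr_n[t]]) * spow[m.dr_l[t]];
        dragsum += f;
      }
    }
    ax[i] = (axi + dragsum * vxi) / N;
    ay[i] = (ayi + dragsum * vyi) / N;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate_model(const arma::vec &x0, const arma::vec &y0,
                              const arma::vec &vx0, const arma::vec &vy0,
                              const arma::mat &W, const arma::imat &terms,
                              double alpha, int L, double dt, int substeps,
                              double blow_bound, double eps_v) {
  const int N = x0.n_elem;
  if ((int)W.n_cols != N) Rcpp::stop("W must have one column per cell");
  std::vector<ModelTerms> models(N);
  for (int i = 0; i < N; ++i) models[i] = split_terms(W.col(i), terms);

  mat PX(L, N), PY(L, N), VX(L, N), VY(L, N);
  vec x = x0, y = y0, vx = vx0, vy = vy0;
  const double h = dt / substeps;
  PX.row(0) = x.t(); PY.row(0) = y.t(); VX.row(0) = vx.t(); VY.row(0) = vy.t();
  for (int k = 1; k < L; ++k) {
    for (int s = 0; s < substeps; ++s) {
      vec ax1, ay1, ax2, ay2, ax3, ay3, ax4, ay4;
      model_accel(x, y, vx, vy, models, alpha, eps_v, ax1, ay1);
      vec x2 = x + 0.5 * h * vx,    y2 = y + 0.5 * h * vy;
      vec vx2 = vx + 0.5 * h * ax1, vy2 = vy + 0.5 * h * ay1;
      model_accel(x2, y2, vx2, vy2, models, alpha, eps_v, ax2, ay2);
      vec x3 = x + 0.5 * h * vx2,   y3 = y + 0.5 * h * vy2;
      vec vx3 = vx + 0.5 * h * ax2, vy3 = vy + 0.5 * h * ay2;
      model_accel(x3, y3, vx3, vy3, models, alpha, eps_v, ax3, ay3);
      vec x4 = x + h * vx3,         y4 = y + h * vy3;
      vec vx4 = vx + h * ax3,       vy4 = vy + h * ay3;
      model_accel(x4, y4, vx4, vy4, models, alpha, eps_v, ax4, ay4);
      x  += (h / 6.0) * (vx + 2.0 * vx2 + 2.0 * vx3 + vx4);
      y  += (h / 6.0) * (vy + 2.0 * vy2 + 2.0 * vy3 + vy4);
      vx += (h / 6.0) * (ax1 + 2.0 * ax2 + 2.0 * ax3 + ax4);
      vy += (h / 6.0) * (ay1 + 2.0 * ay2 + 2.0 * ay3 + ay4);
    }
    for (int i = 0; i < N; ++i) {
      const double nrm = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      if (!std::isfinite(nrm) || nrm > blow_bound)
        Rcpp::stop("simulation blow-up: cell %d exceeded bound %g at t = %g",
                   i + 1, blow_bound, k * dt);
    }
    PX.row(k) = x.t(); PY.row(k) = y.t(); VX.row(k) = vx.t(); VY.row(k) = vy.t();
  }
  return Rcpp::List::create(Rcpp::Named("px") = PX, Rcpp::Named("py") = PY,
                            Rcpp::Named("vx") = VX, Rcpp::Named("vy") = VY);
}

// ---------------------------------------------------------------------------
// Library evaluation for one focal cell
// ---------------------------------------------------------------------------

// Theta is (2L x J): rows 0..L-1 hold the x coordinate, rows L..2L-1 the y
// coordinate of each basis force summed over neighbours (divided by Ntot).
// [[Rcpp::export]]
arma::mat cpp_eval_library(const arma::mat &PX, const arma::mat &PY,
                           const arma::mat &VX, const arma::mat &VY,
                           int focal, const arma::imat &terms, double alpha,
                           double eps_v) {
  const int L = PX.n_rows, N = PX.n_cols, J = terms.n_rows;
  const int i = focal;
  if (i < 0 || i >= N) Rcpp::stop("focal cell index out of range");

  // column lookup per block
  int idx_ar[3][18], idx_al[3][8], idx_dr[2][5], max_ar_l = -1;
  for (auto &row : idx_ar) std::fill(row, row + 18, -1);
  for (auto &row : idx_al) std::fill(row, row + 8, -1);
  for (auto &row : idx_dr) std::fill(row, row + 5, -1);
  for (int j = 0; j < J; ++j) {
    const int blk = terms(j, 0), n = terms(j, 1), l = terms(j, 2);
    if (blk == 0) { idx_ar[n][l] = j; if (l > max_ar_l) max_ar_l = l; }
    else if (blk == 1) idx_al[n][l + 2] = j;
    else idx_dr[n][l] = j;
  }

  mat Theta(2 * L, J, fill::zeros);
  double lag[32];
  for (int k = 0; k < L; ++k) {
    const double xi = PX(k, i), yi = PY(k, i);
    const double vxi = VX(k, i), vyi = VY(k, i);
    const double s = std::sqrt(vxi * vxi + vyi * vyi);
    double A0 = 0.0, A1 = 0.0;  // drag angular sums
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const double dx = PX(k, j) - xi, dy = PY(k, j) - yi;
      const double r = std::sqrt(dx * dx + dy * dy);
      if (r < R_COINCIDENT)
        Rcpp::stop("coincident cells %d and %d at frame %d", i + 1, j + 1, k + 1);
      double c1, c2;
      dir_factors(vxi, vyi, s, dx, dy, r, eps_v, c1, c2);
      const double cn[3] = {1.0, c1, c2};

      if (max_ar_l >= 0) {
        laguerre_all(alpha * r, max_ar_l, lag);
        const double E = std::exp(-0.5 * alpha * r);
        for (int n = 0; n < 3; ++n) {
          const double cE = cn[n] * E;
          if (cE == 0.0 && n > 0) continue;
          for (int l = 0; l <= max_ar_l; ++l) {
            const int col = idx_ar[n][l];
            if (col < 0) continue;
            const double v = cE * lag[l];
            Theta(k, col) -= v * dx;        // (x_i - x_j) = -disp
            Theta(L + k, col) -= v * dy;
          }
        }
      }
      {
        const double dvx = vxi - VX(k, j), dvy = vyi - VY(k, j);
        const double u = std::exp(-2.0 * r);
        double upow = 1.0 / (u * u);        // e^{+4r}, i.e. ell = -2
        for (int le = 0; le < 8; ++le) {    // ell = -2..5
          for (int n = 0; n < 3; ++n) {
            const int col = idx_al[n][le];
            if (col < 0) continue;
            const double v = (1.0 + cn[n]) * upow;
            Theta(k, col) += v * dvx;
            Theta(L + k, col) += v * dvy;
          }
          upow *= u;
        }
      }
      A0 += 2.0;
      A1 += 1.0 + c1;
    }
    // drag columns: f(s, th) v_i summed over neighbours
    double spow = 1.0;
    for (int l = 0; l < 5; ++l) {
      const double base = spow;
      for (int n = 0; n < 2; ++n) {
        const int col = idx_dr[n][l];
        if (col < 0) continue;
        const double A = (n == 0) ? A0 : A1;
        Theta(k, col) += A * base * vxi;
        Theta(L + k, col) += A * base * vyi;
      }
      spow *= s;
    }
  }
  Theta /= (double)N;
  return Theta;
}

// ---------------------------------------------------------------------------
// Data-driven validation simulations
// ---------------------------------------------------------------------------

// One forward-Euler simulation of cell `i` under tabulated mode profiles,
// with neighbours replayed from interpolated data.  Returns the relative
// squared-velocity error over the coarse comparison frames; +Inf on blow-up.
static double validate_one(int i, const mat &FX, const mat &FY,
                           const mat &FVX, const mat &FVY,
                           const mat &DVX, const mat &DVY,
                           const mat &AR, const mat &AL, const mat &DR,
                           bool has_ar, bool has_al, bool has_dr,
                           double dr_r, double dr_s, double h, int nsub,
                           int Lp, int Ntot, double eps_v, double blow_bound,
                           vec *out_px, vec *out_py, vec *out_vx, vec *out_vy) {
  const int N = FX.n_cols;
  const int nr = AR.n_rows, ns = DR.n_rows;
  double x = FX(0, i), y = FY(0, i), vx = FVX(0, i), vy = FVY(0, i);
  double err = 0.0, den = 0.0;
  auto lerp = [](const mat &P, int col, double pos, int nrow) {
    if (pos <= 0.0) return P(0, col);
    if (pos >= nrow - 1.0) return P(nrow - 1, col);
    const int i0 = (int)pos;
    const double f = pos - i0;
    return P(i0, col) * (1.0 - f) + P(i0 + 1, col) * f;
  };
  int t = 0;
  for (int k = 0; k < Lp; ++k) {
    // record / accumulate error at coarse frame k
    const double ex = vx - DVX(k, i), ey = vy - DVY(k, i);
    err += ex * ex + ey * ey;
    den += DVX(k, i) * DVX(k, i) + DVY(k, i) * DVY(k, i);
    if (out_px) { (*out_px)[k] = x; (*out_py)[k] = y; (*out_vx)[k] = vx; (*out_vy)[k] = vy; }
    if (k == Lp - 1) break;
    for (int s = 0; s < nsub; ++s, ++t) {
      const double sp = std::sqrt(vx * vx + vy * vy);
      double axi = 0.0, ayi = 0.0, dragsum = 0.0;
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        const double dx = FX(t, j) - x, dy = FY(t, j) - y;
        const double r = std::sqrt(dx * dx + dy * dy);
        double c1, c2;
        dir_factors(vx, vy, sp, dx, dy, r, eps_v, c1, c2);
        if (has_ar && r >= R_COINCIDENT) {
          const double pos = r / dr_r;
          const double f = lerp(AR, 0, pos, nr) + c1 * lerp(AR, 1, pos, nr)
                         + c2 * lerp(AR, 2, pos, nr);
          axi -= f * dx; ayi -= f * dy;
        }
        if (has_al) {
          const double pos = r / dr_r;
          const double f = lerp(AL, 0, pos, nr) + c1 * lerp(AL, 1, pos, nr)
                         + c2 * lerp(AL, 2, pos, nr);
          axi += f * (vx - FVX(t, j)); ayi += f * (vy - FVY(t, j));
        }
        if (has_dr) {
          const double pos = sp / dr_s;
          dragsum += lerp(DR, 0, pos, ns) + c1 * lerp(DR, 1, pos, ns);
        }
      }
      const double ax = (axi + dragsum * vx) / Ntot;
      const double ay = (ayi + dragsum * vy) / Ntot;
      const double xn = x + h * vx, yn = y + h * vy;   // Euler: x uses old v
      vx += h * ax; vy += h * ay;
      x = xn; y = yn;
      if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(vx) ||
          !std::isfinite(vy) || std::sqrt(x * x + y * y) > blow_bound)
        return datum::inf;
    }
  }
  if (den == 0.0) Rcpp::stop("all data velocities are zero on the validation window");
  return err / den;
}

// Batched validation: tasks is a 2-column matrix (profile index, cell index),
// both 0-based.  Profiles are cubes with one slice per candidate model:
// AR/AL (nr x 3) radial mode profiles, DR (ns x 2) speed mode profiles,
// tabulated on uniform grids [0, r_hi] and [0, s_hi].
// [[Rcpp::export]]
arma::vec cpp_validate_batch(const arma::imat &tasks,
                             const arma::mat &FX, const arma::mat &FY,
                             const arma::mat &FVX, const arma::mat &FVY,
                             const arma::mat &DVX, const arma::mat &DVY,
                             const arma::cube &AR, const arma::cube &AL,
                             const arma::cube &DR, double r_hi, double s_hi,
                             double h, int nsub, int Lp, int Ntot,
                             double eps_v, double blow_bound) {
  const int T = tasks.n_rows;
  vec dv(T);
  const double dr_r = r_hi / (AR.n_rows - 1.0);
  const double dr_s = s_hi / (DR.n_rows - 1.0);
  for (int tix = 0; tix < T; ++tix) {
    const int p = tasks(tix, 0), i = tasks(tix, 1);
    const mat &ARp = AR.slice(p), &ALp = AL.slice(p), &DRp = DR.slice(p);
    const bool has_ar = any(vectorise(ARp) != 0.0);
    const bool has_al = any(vectorise(ALp) != 0.0);
    const bool has_dr = any(vectorise(DRp) != 0.0);
    dv[tix] = validate_one(i, FX, FY, FVX, FVY, DVX, DVY, ARp, ALp, DRp,
                           has_ar, has_al, has_dr, dr_r, dr_s, h, nsub, Lp,
                           Ntot, eps_v, blow_bound,
                           nullptr, nullptr, nullptr, nullptr);
    if (tix % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return dv;
}

// Single validation simulation returning the simulated coarse trajectory.
// [[Rcpp::export]]
Rcpp::List cpp_validate_single(int cell,
                               const arma::mat &FX, const arma::mat &FY,
                               const arma::mat &FVX, const arma::mat &FVY,
                               const arma::mat &DVX, const arma::mat &DVY,
                               const arma::mat &AR, const arma::mat &AL,
                               const arma::mat &DR, double r_hi, double s_hi,
                               double h, int nsub, int Lp, int Ntot,
                               double eps_v, double blow_bound) {
  vec px(Lp), py(Lp), vx(Lp), vy(Lp);
  const double dr_r = r_hi / (AR.n_rows - 1.0);
  const double dr_s = s_hi / (DR.n_rows - 1.0);
  const bool has_ar = any(vectorise(AR) != 0.0);
  const bool has_al = any(vectorise(AL) != 0.0);
  const bool has_dr = any(vectorise(DR) != 0.0);
  const double dv = validate_one(cell, FX, FY, FVX, FVY, DVX, DVY, AR, AL, DR,
                                 has_ar, has_al, has_dr, dr_r, dr_s, h, nsub,
                                 Lp, Ntot, eps_v, blow_bound,
                                 &px, &py, &vx, &vy);
  return Rcpp::List::create(Rcpp::Named("dv") = dv,
                            Rcpp::Named("px") = px, Rcpp::Named("py") = py,
                            Rcpp::Named("vx") = vx, Rcpp::Named("vy") = vy);
}

// ---------------------------------------------------------------------------
// Pairwise statistics
// ---------------------------------------------------------------------------

// Near-field radius (empirical quantile of all pairwise distances over all
// frames, k-th smallest with k = max(1, ceil(p * M))) and maximum distance.
// [[Rcpp::export]]
Rcpp::List cpp_pair_stats(const arma::mat &PX, const arma::mat &PY, double p_nf) {
  const int L = PX.n_rows, N = PX.n_cols;
  const size_t M = (size_t)L * N * (N - 1) / 2;
  std::vector<double> d;
  d.reserve(M);
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        const double dx = PX(k, j) - PX(k, i), dy = PY(k, j) - PY(k, i);
        d.push_back(std::sqrt(dx * dx + dy * dy));
      }
  const double r_max = *std::max_element(d.begin(), d.end());
  size_t kth = (size_t)std::ceil(p_nf * (double)d.size());
  if (kth < 1) kth = 1;
  if (kth > d.size()) kth = d.size();
  std::nth_element(d.begin(), d.begin() + (kth - 1), d.end());
  return Rcpp::List::create(Rcpp::Named("r_nf") = d[kth - 1],
                            Rcpp::Named("r_max") = r_max,
                            Rcpp::Named("n_dists") = (double)d.size());
}

// Per-cell 50-bin histograms of neighbour distances, neighbour velocity
// differences, and own speed, with shared global bin edges [0, max].
// [[Rcpp::export]]
Rcpp::List cpp_cell_stats(const arma::mat &PX, const arma::mat &PY,
                          const arma::mat &VX, const arma::mat &VY, int nbins) {
  const int L = PX.n_rows, N = PX.n_cols;
  double rmax = 0.0, dvmax = 0.0, vmax = 0.0;
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i) {
      const double sp = std::sqrt(VX(k, i) * VX(k, i) + VY(k, i) * VY(k, i));
      if (sp > vmax) vmax = sp;
      for (int j = i + 1; j < N; ++j) {
        const double dx = PX(k, j) - PX(k, i), dy = PY(k, j) - PY(k, i);
        const double r = std::sqrt(dx * dx + dy * dy);
        if (r > rmax) rmax = r;
        const double ux = VX(k, j) - VX(k, i), uy = VY(k, j) - VY(k, i);
        const double dv = std::sqrt(ux * ux + uy * uy);
        if (dv > dvmax) dvmax = dv;
      }
    }
  if (rmax <= 0) rmax = 1.0;
  if (dvmax <= 0) dvmax = 1.0;
  if (vmax <= 0) vmax = 1.0;
  mat RR(nbins, N, fill::zeros), VV(nbins, N, fill::zeros), SP(nbins, N, fill::zeros);
  auto binof = [nbins](double v, double vmx) {
    int b = (int)(v / vmx * nbins);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    return b;
  };
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < N; ++i) {
      const double sp = std::sqrt(VX(k, i) * VX(k, i) + VY(k, i) * VY(k, i));
      SP(binof(sp, vmax), i) += 1.0;
      for (int j = i + 1; j < N; ++j) {
        const double dx = PX(k, j) - PX(k, i), dy = PY(k, j) - PY(k, i);
        const double r = std::sqrt(dx * dx + dy * dy);
        const int br = binof(r, rmax);
        RR(br, i) += 1.0; RR(br, j) += 1.0;
        const double ux = VX(k, j) - VX(k, i), uy = VY(k, j) - VY(k, i);
        const double dv = std::sqrt(ux * ux + uy * uy);
        const int bv = binof(dv, dvmax);
        VV(bv, i) += 1.0; VV(bv, j) += 1.0;
      }
    }
  for (int i = 0; i < N; ++i) {
    RR.col(i) /= accu(RR.col(i));
    VV.col(i) /= accu(VV.col(i));
    SP.col(i) /= accu(SP.col(i));
  }
  return Rcpp::List::create(Rcpp::Named("rr") = RR, Rcpp::Named("vv") = VV,
                            Rcpp::Named("v") = SP,
                            Rcpp::Named("r_max") = rmax,
                            Rcpp::Named("dv_max") = dvmax,
                            Rcpp::Named("v_max") = vmax);
}
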