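// Mean-covariance propagation and cost evaluation for stochastic open-loop
// optimal control (SOOC) of the cup-and-ball system with Ornstein-Uhlenbeck
// uncertainty on pendulum length.
//
// Augmented state (9): x, v, theta, omega, l, F_ff, K, dF_ff, dK
// Pseudo-controls (2): ddK, ddF_ff
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct SoocPar {
  double mc, mb, g, kb, lmean, alpha, sigma_ou;
  double A, f, t_prep, theta_star;
  // weights
  double qx, qv, qvx, qvv;      // running tracking + variance (rhythmic)
  double r;                     // control effort
  double qk;                    // co-contraction (stiffness level) effort
  double wp_x, wp_v, wp_th, wp_om, wpv_x, wpv_v;  // end-of-preparation point
  double wf_x, wf_v, wfv_x, wfv_v;                // terminal
  double kneg;                  // penalty on negative stiffness
};

static SoocPar unpack(const Rcpp::List &cfg) {
  SoocPar p;
  p.mc = cfg["mc"]; p.mb = cfg["mb"]; p.g = cfg["g"]; p.kb = cfg["kb"];
  p.lmean = cfg["lmean"]; p.alpha = cfg["alpha"]; p.sigma_ou = cfg["sigma_ou"];
  p.A = cfg["A"]; p.f = cfg["f"]; p.t_prep = cfg["t_prep"];
  p.theta_star = cfg["theta_star"];
  p.qx = cfg["qx"]; p.qv = cfg["qv"]; p.qvx = cfg["qvx"]; p.qvv = cfg["qvv"];
  p.r = cfg["r"]; p.qk = cfg["qk"];
  p.wp_x = cfg["wp_x"]; p.wp_v = cfg["wp_v"]; p.wp_th = cfg["wp_th"];
  p.wp_om = cfg["wp_om"]; p.wpv_x = cfg["wpv_x"]; p.wpv_v = cfg["wpv_v"];
  p.wf_x = cfg["wf_x"]; p.wf_v = cfg["wf_v"];
  p.wfv_x = cfg["wfv_x"]; p.wfv_v = cfg["wfv_v"];
  p.kneg = cfg["kneg"];
  return p;
}

// Desired cup trajectory: held at the left box during preparation, then a
// cosine between the boxes; continuous at the stage boundary.
static inline void desired(double t, const SoocPar &p, double &xd,
                           double &vd) {
  if (t < p.t_prep) {
    xd = -p.A; vd = 0.0;
  } else {
    double w = 2.0 * M_PI * p.f, tt = t - p.t_prep;
    xd = -p.A * std::cos(w * tt);
    vd = p.A * w * std::sin(w * tt);
  }
}

static vec drift(const vec &m, const vec &u, double t, const SoocPar &p) {
  double xd, vd;
  desired(t, p, xd, vd);
  double x = m(0), v = m(1), th = m(2), om = m(3), l = m(4);
  double Fff = m(5), K = m(6);
  double Fap = K * (xd - x) + p.kb * K * (vd - v) + Fff;
  double s = std::sin(th), c = std::cos(th);
  double D = p.mc + p.mb * s * s;
  double vdot = (p.mb * (l * om * om * s + p.g * s * c) + Fap) / D;
  vec dm(9);
  dm(0) = v;
  dm(1) = vdot;
  dm(2) = om;
  dm(3) = -vdot * c / l - p.g * s / l;
  dm(4) = -p.alpha * (l - p.lmean);
  dm(5) = m(7);   // dF_ff
  dm(6) = m(8);   // dK
  dm(7) = u(1);   // ddF_ff
  dm(8) = u(0);   // ddK
  return dm;
}

// Analytic state Jacobian of the drift.
static mat jac(const vec &m, double t, const SoocPar &p) {
  double xd, vd;
  desired(t, p, xd, vd);
  double x = m(0), v = m(1), th = m(2), om = m(3), l = m(4);
  double Fff = m(5), K = m(6);
  double s = std::sin(th), c = std::cos(th);
  double D = p.mc + p.mb * s * s;
  double Fap = K * (xd - x) + p.kb * K * (vd - v) + Fff;
  double N = p.mb * (l * om * om * s + p.g * s * c) + Fap;
  double vdot = N / D;
  double dN_dth = p.mb * (l * om * om * c + p.g * (c * c - s * s));
  double dD_dth = 2.0 * p.mb * s * c;

  mat F(9, 9, fill::zeros);
  F(0, 1) = 1.0;
  // dv/dt row
  double dv_dx = -K / D;
  double dv_dv = -p.kb * K / D;
  double dv_dth = dN_dth / D - N * dD_dth / (D * D);
  double dv_dom = 2.0 * p.mb * l * om * s / D;
  double dv_dl = p.mb * om * om * s / D;
  double dv_dF = 1.0 / D;
  double dv_dK = ((xd - x) + p.kb * (vd - v)) / D;
  F(1, 0) = dv_dx; F(1, 1) = dv_dv; F(1, 2) = dv_dth; F(1, 3) = dv_dom;
  F(1, 4) = dv_dl; F(1, 5) = dv_dF; F(1, 6) = dv_dK;
  F(2, 3) = 1.0;
  // domega/dt = -vdot*c/l - g*s/l
  F(3, 0) = -dv_dx * c / l;
  F(3, 1) = -dv_dv * c / l;
  F(3, 2) = -dv_dth * c / l + vdot * s / l - p.g * c / l;
  F(3, 3) = -dv_dom * c / l;
  F(3, 4) = -dv_dl * c / l + vdot * c / (l * l) + p.g * s / (l * l);
  F(3, 5) = -dv_dF * c / l;
  F(3, 6) = -dv_dK * c / l;
  F(4, 4) = -p.alpha;
  F(5, 7) = 1.0;
  F(6, 8) = 1.0;
  return F;
}

static inline mat cov_rhs(const mat &P, const mat &F, const mat &GG) {
  return F * P + P * F.t() + GG;
}

static inline void project_psd(mat &P) {
  P = 0.5 * (P + P.t());
  vec ev; mat V;
  eig_sym(ev, V, P);
  if (ev.min() < -1e-10) {
    ev.transform([](double e) { return e < 0.0 ? 0.0 : e; });
    P = V * diagmat(ev) * V.t();
    P = 0.5 * (P + P.t());
  }
}

// Exact covariance step for the frozen (LTI-per-step) linearization via
// the Van Loan block-exponential: unconditionally stable, which matters
// because the OU reversion rate makes the covariance dynamics stiff.
static inline void cov_step_exact(mat &P, const mat &F, const mat &GG,
                                  double dt) {
  mat M(18, 18, fill::zeros);
  M.submat(0, 0, 8, 8) = -F * dt;
  M.submat(0, 9, 8, 17) = GG * dt;
  M.submat(9, 9, 17, 17) = F.t() * dt;
  mat E = expmat(M);
  mat PhiT = E.submat(9, 9, 17, 17);        // Phi'
  mat Q = PhiT.t() * E.submat(0, 9, 8, 17); // Phi * (Phi^-1 Q)
  P = PhiT.t() * P * PhiT + Q;
}

// Propagate mean and covariance under piecewise-linear controls U
// (2 x (n+1), one column per integration node) and accumulate the cost.
// cov_method: 0 = exact (Van Loan; unconditionally stable under the
// stiff OU reversion), 1 = RK4, 2 = Euler (explicit; need alpha*dt small).
// [[Rcpp::export]]
Rcpp::List sooc_propagate_cpp(const arma::mat &U, const arma::vec &m0,
                              const arma::mat &P0, const Rcpp::List &cfg,
                              double dt, int cov_method, bool project,
                              bool full_output) {
  SoocPar p = unpack(cfg);
  int n = U.n_cols - 1;
  int i_prep = (int)std::lround(p.t_prep / dt);
  mat GG(9, 9, fill::zeros);
  GG(4, 4) = p.sigma_ou * p.sigma_ou;

  vec m = m0;
  mat P = P0;
  double J_track = 0.0, J_var = 0.0, J_u = 0.0, J_pen = 0.0;
  double J_point = 0.0, J_term = 0.0;

  mat M_out, Pd_out;
  if (full_output) { M_out.set_size(9, n + 1); Pd_out.set_size(9, n + 1); }

  for (int i = 0; i <= n; ++i) {
    double t = i * dt;
    if (full_output) { M_out.col(i) = m; Pd_out.col(i) = P.diag(); }

    // running cost (left rectangle rule over steps 0..n-1)
    if (i < n) {
      double xd, vd;
      desired(t, p, xd, vd);
      if (t >= p.t_prep) {
        J_track += dt * (p.qx * std::pow(m(0) - xd, 2) +
                         p.qv * std::pow(m(1) - vd, 2));
        J_var += dt * (p.qvx * P(0, 0) + p.qvv * P(1, 1));
      }
      J_u += dt * p.r * (U(0, i) * U(0, i) + U(1, i) * U(1, i));
      J_u += dt * p.qk * m(6) * m(6);
      if (m(6) < 0.0) J_pen += dt * p.kneg * m(6) * m(6);
    }
    // end-of-preparation point cost
    if (i == i_prep) {
      J_point += p.wp_x * std::pow(m(0) + p.A, 2) + p.wp_v * m(1) * m(1) +
                 p.wp_th * std::pow(m(2) - p.theta_star, 2) +
                 p.wp_om * m(3) * m(3) + p.wpv_x * P(0, 0) +
                 p.wpv_v * P(1, 1);
    }
    // terminal cost
    if (i == n) {
      double xd, vd;
      desired(t, p, xd, vd);
      J_term += p.wf_x * std::pow(m(0) - xd, 2) +
                p.wf_v * std::pow(m(1) - vd, 2) + p.wfv_x * P(0, 0) +
                p.wfv_v * P(1, 1);
    }
    if (i == n) break;

    // RK4 step of the mean (controls linearly interpolated within the step)
    vec u0 = U.col(i), u1 = U.col(i + 1), uh = 0.5 * (u0 + u1);
    vec k1 = drift(m, u0, t, p);
    vec k2 = drift(m + 0.5 * dt * k1, uh, t + 0.5 * dt, p);
    vec k3 = drift(m + 0.5 * dt * k2, uh, t + 0.5 * dt, p);
    vec k4 = drift(m + dt * k3, u1, t + dt, p);

    if (cov_method == 0) {
      mat Fm = jac(m + 0.5 * dt * k1, t + 0.5 * dt, p);  // midpoint freeze
      cov_step_exact(P, Fm, GG, dt);
    } else if (cov_method == 1) {
      mat F1 = jac(m, t, p);
      mat F2 = jac(m + 0.5 * dt * k1, t + 0.5 * dt, p);
      mat F3 = jac(m + 0.5 * dt * k2, t + 0.5 * dt, p);
      mat F4 = jac(m + dt * k3, t + dt, p);
      mat L1 = cov_rhs(P, F1, GG);
      mat L2 = cov_rhs(P + 0.5 * dt * L1, F2, GG);
      mat L3 = cov_rhs(P + 0.5 * dt * L2, F3, GG);
      mat L4 = cov_rhs(P + dt * L3, F4, GG);
      P += dt / 6.0 * (L1 + 2.0 * L2 + 2.0 * L3 + L4);
    } else {
      mat F1 = jac(m, t, p);
      P += dt * cov_rhs(P, F1, GG);
    }
    if (project) project_psd(P); else P = 0.5 * (P + P.t());

    m += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!m.is_finite()) {
      return Rcpp::List::create(Rcpp::_["cost"] = 1e12,
                                Rcpp::_["diverged"] = true);
    }
  }

  double J = J_track + J_var + J_u + J_pen + J_point + J_term;
  if (!full_output)
    return Rcpp::List::create(Rcpp::_["cost"] = J,
                              Rcpp::_["diverged"] = false);
  return Rcpp::List::create(
      Rcpp::_["cost"] = J, Rcpp::_["diverged"] = false,
      Rcpp::_["M"] = M_out, Rcpp::_["P_diag"] = Pd_out, Rcpp::_["P_f"] = P,
      Rcpp::_["parts"] = Rcpp::NumericVector::create(
          Rcpp::_["tracking"] = J_track, Rcpp::_["variance"] = J_var,
          Rcpp::_["control"] = J_u, Rcpp::_["k_penalty"] = J_pen,
          Rcpp::_["prep_point"] = J_point, Rcpp::_["terminal"] = J_term));
}

// [[Rcpp::export]]
arma::vec sooc_drift_cpp(const arma::vec &m, const arma::vec &u, double t,
                         const Rcpp::List &cfg) {
  SoocPar p = unpack(cfg);
  return drift(m, u, t, p);
}

// [[Rcpp::export]]
arma::mat sooc_jacobian_cpp(const arma::vec &m, double t,
                            const Rcpp::List &cfg) {
  SoocPar p = unpack(cfg);
  return jac(m, t, p);
}
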