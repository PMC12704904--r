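#include <Rcpp.h>
using namespace Rcpp;

// Solved-form accelerations of the cart-pendulum. The two equations of
// motion are mutually implicit; substituting the ball equation into the
// cart equation gives a denominator mc + mb*sin^2(theta) >= mc > 0.
static inline void cb_accel(double x, double v, double th, double om,
                            double F, double mc, double mb, double l,
                            double g, double &xdd, double &thdd) {
  double s = std::sin(th), c = std::cos(th);
  double D = mc + mb * s * s;
  xdd = (mb * (l * om * om * s + g * s * c) + F) / D;
  thdd = -xdd * c / l - g * s / l;
}

struct CtrlSpec {
  double K, B, A, f;
};

// Restoring impedance force tracking xd(t) = -A*cos(2*pi*f*t).
static inline double imp_force(double x, double v, double t,
                               const CtrlSpec &cs) {
  double w = 2.0 * M_PI * cs.f;
  double xd = -cs.A * std::cos(w * t);
  double vd = cs.A * w * std::sin(w * t);
  return cs.K * (xd - x) + cs.B * (vd - v);
}

// Forward-simulate the impedance-controlled cart-pendulum with classic RK4.
// extra_force: optional per-step additive force (length n or 0), held
// constant within each step (zero-order hold).
// [[Rcpp::export]]
List simulate_trial_cpp(double mc, double mb, double l, double g,
                        double K, double B, double A, double f,
                        double x0, double v0, double theta0, double omega0,
                        double duration, double dt,
                        NumericVector extra_force) {
  int n = (int)std::lround(duration / dt);
  bool has_extra = extra_force.size() > 0;
  if (has_extra && extra_force.size() < n)
    stop("extra_force must have length >= %d", n);

  CtrlSpec cs{K, B, A, f};
  NumericVector t_out(n + 1), x_out(n + 1), v_out(n + 1), th_out(n + 1),
      om_out(n + 1), F_out(n + 1);

  double x = x0, v = v0, th = theta0, om = omega0;
  t_out[0] = 0.0; x_out[0] = x; v_out[0] = v; th_out[0] = th; om_out[0] = om;
  F_out[0] = imp_force(x, v, 0.0, cs) + (has_extra ? extra_force[0] : 0.0);

  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    double fe = has_extra ? extra_force[i] : 0.0;
    double kx[4], kv[4], kth[4], kom[4];
    double cx = x, cv = v, cth = th, com = om, ct = t;
    for (int s = 0; s < 4; ++s) {
      double F = imp_force(cx, cv, ct, cs) + fe;
      double xdd, thdd;
      cb_accel(cx, cv, cth, com, F, mc, mb, l, g, xdd, thdd);
      kx[s] = cv; kv[s] = xdd; kth[s] = com; kom[s] = thdd;
      double h = (s == 2) ? dt : dt / 2.0;
      if (s < 3) {
        cx = x + h * kx[s]; cv = v + h * kv[s];
        cth = th + h * kth[s]; com = om + h * kom[s];
        ct = t + h;
      }
    }
    x += dt / 6.0 * (kx[0] + 2 * kx[1] + 2 * kx[2] + kx[3]);
    v += dt / 6.0 * (kv[0] + 2 * kv[1] + 2 * kv[2] + kv[3]);
    th += dt / 6.0 * (kth[0] + 2 * kth[1] + 2 * kth[2] + kth[3]);
    om += dt / 6.0 * (kom[0] + 2 * kom[1] + 2 * kom[2] + kom[3]);
    if (!std::isfinite(x) || !std::isfinite(v) || !std::isfinite(th) ||
        !std::isfinite(om))
      stop("state diverged (non-finite) at step %d (t = %.3f s)", i + 1,
           (i + 1) * dt);
    t_out[i + 1] = (i + 1) * dt;
    x_out[i + 1] = x; v_out[i + 1] = v;
    th_out[i + 1] = th; om_out[i + 1] = om;
    F_out[i + 1] = imp_force(x, v, (i + 1) * dt, cs) +
                   (has_extra ? extra_force[std::min(i + 1, n - 1)] : 0.0);
  }
  return List::create(_["time_s"] = t_out, _["x"] = x_out, _["v"] = v_out,
                      _["theta"] = th_out, _["omega"] = om_out,
                      _["force"] = F_out);
}
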