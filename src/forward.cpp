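#include <Rcpp.h>
using namespace Rcpp;

// Hill-type muscle-tendon unit: fast path for the per-timestep fiber-state
// solution and 4th-order Runge-Kutta integration of fiber length.
//
// The formulas mirror the exported R operations (active_force_length,
// passive_force_length, force_velocity, invert_force_velocity, tendon_force,
// pennation_angle); the R engine of integrate_fiber_length is the reference
// implementation and the two are cross-checked in the test suite.

static const double FV_MAX = 2.34 / 1.3;  // eccentric asymptote
// cap used inside the integrator: the fv value at lengthening velocity
// v0m (v_norm = +1), so fiber speed is bounded by v0m in both directions
static const double FV_ECC_CAP = (2.34 + 0.039) / (1.3 + 0.039);

struct HillConsts {
  double lambda, q0, q1, q2, eps_knee, k_quad, k_lin, c_lin;
};

struct FiberEval {
  double vm, fv, fA, fP, phi, Ft;
  bool clamp_fv, clamp_den;
};

static inline double active_fl(double l, const HillConsts &c) {
  if (l < 0.5 || l > 1.5) return 0.0;
  double f = c.q0 + c.q1 * l + c.q2 * l * l;
  return f > 0.0 ? f : 0.0;
}

static inline double passive_fl(double l) {
  return std::exp(10.0 * l - 15.0);
}

static inline double tendon_f(double lt, double lst, double F0m,
                              const HillConsts &c) {
  double eps = (lt - lst) / lst;
  if (eps <= 0.0) return 0.0;
  if (eps < c.eps_knee) return F0m * c.k_quad * eps * eps;
  return F0m * (c.k_lin * eps - c.c_lin);
}

// closed-form inverse of the piecewise Mobius force-velocity curve
static inline double inv_fv(double fv) {
  if (fv < 1.0) return 0.3 * (fv - 1.0) / (fv + 0.3);  // concentric
  return 0.039 * (fv - 1.0) / (2.34 - 1.3 * fv);       // eccentric
}

// full per-timestep fiber state from (lm, a, lmt); fv is clamped into the
// invertible range rather than raising mid-integration
static inline FiberEval eval_fiber(double lm, double a, double lmt,
                                   double F0m, double l0m, double lst,
                                   double sinphi0, double v0m,
                                   const HillConsts &c, bool scale_l0m) {
  FiberEval out;
  double s = l0m * sinphi0 / lm;
  if (s > 1.0) s = 1.0;
  if (s < 0.0) s = 0.0;
  out.phi = std::asin(s);
  double cphi = std::cos(out.phi);
  double lt = lmt - lm * cphi;
  out.Ft = tendon_f(lt, lst, F0m, c);
  double l0_eff = scale_l0m ? l0m * (c.lambda * (1.0 - a) + 1.0) : l0m;
  double l = lm / l0_eff;
  out.fA = active_fl(l, c);
  out.fP = passive_fl(l);
  double den = out.fA * a * F0m * cphi;
  double den_min = 1e-6 * F0m;
  out.clamp_den = den < den_min;
  if (out.clamp_den) den = den_min;
  double fv = (out.Ft - out.fP * F0m * cphi) / den;
  out.clamp_fv = (fv < 0.0) || (fv > FV_ECC_CAP);
  if (fv < 0.0) fv = 0.0;
  if (fv > FV_ECC_CAP) fv = FV_ECC_CAP;
  out.fv = fv;
  out.vm = v0m * inv_fv(fv);
  return out;
}

// [[Rcpp::export(name = ".forward_fiber_cpp")]]
List forward_fiber_cpp(NumericVector a, NumericVector lmt, double dt,
                       double F0m, double l0m, double lst, double phi0_rad,
                       double v0m, double lm0,
                       double lambda, double q0, double q1, double q2,
                       double eps_knee, double k_quad, double k_lin,
                       double c_lin, bool scale_l0m) {
  int n = a.size();
  if (lmt.size() != n) stop("a and lmt must share one time base");
  HillConsts c = {lambda, q0, q1, q2, eps_knee, k_quad, k_lin, c_lin};
  double sinphi0 = std::sin(phi0_rad);

  NumericVector lm_out(n), vm_out(n), phi_out(n), FAm(n), FPm(n), Fm(n), Ft(n);
  int n_clamp_fv = 0, n_clamp_den = 0;
  int abort_step = 0;  // 1-based first bad step; 0 = clean

  double lm = lm0;
  double lo = 0.25 * l0m, hi = 2.5 * l0m;

  for (int i = 0; i < n; i++) {
    if (lm <= lo || lm >= hi) { abort_step = i + 1; break; }
    FiberEval st = eval_fiber(lm, a[i], lmt[i], F0m, l0m, lst, sinphi0, v0m,
                              c, scale_l0m);
    if (st.clamp_fv) n_clamp_fv++;
    if (st.clamp_den) n_clamp_den++;
    lm_out[i] = lm;
    vm_out[i] = st.vm;
    phi_out[i] = st.phi;
    // force decomposition per the contractile/parallel-element split; with
    // the clamped fv the tendon-equilibrium identity holds by construction
    // whenever no clamp fired
    FAm[i] = st.fA * st.fv * a[i] * F0m;
    FPm[i] = st.fP * F0m;
    Fm[i] = FAm[i] + FPm[i];
    Ft[i] = st.Ft;
    if (i == n - 1) break;

    // classic RK4 on dlm/dt = vm, inputs interpolated at half steps
    double a_half = 0.5 * (a[i] + a[i + 1]);
    double lmt_half = 0.5 * (lmt[i] + lmt[i + 1]);
    double k1 = st.vm;
    double k2 = eval_fiber(lm + 0.5 * dt * k1, a_half, lmt_half, F0m, l0m,
                           lst, sinphi0, v0m, c, scale_l0m).vm;
    double k3 = eval_fiber(lm + 0.5 * dt * k2, a_half, lmt_half, F0m, l0m,
                           lst, sinphi0, v0m, c, scale_l0m).vm;
    double k4 = eval_fiber(lm + dt * k3, a[i + 1], lmt[i + 1], F0m, l0m,
                           lst, sinphi0, v0m, c, scale_l0m).vm;
    lm = lm + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }

  return List::create(_["lm"] = lm_out, _["vm"] = vm_out, _["phi"] = phi_out,
                      _["FAm"] = FAm, _["FPm"] = FPm, _["Fm"] = Fm,
                      _["Ft"] = Ft, _["abort_step"] = abort_step,
                      _["n_clamp_fv"] = n_clamp_fv,
                      _["n_clamp_den"] = n_clamp_den);
}
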