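#include <Rcpp.h>
using namespace Rcpp;

// Four-variable RHS of the two-compartment nutrient-coupled logistic model.
// p = (mu_max, K_max, k_plus, k_minus, D_n, delta, beta, c_ref)
static inline void rhs(const double* s, const double* p, double* d) {
  const double mu_max = p[0], K_max = p[1], kp = p[2], km = p[3],
               Dn = p[4], delta = p[5], beta = p[6], c_ref = p[7];
  const double rho_b = s[0], rho_p = s[1], c_b = s[2], c_p = s[3];
  const double death = mu_max / K_max;  // nutrient factor cancels in rho^2 term
  const double g_b = mu_max * c_b / c_ref;
  const double g_p = mu_max * c_p / c_ref;
  d[0] = g_b * rho_b - death * rho_b * rho_b + kp * rho_p - km * rho_b;
  d[1] = g_p * rho_p - death * rho_p * rho_p - kp * rho_p + km * rho_b;
  d[2] = -beta * g_b * rho_b - delta * c_b + Dn * (c_p - c_b);
  d[3] = -beta * g_p * rho_p - delta * c_p - Dn * (c_p - c_b);
}

// [[Rcpp::export]]
List rk4_integrate_cpp(NumericVector state0, NumericVector params,
                       double t_end, double dt) {
  const int n_steps = (int)std::round(t_end / dt);
  NumericMatrix out(n_steps + 1, 4);
  NumericVector time(n_steps + 1);
  double s[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  const double* p = params.begin();
  for (int j = 0; j < 4; ++j) { s[j] = state0[j]; out(0, j) = s[j]; }
  int clamped = 0;
  for (int i = 1; i <= n_steps; ++i) {
    rhs(s, p, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = std::max(s[j] + 0.5 * dt * k1[j], 0.0);
    rhs(tmp, p, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = std::max(s[j] + 0.5 * dt * k2[j], 0.0);
    rhs(tmp, p, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = std::max(s[j] + dt * k3[j], 0.0);
    rhs(tmp, p, k4);
    for (int j = 0; j < 4; ++j) {
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (s[j] < 0.0) { s[j] = 0.0; ++clamped; }
      out(i, j) = s[j];
    }
    time[i] = i * dt;
  }
  return List::create(_["time"] = time, _["states"] = out,
                      _["clamped"] = clamped);
}
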