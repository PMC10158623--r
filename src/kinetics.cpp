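#include <Rcpp.h>
#include <cmath>

// Batch kinetics of adherent cells expanding on microcarriers.
//
// State vector y (fixed order):
//   0 X_t    total cells            [cells/mL]
//   1 X_V    attached viable cells  [cells/mL]
//   2 X_Sus  suspension cells       [cells/mL]
//   3 c_Glc  glucose                [mmol/L]
//   4 c_Gln  glutamine              [mmol/L]
//   5 c_LS   limiting substrate     [a.u./L]
//   6 c_Lac  lactate                [mmol/L]
//   7 c_Amm  ammonia                [mmol/L]
//
// Parameter vector p (fixed order, matches R side kinetic_params()):
//   0 mu_max  1 K_S_LS  2 mu_d_min  3 mu_d_max  4 K_d_LS  5 k_att_max
//   6 t_att   7 K_Lys   8 Y_X_Glc   9 k_Glc    10 Y_X_Gln 11 k_Gln
//  12 q_LS_max 13 k_LS  14 Y_Lac_Glc 15 Y_Amm_Gln

static const int NSTATE = 8;

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

static void rhs(double t, const double* y, double* dy,
                const double* p, double xv_max, double k_att,
                bool death_inverse) {
  const double xv   = y[1];
  const double xsus = y[2];
  const double glc  = pos(y[3]);
  const double gln  = pos(y[4]);
  const double ls   = pos(y[5]);

  // free-space fraction on the carriers; 0 when no carriers at all
  double sf = 0.0;
  if (xv_max > 0.0) {
    sf = (xv_max - xv) / xv_max;
    if (sf < 0.0) sf = 0.0;
    if (sf > 1.0) sf = 1.0;
  }

  const double mu = p[0] * ls / (ls + p[1]) * sf;
  const double mud = death_inverse
    ? p[2] + p[3] * p[4] / (ls + p[4])
    : p[2] + p[3] * ls / (ls + p[4]);

  // growth-coupled uptake; the space factor appears a second time, as printed
  const double q_glc = (mu / p[8])  * glc / (glc + p[9])  * sf;
  const double q_gln = (mu / p[10]) * gln / (gln + p[11]) * sf;
  const double q_ls  = p[12] * ls / (ls + p[13]);

  const double att = k_att * sf * xsus;

  dy[0] = mu * xv - p[7] * (y[0] - xv);      // dX_t/dt
  dy[1] = (mu - mud) * xv + att;             // dX_V/dt
  dy[2] = mud * xv - att;                    // dX_Sus/dt
  dy[3] = -q_glc * xv;                       // dc_Glc/dt
  dy[4] = -q_gln * xv;                       // dc_Gln/dt
  dy[5] = -q_ls * xv;                        // dc_LS/dt
  dy[6] = p[14] * q_glc * xv;                // dc_Lac/dt
  dy[7] = p[15] * q_gln * xv;                // dc_Amm/dt
}

// [[Rcpp::export(name = ".rhs_cpp")]]
Rcpp::NumericVector rhs_cpp(double t, Rcpp::NumericVector state,
                            Rcpp::NumericVector params, double xv_max,
                            bool death_inverse = false) {
  if (state.size() != NSTATE) Rcpp::stop("state must have 8 elements");
  if (params.size() != 16) Rcpp::stop("params must have 16 elements");
  const double k_att = (t < params[6]) ? params[5] : 0.0;
  Rcpp::NumericVector dy(NSTATE);
  rhs(t, state.begin(), dy.begin(), params.begin(), xv_max, k_att,
      death_inverse);
  return dy;
}

// Dormand-Prince 5(4) adaptive step from t0 to t1, writing into y in place.
// Returns true on success. k_att is constant within a segment (the
// discontinuity at t_att is handled by segmenting in dp45_path below).
static bool dp45_segment(double t0, double t1, double* y, const double* p,
                         double xv_max, double k_att, bool death_inverse,
                         double rtol, double atol, double& h_guess) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525,
                      e7 = -1.0 / 40;

  if (t1 <= t0) return true;
  double t = t0;
  double h = h_guess;
  if (h <= 0.0 || h > (t1 - t0)) h = t1 - t0;

  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
         k6[NSTATE], k7[NSTATE], ytmp[NSTATE], ynew[NSTATE];
  long max_steps = 1000000;

  rhs(t, y, k1, p, xv_max, k_att, death_inverse);
  while (t < t1) {
    if (--max_steps < 0) return false;
    if (t + h > t1) h = t1 - t;

    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(t + c2 * h, ytmp, k2, p, xv_max, k_att, death_inverse);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + c3 * h, ytmp, k3, p, xv_max, k_att, death_inverse);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + c4 * h, ytmp, k4, p, xv_max, k_att, death_inverse);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(t + c5 * h, ytmp, k5, p, xv_max, k_att, death_inverse);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, ytmp, k6, p, xv_max, k_att, death_inverse);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, ynew, k7, p, xv_max, k_att, death_inverse);

    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSTATE);
    if (!std::isfinite(errnorm)) return false;

    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
    }
    double fac = 0.9 * std::pow(errnorm > 1e-12 ? errnorm : 1e-12, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-12 * (t1 - t0)) return false;
  }
  h_guess = h;
  return true;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
Rcpp::NumericMatrix simulate_cpp(Rcpp::NumericVector y0,
                                 Rcpp::NumericVector params, double xv_max,
                                 Rcpp::NumericVector t_grid,
                                 double rtol = 1e-8, double atol = 1e-10,
                                 bool death_inverse = false) {
  if (y0.size() != NSTATE) Rcpp::stop("y0 must have 8 elements");
  if (params.size() != 16) Rcpp::stop("params must have 16 elements");
  const int nt = t_grid.size();
  if (nt < 1 || t_grid[0] != 0.0)
    Rcpp::stop("t_grid must start at 0");
  for (int j = 1; j < nt; ++j)
    if (t_grid[j] <= t_grid[j - 1])
      Rcpp::stop("t_grid must be strictly increasing");

  const double t_att = params[6];
  const double k_att_max = params[5];

  Rcpp::NumericMatrix out(nt, NSTATE);
  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }

  double h_guess = 0.0;
  double t = 0.0;
  for (int j = 1; j < nt; ++j) {
    double target = t_grid[j];
    // split the step at the attachment-window edge so the k_att switch is
    // never inside an integration segment
    while (t < target) {
      double seg_end = target;
      double k_att = (t < t_att) ? k_att_max : 0.0;
      if (t < t_att && t_att < target) seg_end = t_att;
      if (!dp45_segment(t, seg_end, y, params.begin(), xv_max, k_att,
                        death_inverse, rtol, atol, h_guess))
        Rcpp::stop("ODE integration failed near t = %g h", t);
      t = seg_end;
    }
    for (int i = 0; i < NSTATE; ++i) out(j, i) = y[i];
  }
  return out;
}
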