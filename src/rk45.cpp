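#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dormand-Prince 5(4) tableau
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// b - bhat (embedded 4th order), FSAL stage 7 included
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;

struct ModelParams {
  double gS;        // growth rate of the proliferating compartment
  double theta;     // carrying capacity shared by all compartments
  double gd, kd;    // damaged-cell proliferation rate / asymptotic net rate
  // per damaged subpopulation: death-delay rate and dose time
  std::vector<double> gamma;
  std::vector<double> tdose;
};

// state y = [S, D_1, ..., D_m]; total N couples all compartments
static void rhs(double t, const std::vector<double>& y,
                std::vector<double>& dy, const ModelParams& p) {
  double N = 0.0;
  for (size_t i = 0; i < y.size(); ++i) N += y[i];
  const double crowd = 1.0 - N / p.theta;
  dy[0] = p.gS * y[0] * crowd;
  for (size_t i = 1; i < y.size(); ++i) {
    const double r = p.kd + (p.gd - p.kd) *
      std::exp(-p.gamma[i - 1] * (t - p.tdose[i - 1]));
    dy[i] = r * y[i] * crowd;
  }
}

// advance y from t to t_end with adaptive DP5(4); h_next carried across calls
static void integrate_to(double& t, std::vector<double>& y, double t_end,
                         const ModelParams& p, double rtol, double atol,
                         double& h_next) {
  const size_t n = y.size();
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n);
  bool have_k1 = false;
  while (t < t_end) {
    double h = h_next;
    if (t + h > t_end) h = t_end - t;
    if (!have_k1) { rhs(t, y, k1, p); have_k1 = true; }
    for (;;) {
      if (h < 1e-12 * std::max(1.0, std::fabs(t)))
        stop("integrator step size collapsed near t = %f", t);
      for (size_t i = 0; i < n; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
      rhs(t + C2 * h, ytmp, k2, p);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
      rhs(t + C3 * h, ytmp, k3, p);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
      rhs(t + C4 * h, ytmp, k4, p);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                              A54 * k4[i]);
      rhs(t + C5 * h, ytmp, k5, p);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                              A64 * k4[i] + A65 * k5[i]);
      rhs(t + h, ytmp, k6, p);
      for (size_t i = 0; i < n; ++i)
        ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                              B5 * k5[i] + B6 * k6[i]);
      rhs(t + h, ynew, k7, p);  // FSAL
      double err = 0.0;
      for (size_t i = 0; i < n; ++i) {
        const double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                              E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
        err += (e / sc) * (e / sc);
      }
      err = std::sqrt(err / n);
      if (err <= 1.0 || !R_finite(err)) {
        if (!R_finite(err)) stop("non-finite state in integrator");
        t += h;
        // snap to the segment end when within roundoff, so the remaining
        // sliver cannot trip the minimum-step guard
        if (std::fabs(t_end - t) < 1e-10 * std::max(1.0, std::fabs(t_end)))
          t = t_end;
        double total = 0.0;
        for (size_t i = 0; i < n; ++i) total += ynew[i];
        for (size_t i = 0; i < n; ++i) {
          if (ynew[i] < -1e-6 * std::max(1.0, total))
            stop("negative compartment beyond tolerance at t = %f", t);
          if (ynew[i] < 0) ynew[i] = 0.0;
        }
        y = ynew;
        k1 = k7;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        h_next = h * fac;
        break;
      }
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.2) fac = 0.2;
      h = h * fac;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".sim_multidose_cpp")]]
NumericMatrix sim_multidose_cpp(NumericVector t_grid, NumericVector dose_times,
                                NumericVector fs, NumericVector gamma_d,
                                double g0, double gs, double gd, double kd,
                                double theta_u, double theta_dox, double N0,
                                double rtol, double atol) {
  const int ng = t_grid.size();
  const int nd = dose_times.size();
  if (ng < 1) stop("empty time grid");
  for (int i = 1; i < ng; ++i)
    if (t_grid[i] <= t_grid[i - 1]) stop("time grid must be strictly increasing");
  for (int i = 1; i < nd; ++i)
    if (dose_times[i] < dose_times[i - 1]) stop("dose times must be nondecreasing");

  NumericMatrix out(ng, 2 + nd + 1);  // time, S, D1..Dnd, N
  const double t0 = t_grid[0];
  double t = t0;
  std::vector<double> y(1, N0);  // pre-treatment: single logistic compartment
  ModelParams p;
  p.gS = g0; p.theta = theta_u; p.gd = gd; p.kd = kd;
  double h_next = (t_grid[ng - 1] - t0) / 100.0;
  if (h_next <= 0) h_next = 1.0;
  int gi = 0;
  const double eps = 1e-9 * std::max(1.0, std::fabs(t_grid[ng - 1]));

  auto record = [&](int idx) {
    out(idx, 0) = t_grid[idx];
    out(idx, 1) = y[0];
    double N = y[0];
    for (int j = 0; j < nd; ++j) {
      const double Dj = (j + 1 < (int)y.size()) ? y[j + 1] : 0.0;
      out(idx, 2 + j) = Dj;
      N += Dj;
    }
    out(idx, 2 + nd) = N;
  };

  for (int i = 0; i < nd; ++i) {
    const double td = dose_times[i];
    if (td < t0 - eps) stop("dose time before start of grid");
    // record grid points strictly before the dose, integrating on the way
    while (gi < ng && t_grid[gi] < td - eps) {
      integrate_to(t, y, t_grid[gi], p, rtol, atol, h_next);
      record(gi); ++gi;
    }
    integrate_to(t, y, td, p, rtol, atol, h_next);
    // partition: dose 1 splits total N, later doses split S only
    if (i == 0) {
      const double Nminus = y[0];
      y[0] = fs[0] * Nminus;
      y.push_back((1.0 - fs[0]) * Nminus);
      p.gS = gs; p.theta = theta_dox;  // capacity switches permanently
    } else {
      const double Sminus = y[0];
      y[0] = fs[i] * Sminus;
      y.push_back((1.0 - fs[i]) * Sminus);
    }
    p.gamma.push_back(gamma_d[i]);
    p.tdose.push_back(td);
    h_next = std::min(h_next, 1.0);  // fresh transient after the jump
    // grid points at the dose time report the post-dose state (H(0) = 1);
    // with simultaneous doses, record only after the last one is applied
    const bool more_at_same_time =
        (i + 1 < nd) && std::fabs(dose_times[i + 1] - td) <= eps;
    if (!more_at_same_time)
      while (gi < ng && std::fabs(t_grid[gi] - td) <= eps) { record(gi); ++gi; }
  }
  while (gi < ng) {
    integrate_to(t, y, t_grid[gi], p, rtol, atol, h_next);
    record(gi); ++gi;
  }
  return out;
}
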