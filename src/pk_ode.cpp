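// Adaptive Dormand-Prince 5(4) integrator for the radotinib structural model:
// transit-chain oral input -> first-order absorption depot -> two-compartment
// disposition with circadian-modulated first-order elimination.
//
// State (mg): y0 = absorption depot, y1 = central, y2 = peripheral,
//             y3 = cumulative eliminated mass (for mass-balance checks).
//
// Disposition parameters may switch at occasion boundaries (interoccasion
// variability on Vc/Vp); the integrator restarts at every dose time, segment
// start and output time, so right-hand-side kinks never sit inside a step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Pars {
  double cl, vc, q, vp, ka, mtt, n, f;
  double ktr, lgn1; // (n+1)/mtt, lgamma(n+1)
};

struct Model {
  std::vector<double> dose_t, dose_a, dose_lc, dose_w;
  std::vector<Pars> seg;
  std::vector<double> seg_start; // seg[i] active on [seg_start[i], seg_start[i+1])
  double amp, acro, period;

  // per-dose constants: log(f*D*ktr) and the time window beyond which the
  // transit input is below exp(-40) of its scale and can be skipped
  void finalize() {
    for (size_t d = 0; d < dose_t.size(); ++d) {
      const Pars& p = at(dose_t[d]);
      double lc = std::log(p.f * dose_a[d] * p.ktr);
      double rhs = 40.0 + lc - p.lgn1;
      double x = std::max(rhs, 10.0);
      for (int it = 0; it < 20; ++it) x = std::max(rhs, 10.0) + p.n * std::log(x);
      dose_lc.push_back(lc);
      dose_w.push_back(x / p.ktr);
    }
  }

  const Pars& at(double t) const {
    size_t i = seg.size() - 1;
    while (i > 0 && t < seg_start[i]) --i;
    return seg[i];
  }

  double circ(double t) const {
    return 1.0 + amp * std::cos(2.0 * M_PI * (t - acro) / period);
  }

  // summed analytic transit-chain input rate (mg/h) at time t
  double input_rate(double t, const Pars& p) const {
    double rate = 0.0;
    for (size_t d = 0; d < dose_t.size(); ++d) {
      double dt = t - dose_t[d];
      if (dt <= 0.0) break; // dose times sorted ascending
      if (dt > dose_w[d]) continue;
      double x = p.ktr * dt;
      double lr = dose_lc[d] + p.n * std::log(x) - x - p.lgn1;
      if (lr > -40.0) rate += std::exp(lr);
    }
    return rate;
  }

  void deriv(double t, const double* y, double* dy) const {
    const Pars& p = at(t);
    double clt = p.cl * circ(t);
    double rate = input_rate(t, p);
    dy[0] = rate - p.ka * y[0];
    dy[1] = p.ka * y[0] - (clt / p.vc + p.q / p.vc) * y[1] + (p.q / p.vp) * y[2];
    dy[2] = (p.q / p.vc) * y[1] - (p.q / p.vp) * y[2];
    dy[3] = (clt / p.vc) * y[1];
  }
};

const int NS = 4;

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// integrate from t0 to t1 (t1 > t0), y updated in place; h_carry persists
// the adapted step size across segment restarts
void integrate_segment(const Model& m, double t0, double t1, double* y,
                       double rtol, double atol, double& h_carry) {
  double t = t0;
  double h = std::min(h_carry, t1 - t0);
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double yt[NS], y5[NS];
  m.deriv(t, y, k1); // FSAL seed
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000) stop("ODE integrator exceeded iteration limit");
    bool last = false;
    if (t + h >= t1) { h = t1 - t; last = true; }

    for (int i = 0; i < NS; ++i) yt[i] = y[i] + h * a21 * k1[i];
    m.deriv(t + c2 * h, yt, k2);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.deriv(t + c3 * h, yt, k3);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.deriv(t + c4 * h, yt, k4);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    m.deriv(t + c5 * h, yt, k5);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                          a65 * k5[i]);
    m.deriv(t + h, yt, k6);
    for (int i = 0; i < NS; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    m.deriv(t + h, y5, k7);

    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                              e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4) / sc;
      err += e * e;
    }
    err = std::sqrt(err / NS);
    if (!std::isfinite(err)) { h *= 0.1; continue; }

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      h = std::min(h, 6.0); // stay well inside a circadian quarter-period
      h_carry = h;
      if (!last) h = std::min(h, t1 - t);
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      h *= std::max(0.1, fac);
      h_carry = h;
      last = false;
    }
    if (h < 1e-12) stop("ODE step size underflow");
  }
}

} // namespace

// [[Rcpp::export(name = ".pk_solve_cpp")]]
NumericMatrix pk_solve_cpp(NumericVector out_times,
                           NumericVector dose_times, NumericVector dose_amts,
                           NumericMatrix seg_pars, NumericVector seg_starts,
                           double amp, double acro, double period,
                           double rtol, double atol, NumericVector init) {
  int n_out = out_times.size();
  if (seg_pars.nrow() != seg_starts.size())
    stop("segment parameter matrix and segment starts disagree");
  if (dose_times.size() != dose_amts.size())
    stop("dose times and amounts disagree");

  Model m;
  m.amp = amp; m.acro = acro; m.period = period;
  for (int i = 0; i < dose_times.size(); ++i) {
    m.dose_t.push_back(dose_times[i]);
    m.dose_a.push_back(dose_amts[i]);
  }
  for (int i = 0; i < seg_pars.nrow(); ++i) {
    Pars p;
    p.cl = seg_pars(i, 0); p.vc = seg_pars(i, 1); p.q = seg_pars(i, 2);
    p.vp = seg_pars(i, 3); p.ka = seg_pars(i, 4); p.mtt = seg_pars(i, 5);
    p.n = seg_pars(i, 6);  p.f = seg_pars(i, 7);
    if (p.mtt <= 0.0 || p.vc <= 0.0 || p.vp <= 0.0 || p.ka <= 0.0)
      stop("non-positive structural parameter in ODE solve");
    p.ktr = (p.n + 1.0) / p.mtt;
    p.lgn1 = std::lgamma(p.n + 1.0);
    m.seg.push_back(p);
    m.seg_start.push_back(seg_starts[i]);
  }
  m.finalize();

  // break points: every dose time, segment start and output time
  std::vector<double> brk;
  brk.reserve(m.dose_t.size() + n_out + m.seg.size());
  for (double v : m.dose_t) brk.push_back(v);
  for (double v : m.seg_start) brk.push_back(v);
  for (int i = 0; i < n_out; ++i) brk.push_back(out_times[i]);
  std::sort(brk.begin(), brk.end());

  double t0 = 0.0;
  if (n_out > 0) t0 = std::min(t0, out_times[0]);
  if (!brk.empty()) t0 = std::min(t0, brk.front());

  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = (init.size() > i) ? init[i] : 0.0;

  NumericMatrix out(n_out, NS + 1);
  // walk the sorted output times while advancing through break points
  std::vector<int> ord(n_out);
  for (int i = 0; i < n_out; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return out_times[a] < out_times[b];
  });

  double t = t0;
  size_t bi = 0;
  double h_carry = 0.1;
  for (int oi = 0; oi < n_out; ++oi) {
    double tt = out_times[ord[oi]];
    if (tt < t - 1e-12) stop("output times must be non-decreasing");
    while (bi < brk.size() && brk[bi] <= tt + 1e-12) {
      if (brk[bi] > t + 1e-12) {
        integrate_segment(m, t, brk[bi], y, rtol, atol, h_carry);
        t = brk[bi];
      }
      ++bi;
    }
    if (tt > t + 1e-12) {
      integrate_segment(m, t, tt, y, rtol, atol, h_carry);
      t = tt;
    }
    out(ord[oi], 0) = tt;
    for (int i = 0; i < NS; ++i) out(ord[oi], i + 1) = y[i];
  }
  return out;
}
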