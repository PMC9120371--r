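// Steady-state transfer functions of an exponential integrate-and-fire
// population under white-noise input, computed by threshold integration of
// the stationary Fokker-Planck equation (Richardson 2007), plus the
// effective low-pass timescale obtained from an exponential fit to the
// linear rate response (the "LNexp" reduction of Augustin et al. 2017).
//
// Membrane equation in current-per-capacitance units (mV/ms):
//   dV/dt = F(V) + mu + sigma * xi(t)
//   F(V)  = (gL (EL - V) + gL DeltaT exp((V - VT)/DeltaT)) / C
// with reset Vr, threshold Vs, refractory period Tref. Adaptation is not
// part of the table; the population equations shift mu by -IA/C instead.

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

struct Eif {
  double C, gL, EL, DeltaT, VT, Vr, Vs, Tref;
  double F(double V) const {
    return (gL * (EL - V) + gL * DeltaT * std::exp((V - VT) / DeltaT)) / C;
  }
};

static Eif eif_from_list(const List &p) {
  Eif e;
  e.C = p["C"]; e.gL = p["gL"]; e.EL = p["EL"];
  e.DeltaT = p["DeltaT"]; e.VT = p["VT"];
  e.Vr = p["Vr"]; e.Vs = p["Vs"]; e.Tref = p["Tref"];
  return e;
}

// Backward threshold integration of the stationary density. Returns the
// steady-state rate r0 (kHz) and mean membrane voltage (mV, refractory time
// spent at Vr included). The scaled density q = P/r is integrated from Vs
// down to Vlb with an exponential (locally exact) stepper; q can grow like
// exp(potential/D) in strongly subthreshold regimes, so sums are rescaled on
// the fly to avoid overflow.
static void steady_state(const Eif &e, double mu, double sigma, double Vlb,
                         double dV, double &r0, double &Vmean) {
  const double D = 0.5 * sigma * sigma;
  const int n = (int)std::ceil((e.Vs - Vlb) / dV);
  double q = 0.0;       // scaled density at current grid point
  double S = 0.0;       // integral of q dV (in units of scale)
  double SV = 0.0;      // integral of V q dV
  double scale_log = 0.0;
  const double BIG = 1e250;

  double Vhi = e.Vs;
  for (int k = 0; k < n; k++) {
    double Vlo = Vhi - dV;
    if (Vlo < Vlb) Vlo = Vlb;
    const double h = Vhi - Vlo;
    const double Vm = 0.5 * (Vhi + Vlo);
    const double j = (Vm >= e.Vr) ? 1.0 : 0.0; // unit-rate probability flux
    const double A = (e.F(Vm) + mu) / D;
    const double b = j / D;
    // dq/dV = A q - b  integrated from Vhi down to Vlo (exact for constant A)
    double qlo;
    if (std::fabs(A * h) > 1e-8) {
      const double ba = b / A;
      qlo = (q - ba) * std::exp(-A * h) + ba;
    } else {
      qlo = q - h * (A * q - b);
    }
    if (qlo < 0) qlo = 0; // guard against round-off at the threshold
    S += 0.5 * (q + qlo) * h;
    SV += 0.5 * (q * Vhi + qlo * Vlo) * h;
    q = qlo;
    Vhi = Vlo;
    if (q > BIG) { // rescale to avoid overflow deep below threshold
      q *= 1e-100; S *= 1e-100; SV *= 1e-100; scale_log += 100.0;
    }
  }
  // r = 1 / (Tref + integral q dV); with rescaling the integral is S*10^scale
  if (scale_log > 0 || S > 1e200) {
    r0 = 0.0;
    Vmean = SV / S;
  } else {
    r0 = 1.0 / (e.Tref + S);
    Vmean = r0 * (SV + e.Tref * e.Vr);
  }
}

// Linear rate response r1(omega) to a modulation of the mean input,
// by backward integration of the perturbed flux/density pair (two sweeps:
// homogeneous with unit threshold flux, inhomogeneous forced by the
// stationary density). Requires the stationary scaled density q0(V).
static std::complex<double> rate_response(const Eif &e, double mu, double sigma,
                                          double Vlb, double dV, double omega,
                                          double r0) {
  typedef std::complex<double> cplx;
  const double D = 0.5 * sigma * sigma;
  const int n = (int)std::ceil((e.Vs - Vlb) / dV);
  // recompute the stationary scaled density on the same grid (cheap)
  std::vector<double> P0(n + 1);
  {
    double q = 0.0, Vhi = e.Vs;
    P0[0] = 0.0;
    for (int k = 0; k < n; k++) {
      double Vlo = Vhi - dV; if (Vlo < Vlb) Vlo = Vlb;
      const double h = Vhi - Vlo, Vm = 0.5 * (Vhi + Vlo);
      const double j = (Vm >= e.Vr) ? 1.0 : 0.0;
      const double A = (e.F(Vm) + mu) / D, b = j / D;
      if (std::fabs(A * h) > 1e-8) {
        const double ba = b / A;
        q = (q - ba) * std::exp(-A * h) + ba;
      } else q = q - h * (A * q - b);
      if (q < 0) q = 0;
      if (q > 1e250) q = 1e250; // silent regime; response is ~0 anyway
      P0[k + 1] = r0 * q;       // stationary density (unnormalized if r0=0)
      Vhi = Vlo;
    }
  }
  const cplx I(0.0, 1.0);
  const cplx reset_phase = std::exp(-I * omega * e.Tref);
  // sweep A: rhat = 1, mu_hat = 0 ; sweep B: rhat = 0, mu_hat = 1
  cplx jA(1.0, 0.0), pA(0.0, 0.0), jB(0.0, 0.0), pB(0.0, 0.0);
  double Vhi = e.Vs;
  bool reset_done = false;
  for (int k = 0; k < n; k++) {
    double Vlo = Vhi - dV; if (Vlo < Vlb) Vlo = Vlb;
    const double h = Vhi - Vlo, Vm = 0.5 * (Vhi + Vlo);
    const double A = (e.F(Vm) + mu) / D;
    const double P0m = 0.5 * (P0[k] + P0[k + 1]);
    // dp/dV = A p - c with c = (j - mu_hat P0)/D ; dj/dV = -i w p
    cplx cA = jA / D;
    cplx cB = (jB - P0m) / D;
    cplx pA_new, pB_new;
    if (std::fabs(A * h) > 1e-8) {
      const double eAh = std::exp(-A * h);
      pA_new = (pA - cA / A) * eAh + cA / A;
      pB_new = (pB - cB / A) * eAh + cB / A;
    } else {
      pA_new = pA - h * (A * pA - cA);
      pB_new = pB - h * (A * pB - cB);
    }
    // dj/dV = -i w p, so stepping downward j(V-h) = j(V) + i w pbar h
    jA += I * omega * 0.5 * (pA + pA_new) * h;
    jB += I * omega * 0.5 * (pB + pB_new) * h;
    pA = pA_new; pB = pB_new;
    Vhi = Vlo;
    if (!reset_done && Vhi <= e.Vr + 1e-12) { // re-injection at the reset
      jA -= reset_phase;
      reset_done = true;
    }
    // guard: in deeply subthreshold regions the homogeneous solution blows
    // up; rescale both sweeps identically (ratio is what matters)
    double m = std::max(std::abs(pA), std::abs(jA));
    if (m > 1e200) { pA *= 1e-100; jA *= 1e-100; pB *= 1e-100; jB *= 1e-100; }
  }
  if (std::abs(jA) < 1e-300) return cplx(0.0, 0.0);
  return -jB / jA;
}

// least-squares fit of tau in R(w) ~ R(0)/(1 + i w tau), on a log frequency
// grid; golden-section search on log10(tau)
static double fit_tau(const std::vector<double> &w,
                      const std::vector<std::complex<double> > &resp,
                      double r1_0) {
  if (std::fabs(r1_0) < 1e-14) return 15.0; // silent regime: inert default
  auto loss = [&](double tau) {
    double s = 0.0;
    for (size_t i = 0; i < w.size(); i++) {
      std::complex<double> model =
          r1_0 / std::complex<double>(1.0, w[i] * tau);
      s += std::norm(resp[i] - model);
    }
    return s;
  };
  double lo = std::log10(0.05), hi = std::log10(150.0);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = loss(std::pow(10.0, c)), fd = loss(std::pow(10.0, d));
  for (int it = 0; it < 60; it++) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = loss(std::pow(10.0, c)); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = loss(std::pow(10.0, d)); }
  }
  return std::pow(10.0, 0.5 * (a + b));
}

// [[Rcpp::export]]
List build_transfer_table_cpp(List neuron, NumericVector mu_grid,
                              NumericVector sigma_grid, double Vlb, double dV,
                              NumericVector fit_freqs_hz) {
  Eif e = eif_from_list(neuron);
  const int nm = mu_grid.size(), ns = sigma_grid.size();
  NumericMatrix r(nm, ns), V(nm, ns), tau(nm, ns);

  std::vector<double> w(fit_freqs_hz.size());
  for (int i = 0; i < (int)w.size(); i++)
    w[i] = 2.0 * M_PI * fit_freqs_hz[i] * 1e-3; // rad/ms

  for (int jx = 0; jx < ns; jx++) {
    const double sg = sigma_grid[jx];
    for (int ix = 0; ix < nm; ix++) {
      const double mu = mu_grid[ix];
      double r0, Vm;
      steady_state(e, mu, sg, Vlb, dV, r0, Vm);
      r(ix, jx) = r0;
      V(ix, jx) = Vm;
      if (r0 < 1e-7) { // essentially silent: response fit is ill-conditioned
        tau(ix, jx) = e.C / e.gL;
        continue;
      }
      // zero-frequency response by central finite difference of r0(mu)
      double rp, rm, dummy;
      const double dmu = 1e-3;
      steady_state(e, mu + dmu, sg, Vlb, dV, rp, dummy);
      steady_state(e, mu - dmu, sg, Vlb, dV, rm, dummy);
      const double r1_0 = (rp - rm) / (2.0 * dmu);
      std::vector<std::complex<double> > resp(w.size());
      for (size_t k = 0; k < w.size(); k++)
        resp[k] = rate_response(e, mu, sg, Vlb, dV, w[k], r0);
      tau(ix, jx) = fit_tau(w, resp, r1_0);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["mu_grid"] = mu_grid, _["sigma_grid"] = sigma_grid,
                      _["r"] = r, _["V"] = V, _["tau"] = tau);
}

// Monte-Carlo oracle: population rate of N independent EIF neurons (no
// adaptation) under matching white-noise input, used to validate the
// Fokker-Planck tables.
// [[Rcpp::export]]
NumericVector mc_eif_rate_cpp(List neuron, double mu, double sigma, int n_neuron,
                              double t_total, double dt, double t_burn) {
  Eif e = eif_from_list(neuron);
  const int n_steps = (int)std::round(t_total / dt);
  const int burn_steps = (int)std::round(t_burn / dt);
  const double sq = sigma * std::sqrt(dt);
  long spikes = 0;
  RNGScope scope;
  for (int j = 0; j < n_neuron; j++) {
    double v = e.EL;
    double refr = 0.0;
    for (int i = 0; i < n_steps; i++) {
      if (refr > 0) { refr -= dt; continue; }
      v += dt * (e.F(v) + mu) + sq * norm_rand();
      if (v >= e.Vs) {
        v = e.Vr;
        refr = e.Tref;
        if (i >= burn_steps) spikes++;
      }
    }
  }
  const double rate_khz =
      (double)spikes / n_neuron / (t_total - t_burn); // spikes per ms
  return NumericVector::create(rate_khz);
}
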