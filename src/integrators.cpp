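// Forward-Euler integrators for the thalamic node, the cortical mean-field
// node, and the coupled thalamocortical loop.
//
// Conventions: time in ms, voltages in mV, conductances in mS/cm^2 (thalamus),
// currents in mV/ms ("current" divided by capacitance; cortex), firing rates
// in kHz internally (converted to Hz at the R interface). Background noise is
// a pre-integrated Ornstein-Uhlenbeck series sampled at dt and inserted with
// zero-order hold.
//
// Thalamic kinetics: relay-cell T-current after Destexhe et al. (1998),
// reticular T-current after Destexhe et al. (1996), anomalous rectifier I_h
// with two-state calcium-dependent open states after Destexhe et al. (1996),
// assembled as in the conductance-based thalamic mass model of
// Schellenberger Costa et al. (2016). Cortical mean-field follows the
// linear-nonlinear cascade reduction of AdEx populations (Augustin et al.
// 2017; Cakan & Obermayer 2020).

#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------- thalamus

struct ThalParams {
  double tau_t, tau_r, C_m, Q_max, theta, sigma, C1;
  double gamma_e, gamma_i, w_e, w_i;
  double E_L, E_AMPA, E_GABA, E_K, E_Ca, E_h;
  double g_LK, g_T_t, g_T_r, g_h, g_inc;
  double alpha_Ca, tau_Ca, Ca_0, k1, k2, k3, k4, n_P;
  double N_tr, N_rt, N_rr;
};

static ThalParams thal_from_list(const List &p) {
  ThalParams q;
  q.tau_t = p["tau_t"]; q.tau_r = p["tau_r"]; q.C_m = p["C_m"];
  q.Q_max = p["Q_max"]; q.theta = p["theta"]; q.sigma = p["sigma"];
  q.C1 = p["C1"];
  q.gamma_e = p["gamma_e"]; q.gamma_i = p["gamma_i"];
  q.w_e = p["w_e"]; q.w_i = p["w_i"];
  q.E_L = p["E_L"]; q.E_AMPA = p["E_AMPA"]; q.E_GABA = p["E_GABA"];
  q.E_K = p["E_K"]; q.E_Ca = p["E_Ca"]; q.E_h = p["E_h"];
  q.g_LK = p["g_LK"]; q.g_T_t = p["g_T_t"]; q.g_T_r = p["g_T_r"];
  q.g_h = p["g_h"]; q.g_inc = p["g_inc"];
  q.alpha_Ca = p["alpha_Ca"]; q.tau_Ca = p["tau_Ca"]; q.Ca_0 = p["Ca_0"];
  q.k1 = p["k1"]; q.k2 = p["k2"]; q.k3 = p["k3"]; q.k4 = p["k4"];
  q.n_P = p["n_P"];
  q.N_tr = p["N_tr"]; q.N_rt = p["N_rt"]; q.N_rr = p["N_rr"];
  return q;
}

inline double thal_rate(double V, const ThalParams &p) {
  return p.Q_max / (1.0 + std::exp(-p.C1 * (V - p.theta) / p.sigma));
}
inline double m_inf_T_t(double V) { return 1.0 / (1.0 + std::exp(-(V + 59.0) / 6.2)); }
inline double h_inf_T_t(double V) { return 1.0 / (1.0 + std::exp((V + 81.0) / 4.0)); }
inline double tau_h_T_t(double V) {
  return (30.8 + (211.4 + std::exp((V + 115.2) / 5.0)) /
                     (1.0 + std::exp((V + 86.0) / 3.2))) / 3.7371928;
}
inline double m_inf_T_r(double V) { return 1.0 / (1.0 + std::exp(-(V + 52.0) / 7.4)); }
inline double h_inf_T_r(double V) { return 1.0 / (1.0 + std::exp((V + 80.0) / 5.0)); }
inline double tau_h_T_r(double V) {
  return (85.0 + 1.0 / (std::exp((V + 48.0) / 4.0) +
                        std::exp(-(V + 407.0) / 50.0))) / 3.7371928;
}
inline double m_inf_h(double V) { return 1.0 / (1.0 + std::exp((V + 75.0) / 5.5)); }
inline double tau_m_h(double V) {
  return 20.0 + 1000.0 / (std::exp((V + 71.5) / 14.2) +
                          std::exp(-(V + 89.0) / 11.6));
}

// state layout: V_t, V_r, h_t, h_r, m_h1, m_h2, Ca,
//               s_et, ds_et, s_it, ds_it, s_er, ds_er, s_ir, ds_ir
#define NTHAL 15

static void thal_derivs(const double *x, double *dx, const ThalParams &p,
                        double ext_exc_khz, double noise) {
  const double V_t = x[0], V_r = x[1], h_t = x[2], h_r = x[3];
  const double m_h1 = x[4], m_h2 = x[5], Ca = x[6];

  const double Q_t = thal_rate(V_t, p), Q_r = thal_rate(V_r, p);

  const double mt = m_inf_T_t(V_t), mr = m_inf_T_r(V_r);
  const double I_LK_t = p.g_LK * (V_t - p.E_K);
  const double I_LK_r = p.g_LK * (V_r - p.E_K);
  const double I_T_t = p.g_T_t * mt * mt * h_t * (V_t - p.E_Ca);
  const double I_T_r = p.g_T_r * mr * mr * h_r * (V_r - p.E_Ca);
  const double I_h = p.g_h * (m_h1 + p.g_inc * m_h2) * (V_t - p.E_h);

  dx[0] = (-(V_t - p.E_L) - p.w_e * x[7] * (V_t - p.E_AMPA) -
           p.w_i * x[9] * (V_t - p.E_GABA)) / p.tau_t -
          (I_LK_t + I_T_t + I_h) / p.C_m;
  dx[1] = (-(V_r - p.E_L) - p.w_e * x[11] * (V_r - p.E_AMPA) -
           p.w_i * x[13] * (V_r - p.E_GABA)) / p.tau_r -
          (I_LK_r + I_T_r) / p.C_m;

  dx[2] = (h_inf_T_t(V_t) - h_t) / tau_h_T_t(V_t);
  dx[3] = (h_inf_T_r(V_r) - h_r) / tau_h_T_r(V_r);

  const double ca_pow = std::pow(Ca, p.n_P);
  const double P_h = p.k1 * ca_pow / (p.k1 * ca_pow + p.k2);
  dx[4] = (m_inf_h(V_t) * (1.0 - m_h1 - m_h2) - m_h1) / tau_m_h(V_t) -
          p.k3 * P_h * m_h1 + p.k4 * m_h2;
  dx[5] = p.k3 * P_h * m_h1 - p.k4 * m_h2;
  dx[6] = p.alpha_Ca * I_T_t + (p.Ca_0 - Ca) / p.tau_Ca;

  const double ge2 = p.gamma_e * p.gamma_e, gi2 = p.gamma_i * p.gamma_i;
  // AMPA onto TCR: cortical/external drive + background noise (only entry
  // point of the thalamic noise)
  dx[7] = x[8];
  dx[8] = ge2 * (ext_exc_khz + noise - x[7]) - 2.0 * p.gamma_e * x[8];
  // GABA_A onto TCR: TRN
  dx[9] = x[10];
  dx[10] = gi2 * (p.N_tr * Q_r - x[9]) - 2.0 * p.gamma_i * x[10];
  // AMPA onto TRN: TCR + cortical/external drive
  dx[11] = x[12];
  dx[12] = ge2 * (p.N_rt * Q_t + ext_exc_khz - x[11]) - 2.0 * p.gamma_e * x[12];
  // GABA_A onto TRN: TRN self-inhibition
  dx[13] = x[14];
  dx[14] = gi2 * (p.N_rr * Q_r - x[13]) - 2.0 * p.gamma_i * x[14];
}

static void thal_init(double *x, const ThalParams &p) {
  x[0] = p.E_L; x[1] = p.E_L;
  x[2] = h_inf_T_t(p.E_L); x[3] = h_inf_T_r(p.E_L);
  x[4] = m_inf_h(p.E_L); x[5] = 0.0; x[6] = p.Ca_0;
  for (int i = 7; i < NTHAL; i++) x[i] = 0.0;
}

inline double series_at(const NumericVector &v, int i) {
  // broadcast a length-1 vector (constant drive / noise-free case)
  if (v.size() == 1) return v[0];
  return v[i];
}

// [[Rcpp::export]]
List sim_thalamus_cpp(List par, double dt, double duration, int samp_every,
                      NumericVector noise, NumericVector ext_rate_khz,
                      bool keep_full) {
  ThalParams p = thal_from_list(par);
  const int n_steps = (int)std::round(duration / dt);
  const bool has_noise = noise.size() > 0, has_ext = ext_rate_khz.size() > 0;
  if (has_noise && noise.size() != 1 && noise.size() < n_steps)
    stop("noise series shorter than the number of integration steps");
  if (has_ext && ext_rate_khz.size() != 1 && ext_rate_khz.size() < n_steps)
    stop("external rate series shorter than the number of integration steps");

  double x[NTHAL], dx[NTHAL];
  thal_init(x, p);

  const int n_out = n_steps / samp_every;
  NumericVector t_out(n_out), r_t(n_out), r_r(n_out), V_t(n_out), V_r(n_out);
  NumericVector full_r_t(keep_full ? n_steps : 0);

  int k = 0;
  for (int i = 0; i < n_steps; i++) {
    const double ext = has_ext ? series_at(ext_rate_khz, i) : 0.0;
    const double ns = has_noise ? series_at(noise, i) : 0.0;
    thal_derivs(x, dx, p, ext, ns);
    for (int j = 0; j < NTHAL; j++) x[j] += dt * dx[j];
    if (!R_finite(x[0]) || !R_finite(x[1]))
      stop("thalamic state diverged at t = %g ms", (i + 1) * dt);
    if (keep_full) full_r_t[i] = 1000.0 * thal_rate(x[0], p);
    if ((i + 1) % samp_every == 0) {
      t_out[k] = (i + 1) * dt;
      r_t[k] = 1000.0 * thal_rate(x[0], p);
      r_r[k] = 1000.0 * thal_rate(x[1], p);
      V_t[k] = x[0]; V_r[k] = x[1];
      k++;
    }
  }
  List out = List::create(_["time"] = t_out, _["r_TCR"] = r_t,
                          _["r_TRN"] = r_r, _["V_t"] = V_t, _["V_r"] = V_r);
  if (keep_full) out["r_TCR_full"] = full_r_t;
  return out;
}

// ------------------------------------------------------------------ cortex

struct Table {
  NumericVector mu, sg;   // strictly increasing axes
  NumericMatrix r, V, tau; // nrow = length(mu), ncol = length(sg)
};

struct CxParams {
  double C, a, b, EA, tauA, taum;
  double tau_se, tau_si;
  double cee, cie, cei, cii;  // per-spike increment constants
  double c_ext, K_ext;        // long-range afferent channel (thalamic drive)
  double Ke, Ki;
  double Jee, Jie, Jei, Jii;  // maximum synaptic currents (mV/ms, signed)
  double de, di;
  double sigmae_ext, sigmai_ext;
};

static CxParams cx_from_list(const List &p) {
  CxParams q;
  q.C = p["C"]; q.a = p["a"]; q.b = p["b"]; q.EA = p["EA"];
  q.tauA = p["tauA"]; q.taum = p["taum"];
  q.tau_se = p["tau_se"]; q.tau_si = p["tau_si"];
  q.cee = p["cee"]; q.cie = p["cie"]; q.cei = p["cei"]; q.cii = p["cii"];
  q.c_ext = p["c_ext"]; q.K_ext = p["K_ext"];
  q.Ke = p["Ke"]; q.Ki = p["Ki"];
  q.Jee = p["Jee"]; q.Jie = p["Jie"]; q.Jei = p["Jei"]; q.Jii = p["Jii"];
  q.de = p["de"]; q.di = p["di"];
  q.sigmae_ext = p["sigmae_ext"]; q.sigmai_ext = p["sigmai_ext"];
  return q;
}

static Table table_from_list(const List &tl) {
  Table t;
  t.mu = tl["mu_grid"]; t.sg = tl["sigma_grid"];
  t.r = as<NumericMatrix>(tl["r"]);
  t.V = as<NumericMatrix>(tl["V"]);
  t.tau = as<NumericMatrix>(tl["tau"]);
  return t;
}

// bilinear interpolation with clamped extrapolation (uniform grids)
static void table_lookup(const Table &t, double mu, double sg,
                         double &r, double &V, double &tau) {
  const int nm = t.mu.size(), ns = t.sg.size();
  const double dmu = t.mu[1] - t.mu[0], dsg = t.sg[1] - t.sg[0];
  double fx = (mu - t.mu[0]) / dmu, fy = (sg - t.sg[0]) / dsg;
  if (fx < 0) fx = 0; if (fx > nm - 1) fx = nm - 1;
  if (fy < 0) fy = 0; if (fy > ns - 1) fy = ns - 1;
  int ix = (int)fx, iy = (int)fy;
  if (ix > nm - 2) ix = nm - 2;
  if (iy > ns - 2) iy = ns - 2;
  const double wx = fx - ix, wy = fy - iy;
  const double w00 = (1 - wx) * (1 - wy), w10 = wx * (1 - wy),
               w01 = (1 - wx) * wy, w11 = wx * wy;
  r = w00 * t.r(ix, iy) + w10 * t.r(ix + 1, iy) +
      w01 * t.r(ix, iy + 1) + w11 * t.r(ix + 1, iy + 1);
  V = w00 * t.V(ix, iy) + w10 * t.V(ix + 1, iy) +
      w01 * t.V(ix, iy + 1) + w11 * t.V(ix + 1, iy + 1);
  tau = w00 * t.tau(ix, iy) + w10 * t.tau(ix + 1, iy) +
        w01 * t.tau(ix, iy + 1) + w11 * t.tau(ix + 1, iy + 1);
}

// [[Rcpp::export]]
List lookup_transfer_cpp(List table, NumericVector mu, NumericVector sigma) {
  Table t = table_from_list(table);
  const int n = mu.size();
  NumericVector r(n), V(n), tau(n);
  for (int i = 0; i < n; i++) table_lookup(t, mu[i], sigma[i], r[i], V[i], tau[i]);
  return List::create(_["r"] = r, _["V"] = V, _["tau"] = tau);
}

// Cortical state: mufe, mufi, IA, seem, seim, siem, siim,
//                 seev, seiv, siev, siiv  (means/variances of active-synapse
//                 fractions; "seim" = E population, inhibitory afferent)
struct CxState {
  double mufe, mufi, IA;
  double seem, seim, siem, siim;
  double seev, seiv, siev, siiv;
  double re, ri, Ve; // algebraic outputs of the transfer functions (kHz, mV)
};

static void cx_algebraic(CxState &s, const CxParams &p, const Table &t,
                         double z1ee, double z1ei, double z1ie, double z1ii,
                         double &sigmae, double &sigmai,
                         double &tau_e, double &tau_i) {
  sigmae = std::sqrt(
      2.0 * p.Jee * p.Jee * s.seev * p.tau_se * p.taum /
          ((1.0 + z1ee) * p.taum + p.tau_se) +
      2.0 * p.Jei * p.Jei * s.seiv * p.tau_si * p.taum /
          ((1.0 + z1ei) * p.taum + p.tau_si) +
      p.sigmae_ext * p.sigmae_ext);
  sigmai = std::sqrt(
      2.0 * p.Jie * p.Jie * s.siev * p.tau_se * p.taum /
          ((1.0 + z1ie) * p.taum + p.tau_se) +
      2.0 * p.Jii * p.Jii * s.siiv * p.tau_si * p.taum /
          ((1.0 + z1ii) * p.taum + p.tau_si) +
      p.sigmai_ext * p.sigmai_ext);
  double dummyV, dummyTau;
  // adaptation shifts the effective mean input of the E population only
  table_lookup(t, s.mufe - s.IA / p.C, sigmae, s.re, s.Ve, tau_e);
  table_lookup(t, s.mufi, sigmai, s.ri, dummyV, dummyTau);
  tau_i = dummyTau;
  (void)dummyV;
}

// One Euler step of the cortical node. rd_* are delayed rates (kHz);
// ext_ee_khz is an additional excitatory afferent rate entering the E<-E
// synaptic channel (thalamic relay drive); mu_ou_* are the pre-integrated
// external OU currents (mV/ms).
static void cx_step(CxState &s, const CxParams &p, const Table &t, double dt,
                    double rd_ee, double rd_ie, double rd_ei, double rd_ii,
                    double ext_ee_khz, double mu_ou_e, double mu_ou_i) {
  const double z1ee = p.cee * p.Ke * p.tau_se * rd_ee +
                      p.c_ext * p.K_ext * p.tau_se * ext_ee_khz;
  const double z2ee = p.cee * p.cee * p.Ke * p.tau_se * p.tau_se * rd_ee +
                      p.c_ext * p.c_ext * p.K_ext * p.tau_se * p.tau_se * ext_ee_khz;
  const double z1ie = p.cie * p.Ke * p.tau_se * rd_ie;
  const double z2ie = p.cie * p.cie * p.Ke * p.tau_se * p.tau_se * rd_ie;
  const double z1ei = p.cei * p.Ki * p.tau_si * rd_ei;
  const double z2ei = p.cei * p.cei * p.Ki * p.tau_si * p.tau_si * rd_ei;
  const double z1ii = p.cii * p.Ki * p.tau_si * rd_ii;
  const double z2ii = p.cii * p.cii * p.Ki * p.tau_si * p.tau_si * rd_ii;

  double sigmae, sigmai, tau_e, tau_i;
  cx_algebraic(s, p, t, z1ee, z1ei, z1ie, z1ii, sigmae, sigmai, tau_e, tau_i);

  const double mue = p.Jee * s.seem + p.Jei * s.seim + mu_ou_e;
  const double mui = p.Jie * s.siem + p.Jii * s.siim + mu_ou_i;

  const double d_mufe = (mue - s.mufe) / tau_e;
  const double d_mufi = (mui - s.mufi) / tau_i;
  const double d_IA = (p.a * (s.Ve - p.EA) - s.IA) / p.tauA + p.b * s.re;

  const double d_seem = ((1.0 - s.seem) * z1ee - s.seem) / p.tau_se;
  const double d_seim = ((1.0 - s.seim) * z1ei - s.seim) / p.tau_si;
  const double d_siem = ((1.0 - s.siem) * z1ie - s.siem) / p.tau_se;
  const double d_siim = ((1.0 - s.siim) * z1ii - s.siim) / p.tau_si;

  const double tse2 = p.tau_se * p.tau_se, tsi2 = p.tau_si * p.tau_si;
  const double d_seev = ((1.0 - s.seem) * (1.0 - s.seem) * z2ee +
                         (z2ee - 2.0 * p.tau_se * (z1ee + 1.0)) * s.seev) / tse2;
  const double d_seiv = ((1.0 - s.seim) * (1.0 - s.seim) * z2ei +
                         (z2ei - 2.0 * p.tau_si * (z1ei + 1.0)) * s.seiv) / tsi2;
  const double d_siev = ((1.0 - s.siem) * (1.0 - s.siem) * z2ie +
                         (z2ie - 2.0 * p.tau_se * (z1ie + 1.0)) * s.siev) / tse2;
  const double d_siiv = ((1.0 - s.siim) * (1.0 - s.siim) * z2ii +
                         (z2ii - 2.0 * p.tau_si * (z1ii + 1.0)) * s.siiv) / tsi2;

  s.mufe += dt * d_mufe; s.mufi += dt * d_mufi; s.IA += dt * d_IA;
  s.seem += dt * d_seem; s.seim += dt * d_seim;
  s.siem += dt * d_siem; s.siim += dt * d_siim;
  s.seev += dt * d_seev; s.seiv += dt * d_seiv;
  s.siev += dt * d_siev; s.siiv += dt * d_siiv;
  if (s.seev < 0) s.seev = 0; if (s.seiv < 0) s.seiv = 0;
  if (s.siev < 0) s.siev = 0; if (s.siiv < 0) s.siiv = 0;
}

static void cx_init(CxState &s, const CxParams &p, const Table &t,
                    double mu_e0, double mu_i0) {
  s.mufe = mu_e0; s.mufi = mu_i0; s.IA = 0.0;
  s.seem = s.seim = s.siem = s.siim = 0.0;
  s.seev = s.seiv = s.siev = s.siiv = 0.0;
  double sigmae, sigmai, tau_e, tau_i;
  cx_algebraic(s, p, t, 0, 0, 0, 0, sigmae, sigmai, tau_e, tau_i);
}

struct Ring {
  std::vector<double> buf;
  int n, head;
  void init(int steps, double value) {
    n = steps > 0 ? steps : 1;
    buf.assign(n, value);
    head = 0;
  }
  // value delayed by exactly n steps (the oldest stored entry)
  double read() const { return buf[head]; }
  void push(double v) { buf[head] = v; head = (head + 1) % n; }
};

// [[Rcpp::export]]
List sim_cortex_cpp(List par, List table, double dt, double duration,
                    int samp_every, double mu_e_drift, double mu_i_drift,
                    NumericVector ou_e, NumericVector ou_i,
                    NumericVector ext_rate_khz) {
  CxParams p = cx_from_list(par);
  Table t = table_from_list(table);
  const int n_steps = (int)std::round(duration / dt);
  const bool has_ext = ext_rate_khz.size() > 0;

  CxState s;
  cx_init(s, p, t, mu_e_drift, mu_i_drift);

  Ring rde, rdi;
  rde.init((int)std::round(p.de / dt), s.re);
  rdi.init((int)std::round(p.di / dt), s.ri);

  const int n_out = n_steps / samp_every;
  NumericVector t_out(n_out), r_e(n_out), r_i(n_out), IA(n_out), mufe(n_out);
  int k = 0;
  for (int i = 0; i < n_steps; i++) {
    const double rd_exc = rde.read(), rd_inh = rdi.read();
    const double ext = has_ext ? series_at(ext_rate_khz, i) : 0.0;
    const double oue = ou_e.size() ? series_at(ou_e, i) : mu_e_drift;
    const double oui = ou_i.size() ? series_at(ou_i, i) : mu_i_drift;
    cx_step(s, p, t, dt, rd_exc, rd_exc, rd_inh, rd_inh, ext, oue, oui);
    if (!R_finite(s.mufe) || !R_finite(s.re))
      stop("cortical state diverged at t = %g ms", (i + 1) * dt);
    rde.push(s.re); rdi.push(s.ri);
    if ((i + 1) % samp_every == 0) {
      t_out[k] = (i + 1) * dt;
      r_e[k] = 1000.0 * s.re; r_i[k] = 1000.0 * s.ri;
      IA[k] = s.IA; mufe[k] = s.mufe;
      k++;
    }
  }
  return List::create(_["time"] = t_out, _["r_E"] = r_e, _["r_I"] = r_i,
                      _["I_A"] = IA, _["mu_E"] = mufe);
}

// ------------------------------------------------------------- full loop

// [[Rcpp::export]]
List sim_loop_cpp(List cx_par, List table, List thal_par, double dt,
                  double duration, int samp_every,
                  double mu_e_drift, double mu_i_drift,
                  double n_ctx_thal, double n_thal_ctx, double delay_ms,
                  NumericVector ou_e, NumericVector ou_i,
                  NumericVector noise_tcr) {
  CxParams cp = cx_from_list(cx_par);
  Table t = table_from_list(table);
  ThalParams tp = thal_from_list(thal_par);
  const int n_steps = (int)std::round(duration / dt);

  CxState cs;
  cx_init(cs, cp, t, mu_e_drift, mu_i_drift);
  double x[NTHAL], dx[NTHAL];
  thal_init(x, tp);

  Ring rde, rdi;                 // intracortical delays
  rde.init((int)std::round(cp.de / dt), cs.re);
  rdi.init((int)std::round(cp.di / dt), cs.ri);
  Ring ctx2thal, thal2ctx;       // long-range 13 ms delays (both directions)
  const int dsteps = (int)std::round(delay_ms / dt);
  ctx2thal.init(dsteps, cs.re);
  thal2ctx.init(dsteps, thal_rate(x[0], tp));

  const int n_out = n_steps / samp_every;
  NumericVector t_out(n_out), r_e(n_out), r_i(n_out), r_t(n_out), r_r(n_out),
      IA(n_out);
  int k = 0;
  for (int i = 0; i < n_steps; i++) {
    const double rd_exc = rde.read(), rd_inh = rdi.read();
    const double r_ctx_del = ctx2thal.read();   // r_E(t - d), kHz
    const double r_tcr_del = thal2ctx.read();   // r_TCR(t - d), kHz
    const double oue = ou_e.size() ? series_at(ou_e, i) : mu_e_drift;
    const double oui = ou_i.size() ? series_at(ou_i, i) : mu_i_drift;
    const double ns = noise_tcr.size() ? series_at(noise_tcr, i) : 0.0;

    cx_step(cs, cp, t, dt, rd_exc, rd_exc, rd_inh, rd_inh,
            n_thal_ctx * r_tcr_del, oue, oui);
    thal_derivs(x, dx, tp, n_ctx_thal * r_ctx_del, ns);
    for (int j = 0; j < NTHAL; j++) x[j] += dt * dx[j];

    if (!R_finite(cs.mufe) || !R_finite(x[0]))
      stop("loop state diverged at t = %g ms", (i + 1) * dt);

    rde.push(cs.re); rdi.push(cs.ri);
    ctx2thal.push(cs.re);
    thal2ctx.push(thal_rate(x[0], tp));

    if ((i + 1) % samp_every == 0) {
      t_out[k] = (i + 1) * dt;
      r_e[k] = 1000.0 * cs.re; r_i[k] = 1000.0 * cs.ri;
      r_t[k] = 1000.0 * thal_rate(x[0], tp);
      r_r[k] = 1000.0 * thal_rate(x[1], tp);
      IA[k] = cs.IA;
      k++;
    }
  }
  return List::create(_["time"] = t_out, _["r_E"] = r_e, _["r_I"] = r_i,
                      _["r_TCR"] = r_t, _["r_TRN"] = r_r, _["I_A"] = IA);
}
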