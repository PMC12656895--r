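// Backward-Euler integrator for an unbranched compartmental cable
// (dendrite -- soma -- hillock -- myelinated axon chain).
//
// Units: V mV, t ms, capacitance nF, conductance uS, current nA,
// concentration mM.  Gate variables advance by exact exponential
// relaxation at the freshly solved voltage (operator splitting), so the
// scheme is unconditionally stable at the default 25 us step.
//
// The exported entry point equilibrates the cell once and then runs a
// batch of current-clamp protocols from the cached equilibrium state;
// rate lookup tables are built once per call.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
using namespace Rcpp;

namespace {

const double VMIN = -150.0, VMAX = 100.0, DV = 0.05;
const int NTAB = (int)((VMAX - VMIN) / DV + 0.5) + 1;
const double FARADAY = 96485.0; // C/mol

struct GateTab {
  std::vector<double> inf, fac; // fac = 1 - exp(-dt/tau)
};

inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

double tau_eval(const List& tau, double v) {
  std::string type = as<std::string>(tau["type"]);
  double tmin = as<double>(tau["tmin"]);
  if (type == "const") return tmin;
  // bell: tmin + tamp / (exp((v-vt)/k1) + exp(-(v-vt)/k2))
  double tamp = as<double>(tau["tamp"]);
  double vt = as<double>(tau["vt"]);
  double k1 = as<double>(tau["k1"]);
  double k2 = as<double>(tau["k2"]);
  return tmin + tamp / (std::exp((v - vt) / k1) + std::exp(-(v - vt) / k2));
}

GateTab build_vgate_tab(const List& g, double dt, double tau_scale) {
  GateTab t;
  t.inf.resize(NTAB);
  t.fac.resize(NTAB);
  double vh = as<double>(g["vh"]), k = as<double>(g["k"]);
  List tau = g["tau"];
  for (int i = 0; i < NTAB; ++i) {
    double v = VMIN + i * DV;
    t.inf[i] = boltz(v, vh, k);
    double tv = tau_eval(tau, v) * tau_scale;
    if (tv < 1e-4) tv = 1e-4;
    t.fac[i] = 1.0 - std::exp(-dt / tv);
  }
  return t;
}

// Squid-type nodal kinetics (rate functions of the classic 'hh' scheme).
inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

void build_hh_tabs(double dt, double tau_scale, GateTab& m, GateTab& h,
                   GateTab& n) {
  m.inf.resize(NTAB); m.fac.resize(NTAB);
  h.inf.resize(NTAB); h.fac.resize(NTAB);
  n.inf.resize(NTAB); n.fac.resize(NTAB);
  for (int i = 0; i < NTAB; ++i) {
    double v = VMIN + i * DV;
    double am = 0.1 * vtrap(-(v + 40.0), 10.0);
    double bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
    double ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
    double bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    double an = 0.01 * vtrap(-(v + 55.0), 10.0);
    double bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
    double tm = tau_scale / (am + bm), th = tau_scale / (ah + bh),
           tn = tau_scale / (an + bn);
    m.inf[i] = am / (am + bm); m.fac[i] = 1.0 - std::exp(-dt / tm);
    h.inf[i] = ah / (ah + bh); h.fac[i] = 1.0 - std::exp(-dt / th);
    n.inf[i] = an / (an + bn); n.fac[i] = 1.0 - std::exp(-dt / tn);
  }
}

inline void tab_at(const GateTab& t, double v, double& inf, double& fac) {
  double x = (v - VMIN) / DV;
  if (x < 0) x = 0;
  if (x > NTAB - 1.001) x = NTAB - 1.001;
  int i = (int)x;
  double w = x - i;
  inf = t.inf[i] + w * (t.inf[i + 1] - t.inf[i]);
  fac = t.fac[i] + w * (t.fac[i + 1] - t.fac[i]);
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

struct ChanSpec {
  // gate exponents; p_inact/p_inact2 of 0 mean the gate is absent.
  // inact2 is a second (slow) inactivation gate, used by the sodium
  // channel to model use-dependent depolarization block.
  int p_act, p_inact, p_inact2;
  int act_type;            // 0 voltage, 1 SK (Ca Hill), 2 BK (V + Ca)
  double erev;
  bool is_ca;
  GateTab act_tab, inact_tab, inact2_tab; // voltage gates
  double sk_ec50, sk_n, sk_fac;
  double bk_vh0, bk_shift, bk_caref, bk_k, bk_fac;
};

struct Protocol {
  int kind; // 0 hold, 1 step, 2 ramp
  double t_on, t_off, a0, a1, tstop;
  double current_pA(double t) const {
    if (kind == 0 || t <= t_on || t > t_off) return 0.0;
    if (kind == 1) return a0;
    return a0 + (a1 - a0) * (t - t_on) / (t_off - t_on);
  }
};

struct Sim {
  int ncomp, nh, nn, nch, inj;
  double dt;
  std::vector<double> cm, area, gl, el, glo, ghi;
  std::vector<int> hill_idx, node_idx, is_hill, is_node;
  std::vector<ChanSpec> cs;
  std::vector<std::vector<double>> gbar_uS; // [chan][hill comp]
  std::vector<double> gna_uS, gk_uS, glhh_uS;
  double hh_ena, hh_ek, hh_el;
  GateTab tm, th, tn;
  double depth_cm, ca0, tau_ca, ptot, kon, koff;
  // state layout offsets
  int off_ga, off_gi, off_gi2, off_nd, off_ca, off_b, nstate;
  // workspace
  std::vector<double> adiag, rhs, cpr, dpr;

  void init_offsets() {
    off_ga = ncomp;
    off_gi = off_ga + nch * nh;
    off_gi2 = off_gi + nch * nh;
    off_nd = off_gi2 + nch * nh;
    off_ca = off_nd + 3 * nn;
    off_b = off_ca + nh;
    nstate = off_b + nh;
    adiag.resize(ncomp);
    rhs.resize(ncomp);
    cpr.resize(ncomp);
    dpr.resize(ncomp);
  }

  void steady_state(std::vector<double>& st, double v_init) const {
    for (int i = 0; i < ncomp; ++i) st[i] = v_init;
    for (int c = 0; c < nch; ++c)
      for (int j = 0; j < nh; ++j) {
        double inf = 1.0, fac;
        if (cs[c].act_type == 0)
          tab_at(cs[c].act_tab, v_init, inf, fac);
        else if (cs[c].act_type == 1) {
          double cn = std::pow(ca0, cs[c].sk_n);
          inf = cn / (cn + std::pow(cs[c].sk_ec50, cs[c].sk_n));
        } else {
          double vh = cs[c].bk_vh0 -
                      cs[c].bk_shift * std::log10(ca0 / cs[c].bk_caref);
          inf = boltz(v_init, vh, cs[c].bk_k);
        }
        st[off_ga + c * nh + j] = inf;
        double iinf = 1.0;
        if (cs[c].p_inact > 0) {
          double f;
          tab_at(cs[c].inact_tab, v_init, iinf, f);
        }
        st[off_gi + c * nh + j] = iinf;
        double i2inf = 1.0;
        if (cs[c].p_inact2 > 0) {
          double f;
          tab_at(cs[c].inact2_tab, v_init, i2inf, f);
        }
        st[off_gi2 + c * nh + j] = i2inf;
      }
    for (int j = 0; j < nn; ++j) {
      double inf, fac;
      tab_at(tm, v_init, inf, fac); st[off_nd + 3 * j] = inf;
      tab_at(th, v_init, inf, fac); st[off_nd + 3 * j + 1] = inf;
      tab_at(tn, v_init, inf, fac); st[off_nd + 3 * j + 2] = inf;
    }
    double kd = (kon > 0) ? koff / kon : 1.0;
    for (int j = 0; j < nh; ++j) {
      st[off_ca + j] = ca0;
      st[off_b + j] = (ptot > 0) ? ptot * ca0 / (ca0 + kd) : 0.0;
    }
  }

  // advance one backward-Euler step; returns false on divergence
  bool step(std::vector<double>& st, double iinj_nA) {
    for (int i = 0; i < ncomp; ++i) {
      double a = cm[i] / dt + gl[i] + glo[i] + ghi[i];
      double b = cm[i] / dt * st[i] + gl[i] * el[i];
      int jh = is_hill[i];
      if (jh >= 0) {
        for (int c = 0; c < nch; ++c) {
          double g = gbar_uS[c][jh] *
                     ipow(st[off_ga + c * nh + jh], cs[c].p_act);
          if (cs[c].p_inact > 0)
            g *= ipow(st[off_gi + c * nh + jh], cs[c].p_inact);
          if (cs[c].p_inact2 > 0)
            g *= ipow(st[off_gi2 + c * nh + jh], cs[c].p_inact2);
          a += g;
          b += g * cs[c].erev;
        }
      }
      int jn = is_node[i];
      if (jn >= 0) {
        double m = st[off_nd + 3 * jn], h = st[off_nd + 3 * jn + 1],
               n = st[off_nd + 3 * jn + 2];
        double gna = gna_uS[jn] * m * m * m * h;
        double gk = gk_uS[jn] * n * n * n * n;
        a += gna + gk + glhh_uS[jn];
        b += gna * hh_ena + gk * hh_ek + glhh_uS[jn] * hh_el;
      }
      if (i == inj) b += iinj_nA;
      adiag[i] = a;
      rhs[i] = b;
    }
    // Thomas solve (sub-diagonal -glo, super-diagonal -ghi)
    cpr[0] = -ghi[0] / adiag[0];
    dpr[0] = rhs[0] / adiag[0];
    for (int i = 1; i < ncomp; ++i) {
      double mden = adiag[i] + glo[i] * cpr[i - 1];
      cpr[i] = -ghi[i] / mden;
      dpr[i] = (rhs[i] + glo[i] * dpr[i - 1]) / mden;
    }
    st[ncomp - 1] = dpr[ncomp - 1];
    for (int i = ncomp - 2; i >= 0; --i)
      st[i] = dpr[i] - cpr[i] * st[i + 1];

    // gate updates at the new voltage
    for (int j = 0; j < nh; ++j) {
      double v = st[hill_idx[j]];
      double caj = st[off_ca + j];
      for (int c = 0; c < nch; ++c) {
        double inf, fac;
        if (cs[c].act_type == 0) {
          tab_at(cs[c].act_tab, v, inf, fac);
        } else if (cs[c].act_type == 1) {
          double cn = std::pow(caj, cs[c].sk_n);
          inf = cn / (cn + std::pow(cs[c].sk_ec50, cs[c].sk_n));
          fac = cs[c].sk_fac;
        } else {
          double vh = cs[c].bk_vh0 -
                      cs[c].bk_shift * std::log10(caj / cs[c].bk_caref);
          inf = boltz(v, vh, cs[c].bk_k);
          fac = cs[c].bk_fac;
        }
        double& x = st[off_ga + c * nh + j];
        x += fac * (inf - x);
        if (cs[c].p_inact > 0) {
          double iinf, ifac;
          tab_at(cs[c].inact_tab, v, iinf, ifac);
          double& y = st[off_gi + c * nh + j];
          y += ifac * (iinf - y);
        }
        if (cs[c].p_inact2 > 0) {
          double iinf, ifac;
          tab_at(cs[c].inact2_tab, v, iinf, ifac);
          double& y2 = st[off_gi2 + c * nh + j];
          y2 += ifac * (iinf - y2);
        }
      }
    }
    for (int j = 0; j < nn; ++j) {
      double v = st[node_idx[j]];
      double inf, fac;
      double& m = st[off_nd + 3 * j];
      tab_at(tm, v, inf, fac); m += fac * (inf - m);
      double& h = st[off_nd + 3 * j + 1];
      tab_at(th, v, inf, fac); h += fac * (inf - h);
      double& n = st[off_nd + 3 * j + 2];
      tab_at(tn, v, inf, fac); n += fac * (inf - n);
    }

    // calcium + parvalbumin (implicit 2x2 Newton; reduces to the exact
    // linear backward-Euler update when no buffer is present)
    for (int j = 0; j < nh; ++j) {
      double v = st[hill_idx[j]];
      double ica_nA = 0.0;
      for (int c = 0; c < nch; ++c) {
        if (!cs[c].is_ca) continue;
        double g = gbar_uS[c][j] *
                   ipow(st[off_ga + c * nh + j], cs[c].p_act);
        if (cs[c].p_inact > 0)
          g *= ipow(st[off_gi + c * nh + j], cs[c].p_inact);
        if (cs[c].p_inact2 > 0)
          g *= ipow(st[off_gi2 + c * nh + j], cs[c].p_inact2);
        ica_nA += g * (v - cs[c].erev);
      }
      double ica_dens = ica_nA * 1e-6 / area[hill_idx[j]]; // mA/cm^2
      double J = -ica_dens / (2.0 * FARADAY * depth_cm);   // mM/ms
      if (J < 0) J = 0; // inward rectification of the shell source term
      double can = st[off_ca + j], bn = st[off_b + j];
      double ca = can, b = bn;
      for (int it = 0; it < 4; ++it) {
        double bind = kon * ca * (ptot - b) - koff * b;
        double f1 = ca - can - dt * (J - (ca - ca0) / tau_ca - bind);
        double f2 = b - bn - dt * bind;
        double j11 = 1.0 + dt / tau_ca + dt * kon * (ptot - b);
        double j12 = -dt * (kon * ca + koff);
        double j21 = -dt * kon * (ptot - b);
        double j22 = 1.0 + dt * (kon * ca + koff);
        double det = j11 * j22 - j12 * j21;
        double dca = (-f1 * j22 + f2 * j12) / det;
        double db = (-j11 * f2 + j21 * f1) / det;
        ca += dca;
        b += db;
        if (std::fabs(dca) < 1e-15 && std::fabs(db) < 1e-15) break;
      }
      if (ca < 0) ca = 0;
      if (b < 0) b = 0;
      if (b > ptot) b = ptot;
      st[off_ca + j] = ca;
      st[off_b + j] = b;
    }

    for (int i = 0; i < ncomp; ++i)
      if (!std::isfinite(st[i]) || std::fabs(st[i]) > 200.0) return false;
    return true;
  }
};

Sim build_sim(List cell, double dt, double tau_scale) {
  Sim s;
  s.dt = dt;
  s.ncomp = as<int>(cell["ncomp"]);
  s.cm = as<std::vector<double>>(cell["cm_nF"]);
  s.area = as<std::vector<double>>(cell["area_cm2"]);
  s.gl = as<std::vector<double>>(cell["gl_uS"]);
  s.el = as<std::vector<double>>(cell["el_mV"]);
  std::vector<double> gax = as<std::vector<double>>(cell["g_ax_uS"]);
  s.glo.assign(s.ncomp, 0.0);
  s.ghi.assign(s.ncomp, 0.0);
  for (int i = 0; i + 1 < s.ncomp; ++i) {
    s.ghi[i] = gax[i];
    s.glo[i + 1] = gax[i];
  }
  s.hill_idx = as<std::vector<int>>(cell["hillock_idx"]);
  s.node_idx = as<std::vector<int>>(cell["node_idx"]);
  s.nh = (int)s.hill_idx.size();
  s.nn = (int)s.node_idx.size();
  s.inj = as<int>(cell["inj_idx"]);
  s.is_hill.assign(s.ncomp, -1);
  s.is_node.assign(s.ncomp, -1);
  for (int j = 0; j < s.nh; ++j) s.is_hill[s.hill_idx[j]] = j;
  for (int j = 0; j < s.nn; ++j) s.is_node[s.node_idx[j]] = j;

  List channels = cell["channels"];
  NumericVector theta = cell["theta"];
  s.nch = channels.size();
  s.cs.resize(s.nch);
  s.gbar_uS.assign(s.nch, std::vector<double>(s.nh, 0.0));
  for (int c = 0; c < s.nch; ++c) {
    List ch = channels[c];
    ChanSpec& q = s.cs[c];
    q.p_act = as<int>(ch["p_act"]);
    q.p_inact = as<int>(ch["p_inact"]);
    q.p_inact2 = ch.containsElementNamed("p_inact2")
                     ? as<int>(ch["p_inact2"]) : 0;
    q.erev = as<double>(ch["erev"]);
    q.is_ca = as<bool>(ch["is_ca"]);
    List act = ch["act"];
    std::string at = as<std::string>(act["type"]);
    if (at == "v") {
      q.act_type = 0;
      q.act_tab = build_vgate_tab(act, dt, tau_scale);
    } else if (at == "sk") {
      q.act_type = 1;
      q.sk_ec50 = as<double>(act["ec50"]);
      q.sk_n = as<double>(act["hill_n"]);
      double tv = as<double>(act["tau_ms"]) * tau_scale;
      q.sk_fac = 1.0 - std::exp(-dt / tv);
    } else {
      q.act_type = 2;
      q.bk_vh0 = as<double>(act["vh0"]);
      q.bk_shift = as<double>(act["shift_per_decade"]);
      q.bk_caref = as<double>(act["caref"]);
      q.bk_k = as<double>(act["k"]);
      double tv = as<double>(act["tau_ms"]) * tau_scale;
      q.bk_fac = 1.0 - std::exp(-dt / tv);
    }
    if (q.p_inact > 0) {
      List inact = ch["inact"];
      q.inact_tab = build_vgate_tab(inact, dt, tau_scale);
    }
    if (q.p_inact2 > 0) {
      List inact2 = ch["inact2"];
      q.inact2_tab = build_vgate_tab(inact2, dt, tau_scale);
    }
    double dens = theta[c];
    for (int j = 0; j < s.nh; ++j)
      s.gbar_uS[c][j] = dens * s.area[s.hill_idx[j]] * 1e6;
  }

  List hh = cell["hh"];
  s.hh_ena = as<double>(hh["ena"]);
  s.hh_ek = as<double>(hh["ek"]);
  s.hh_el = as<double>(hh["el"]);
  double gna = as<double>(hh["gna"]), gk = as<double>(hh["gk"]),
         glh = as<double>(hh["gl"]);
  s.gna_uS.resize(s.nn);
  s.gk_uS.resize(s.nn);
  s.glhh_uS.resize(s.nn);
  for (int j = 0; j < s.nn; ++j) {
    double a = s.area[s.node_idx[j]] * 1e6;
    s.gna_uS[j] = gna * a;
    s.gk_uS[j] = gk * a;
    s.glhh_uS[j] = glh * a;
  }
  double hh_q10 = hh.containsElementNamed("rate_factor")
                      ? as<double>(hh["rate_factor"]) : 1.0;
  build_hh_tabs(dt, tau_scale / hh_q10, s.tm, s.th, s.tn);

  List ca_par = cell["ca"];
  s.depth_cm = as<double>(ca_par["depth_um"]) * 1e-4;
  s.ca0 = as<double>(ca_par["ca0_mM"]);
  s.tau_ca = as<double>(ca_par["tau_ms"]);
  List pv = cell["pv"];
  s.ptot = as<double>(pv["ptot_mM"]);
  s.kon = as<double>(pv["kon"]);
  s.koff = as<double>(pv["koff"]);

  s.init_offsets();
  return s;
}

Protocol parse_protocol(List p) {
  Protocol q;
  std::string kind = as<std::string>(p["kind"]);
  double onset = as<double>(p["onset_ms"]);
  double dur = as<double>(p["duration_ms"]);
  double tail = as<double>(p["tail_ms"]);
  q.t_on = onset;
  q.t_off = onset + dur;
  q.tstop = onset + dur + tail;
  if (kind == "hold") {
    q.kind = 0;
    q.a0 = q.a1 = 0.0;
  } else if (kind == "step") {
    q.kind = 1;
    q.a0 = q.a1 = as<double>(p["amplitude_pA"]);
  } else if (kind == "ramp") {
    q.kind = 2;
    q.a0 = as<double>(p["from_pA"]);
    q.a1 = as<double>(p["to_pA"]);
  } else {
    stop("unknown protocol kind: %s", kind.c_str());
  }
  return q;
}

} // namespace

// Equilibrate for t_equil, then run each protocol from the cached
// equilibrium state.  Records voltage at record_idx (0-based) compartments
// every step.  Returns equilibration trace, one trace matrix per protocol,
// per-protocol divergence flags, optional submembrane-calcium traces and
// the full equilibrated state vector.
// [[Rcpp::export(name = ".sim_batch")]]
List sim_batch(List cell, List protocols, double dt, double t_equil,
               double v_init, IntegerVector record_idx, double tau_scale,
               Nullable<NumericVector> state0_ = R_NilValue,
               bool record_ca = false, bool record_equil = false) {
  Sim s = build_sim(cell, dt, tau_scale);
  const int nrec = record_idx.size();
  for (int r = 0; r < nrec; ++r)
    if (record_idx[r] < 0 || record_idx[r] >= s.ncomp)
      stop("record index out of range");

  std::vector<double> st(s.nstate);
  if (state0_.isNotNull()) {
    NumericVector s0(state0_);
    if ((int)s0.size() != s.nstate) stop("state vector has wrong length");
    for (int i = 0; i < s.nstate; ++i) st[i] = s0[i];
  } else {
    s.steady_state(st, v_init);
  }

  const int nequil = (int)std::lround(t_equil / dt);
  NumericMatrix equil_v(record_equil ? nrec : 0,
                        record_equil ? nequil + 1 : 0);
  bool equil_ok = true;
  if (record_equil)
    for (int r = 0; r < nrec; ++r) equil_v(r, 0) = st[record_idx[r]];
  for (int k = 1; k <= nequil; ++k) {
    if (!s.step(st, 0.0)) {
      equil_ok = false;
      break;
    }
    if (record_equil)
      for (int r = 0; r < nrec; ++r) equil_v(r, k) = st[record_idx[r]];
  }

  NumericVector eq_state(s.nstate);
  for (int i = 0; i < s.nstate; ++i) eq_state[i] = st[i];

  const int nprot = protocols.size();
  List traces(nprot), ca_traces(nprot);
  LogicalVector diverged(nprot);
  for (int p = 0; p < nprot; ++p) {
    Protocol pr = parse_protocol(protocols[p]);
    int nsteps = (int)std::lround(pr.tstop / dt);
    NumericMatrix vrec(nrec, nsteps + 1);
    NumericVector carec(record_ca ? nsteps + 1 : 0);
    std::vector<double> stp(eq_state.begin(), eq_state.end());
    for (int r = 0; r < nrec; ++r) vrec(r, 0) = stp[record_idx[r]];
    if (record_ca && s.nh > 0) carec[0] = stp[s.off_ca];
    bool ok = equil_ok;
    for (int k = 1; k <= nsteps && ok; ++k) {
      double t_new = k * dt;
      ok = s.step(stp, pr.current_pA(t_new) * 1e-3);
      for (int r = 0; r < nrec; ++r) vrec(r, k) = stp[record_idx[r]];
      if (record_ca && s.nh > 0) carec[k] = stp[s.off_ca];
    }
    diverged[p] = !ok;
    traces[p] = vrec;
    ca_traces[p] = carec;
  }

  return List::create(
      _["equil_v"] = equil_v, _["equil_ok"] = equil_ok,
      _["eq_state"] = eq_state, _["traces"] = traces,
      _["ca"] = ca_traces, _["diverged"] = diverged);
}

// Single-step sanity helper: maximum absolute rate of voltage change over
// all compartments for a run with no stimulus (used by resting-state
// diagnostics and tests).
// [[Rcpp::export(name = ".rest_dvdt")]]
NumericVector rest_dvdt(List cell, double dt, double t_total, double v_init,
                        double tau_scale) {
  Sim s = build_sim(cell, dt, tau_scale);
  std::vector<double> st(s.nstate);
  s.steady_state(st, v_init);
  int nsteps = (int)std::lround(t_total / dt);
  NumericVector out(nsteps);
  std::vector<double> prev(st.begin(), st.begin() + s.ncomp);
  for (int k = 0; k < nsteps; ++k) {
    if (!s.step(st, 0.0)) {
      for (int j = k; j < nsteps; ++j) out[j] = NA_REAL;
      break;
    }
    double mx = 0.0;
    for (int i = 0; i < s.ncomp; ++i) {
      double d = std::fabs(st[i] - prev[i]) / dt;
      if (d > mx) mx = d;
      prev[i] = st[i];
    }
    out[k] = mx;
  }
  return out;
}
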